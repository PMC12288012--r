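#' Label frames by property-derived conformational state
#'
#' Partitions frames into low / intermediate / high property states (e.g.
#' inactive, intermediate and active states of a receptor, or unfolded /
#' intermediate / folded states along an RMSD) using two cutoffs. By
#' default the cutoffs are the property's tercile quantiles.
#'
#' @param property An `rc_property` or numeric vector.
#' @param cutoffs Numeric pair of strictly increasing cutoffs in property
#'   units, or `NULL` for tercile quantiles.
#' @return An object of class `rc_states`: list with `labels` (integer per
#'   frame: 0 low, 1 intermediate, 2 high) and `cutoffs`.
#' @export
state_labels <- function(property, cutoffs = NULL) {
  v <- property_values(property)
  if (any(!is.finite(v))) stop("property values must be finite")
  if (is.null(cutoffs)) {
    cutoffs <- unname(stats::quantile(v, c(1 / 3, 2 / 3)))
  }
  stopifnot(is.numeric(cutoffs), length(cutoffs) == 2L)
  if (!(cutoffs[1] < cutoffs[2])) {
    rc_stop("state cutoffs must be strictly increasing", "rc_invalid_cutoffs")
  }
  labels <- (v > cutoffs[1]) + (v > cutoffs[2])
  structure(list(labels = as.integer(labels), cutoffs = cutoffs),
            class = "rc_states")
}

#' Residue covariation network among top-ranked reaction coordinates
#'
#' Nodes are the `top_k` residues of a reaction-coordinate ranking; for
#' every unordered pair the edge weight is the Pearson correlation of their
#' polar-angle series across frames. Edges are flagged as passing when
#' `|weight| >= threshold` — absolute value, because anticorrelated coupling
#' is coordination all the same. Edges measure temporal coordination only,
#' never spatial proximity. All `k(k-1)/2` pairs are reported.
#'
#' @param ranking An `rc_ranking` from [rank_reaction_coordinates()].
#' @param top_k Number of top-ranked residues to use as nodes (default 10).
#' @param threshold Absolute-correlation threshold in \[0, 1\] (default 0.7).
#' @return A data frame with columns `residue_a`, `residue_b` (labels,
#'   canonical order: ascending residue index), `weight`, `passes`;
#'   `threshold` and `top_k` kept as attributes.
#' @export
residue_network <- function(ranking, top_k = 10L, threshold = 0.7) {
  stopifnot(inherits(ranking, "rc_ranking"),
            is.numeric(threshold), threshold >= 0, threshold <= 1)
  if (!is_count(top_k) || top_k < 2L) {
    rc_stop("need at least 2 nodes for a network", "rc_insufficient_nodes")
  }
  if (top_k > nrow(ranking$table)) {
    rc_stop(sprintf("top_k = %d exceeds the %d ranked residues",
                    top_k, nrow(ranking$table)),
            "rc_insufficient_nodes")
  }
  tab <- ranking$table[seq_len(top_k), ]
  th <- ranking$theta[, seq_len(top_k), drop = FALSE]
  pairs <- utils::combn(top_k, 2L)
  edges <- data.frame(
    residue_a = character(ncol(pairs)), residue_b = character(ncol(pairs)),
    weight = numeric(ncol(pairs)), passes = logical(ncol(pairs)),
    stringsAsFactors = FALSE
  )
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    if (tab$residue_index[i] > tab$residue_index[j]) { tmp <- i; i <- j; j <- tmp }
    w <- stats::cor(th[, pairs[1, p]], th[, pairs[2, p]])
    edges$residue_a[p] <- tab$residue_label[i]
    edges$residue_b[p] <- tab$residue_label[j]
    edges$weight[p] <- w
    edges$passes[p] <- is.finite(w) && abs(w) >= threshold
  }
  attr(edges, "threshold") <- threshold
  attr(edges, "top_k") <- as.integer(top_k)
  edges
}

#' Write network edge and node tables as CSV
#'
#' @param edges Edge data frame from [residue_network()].
#' @param ranking The `rc_ranking` the network was built from (for the node
#'   table); may be `NULL` to skip nodes.
#' @param edge_file,node_file Output paths (`node_file` optional).
#' @return `edge_file`, invisibly.
#' @export
write_network_csv <- function(edges, edge_file, ranking = NULL, node_file = NULL) {
  utils::write.csv(edges, edge_file, row.names = FALSE)
  if (!is.null(node_file) && !is.null(ranking)) {
    k <- attr(edges, "top_k")
    utils::write.csv(ranking$table[seq_len(k), ], node_file, row.names = FALSE)
  }
  invisible(edge_file)
}
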