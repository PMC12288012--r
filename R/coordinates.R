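#' Polar-angle series of a residue's alpha-carbon
#'
#' The reaction-coordinate features are per-residue polar angles
#' \eqn{\theta = \arccos(z/r)} of the alpha-carbon (CA) in the aligned
#' common frame, with `r` the atom's distance from the origin; the CA is a
#' sufficient proxy for whole-residue dynamics. The ratio `z/r` is clamped
#' to \[-1, 1\] before `arccos` to guard against rounding.
#'
#' @param traj An aligned `rc_trajectory`.
#' @param residue Residue selector (internal 0-based index, `"R131"`,
#'   `"131"`, or `"A:131"`).
#' @param r_min Guard radius for atoms at the origin.
#' @return An object of class `rc_theta`: list with `residue_index`,
#'   `residue_label`, `values` (radians, in \[0, pi\]).
#' @export
theta_series <- function(traj, residue, r_min = 1e-6) {
  ridx <- resolve_residue(traj, residue)
  a <- which(traj$atoms$residue_index == ridx & traj$atoms$atom_name == "CA")
  if (length(a) == 0L) {
    rc_stop(paste0("residue ", ridx, " has no CA atom"), "rc_selector_resolution")
  }
  a <- a[1]
  P <- matrix(traj$coords[, a, ], ncol = 3L)
  r <- sqrt(rowSums(P^2))
  if (any(r < r_min)) {
    rc_stop(sprintf("CA of residue %d lies at the origin in frame %d",
                    ridx, which(r < r_min)[1]),
            "rc_degenerate_position")
  }
  theta <- acos(pmin(1, pmax(-1, P[, 3] / r)))
  structure(list(residue_index = ridx,
                 residue_label = traj$atoms$residue_label[a],
                 values = theta),
            class = "rc_theta")
}

#' Rank residues as reaction coordinates on a fixed embedding
#'
#' Scores every residue's CA polar-angle series against PC1 of the supplied
#' (property-optimal) embedding with [correlation_ratio()], reusing one PC1
#' partition for all residues so that scores are computed on exactly the
#' representation that won the property search. Residues are ranked by `Cr`
#' descending, ties broken by residue index ascending. Residues lacking a
#' CA atom (e.g. coarse or non-standard entries) are skipped with a warning.
#'
#' @param traj The aligned `rc_trajectory` the embedding was computed from.
#' @param embedding The winning `rc_embedding` (e.g.
#'   `search$best_embedding`), or a numeric PC1 vector.
#' @param n_sections,scheme Sectioning, normally the same as used for the
#'   property search.
#' @return An object of class `rc_ranking`: list with `table` (columns
#'   `rank`, `residue_label`, `residue_index`, `Cr`, `S`, `R2`, `V`),
#'   `theta` (`n_frames x n_ranked` matrix of angle series, columns in rank
#'   order), and `results` (per-residue `rc_cr` in rank order).
#' @export
rank_reaction_coordinates <- function(traj, embedding, n_sections = 5L,
                                      scheme = c("equal-count", "equal-width")) {
  scheme <- match.arg(scheme)
  pc1 <- if (inherits(embedding, "rc_embedding")) embedding$pc1 else as.numeric(embedding)
  stopifnot(length(pc1) == n_frames(traj))
  pc1s <- (pc1 - mean(pc1)) / stats::sd(pc1)
  base <- make_sections(pc1s, pc1s, n_sections = n_sections, scheme = scheme)

  ridx_all <- unique(traj$atoms$residue_index)
  has_ca <- ridx_all %in% traj$atoms$residue_index[traj$atoms$atom_name == "CA"]
  if (any(!has_ca)) {
    warning(sum(!has_ca), " residue(s) lack a CA atom and were skipped")
  }
  ridx <- ridx_all[has_ca]
  thetas <- lapply(ridx, function(i) theta_series(traj, i))
  scores <- lapply(thetas, function(th) {
    correlation_ratio(pc1, th$values, n_sections = n_sections, scheme = scheme,
                      sections = base)
  })
  tab <- data.frame(
    residue_label = vapply(thetas, `[[`, "", "residue_label"),
    residue_index = vapply(thetas, `[[`, 0L, "residue_index"),
    Cr = vapply(scores, `[[`, 0, "Cr"),
    S = vapply(scores, `[[`, 0, "S"),
    R2 = vapply(scores, `[[`, 0, "R2"),
    V = vapply(scores, `[[`, 0, "V"),
    stringsAsFactors = FALSE
  )
  ord <- order(-tab$Cr, tab$residue_index)
  tab <- tab[ord, , drop = FALSE]
  tab <- cbind(rank = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  theta_mat <- do.call(cbind, lapply(thetas[ord], `[[`, "values"))
  colnames(theta_mat) <- tab$residue_label
  structure(list(table = tab, theta = theta_mat, results = scores[ord]),
            class = "rc_ranking")
}

#' @export
print.rc_ranking <- function(x, n = 10L, ...) {
  cat(sprintf("<rc_ranking> %d residues scored; top %d:\n",
              nrow(x$table), min(n, nrow(x$table))))
  print(utils::head(x$table, n), row.names = FALSE)
  invisible(x)
}

#' Write a ranked-coordinate table as CSV
#'
#' Angles are scored in radians internally; this table is the user-facing
#' report (one row per residue, rank order).
#'
#' @param ranking An `rc_ranking`.
#' @param file Output path.
#' @param top_k Optional cap on the number of rows written.
#' @return `file`, invisibly.
#' @export
write_ranking_csv <- function(ranking, file, top_k = NULL) {
  tab <- ranking$table
  if (!is.null(top_k)) tab <- utils::head(tab, top_k)
  utils::write.csv(tab, file, row.names = FALSE)
  invisible(file)
}
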