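#' Grid search for the kernel weights maximizing the correlation ratio
#'
#' Runs the full representation pipeline — kernel feature map, 2D PCA
#' embedding, correlation ratio of PC1 against the property — for every
#' weight triple in `grid`, and flags the entry with the highest `Cr` as the
#' optimal representation. Ties are broken by the lexicographically smallest
#' weight triple (and by grid position among exact duplicates), so the
#' search is fully deterministic.
#'
#' @param traj An aligned `rc_trajectory`.
#' @param property An `rc_property` (or numeric vector) of length `n_frames`.
#' @param grid List of [kernel_weights()]; default [lambda_grid()] (15 triples).
#' @param n_sections,scheme Sectioning for [correlation_ratio()].
#' @param atom_mode Label recorded in the report (`"all-atoms"`, `"CB-only"`,
#'   `"custom"`); purely descriptive.
#' @return An object of class `rc_search`: list with `table` (one row per
#'   grid entry: lambda1..3, S, R2, V, Cr, is_best), `results` (the `rc_cr`
#'   objects), `best` (index), `best_weights`, `best_result`, and
#'   `best_embedding` (the winning `rc_embedding`, kept for downstream
#'   residue ranking).
#' @export
find_optimal_representation <- function(traj, property, grid = lambda_grid(),
                                        n_sections = 5L,
                                        scheme = c("equal-count", "equal-width"),
                                        atom_mode = "custom") {
  scheme <- match.arg(scheme)
  if (length(grid) == 0L) rc_stop("kernel weight grid is empty", "rc_empty_grid")
  pv <- property_values(property)
  stopifnot(length(pv) == n_frames(traj))
  results <- vector("list", length(grid))
  embeddings <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    emb <- pca_embed(kernel_transform(traj, grid[[i]]))
    results[[i]] <- correlation_ratio(emb$pc1, pv, n_sections = n_sections,
                                      scheme = scheme)
    embeddings[[i]] <- emb
  }
  W <- do.call(rbind, lapply(grid, unclass))
  tab <- data.frame(
    lambda1 = W[, 1], lambda2 = W[, 2], lambda3 = W[, 3],
    S = vapply(results, `[[`, 0, "S"),
    R2 = vapply(results, `[[`, 0, "R2"),
    V = vapply(results, `[[`, 0, "V"),
    Cr = vapply(results, `[[`, 0, "Cr")
  )
  cand <- which(tab$Cr == max(tab$Cr))
  cand <- cand[order(tab$lambda1[cand], tab$lambda2[cand], tab$lambda3[cand], cand)]
  best <- cand[1]
  tab$is_best <- seq_len(nrow(tab)) == best
  structure(list(table = tab, results = results, best = best,
                 best_weights = grid[[best]],
                 best_result = results[[best]],
                 best_embedding = embeddings[[best]],
                 n_sections = as.integer(n_sections), scheme = scheme,
                 atom_mode = atom_mode),
            class = "rc_search")
}

#' @export
print.rc_search <- function(x, ...) {
  b <- x$table[x$best, ]
  cat(sprintf("<rc_search> %d weight triples (%s); best K(%g, %g, %g) with Cr = %.4g\n",
              nrow(x$table), x$atom_mode, b$lambda1, b$lambda2, b$lambda3, b$Cr))
  invisible(x)
}

#' Write a search report as CSV / JSON
#'
#' @param report An `rc_search`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_search_csv <- function(report, file) {
  utils::write.csv(report$table, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_search_csv
#' @export
search_to_json <- function(report, file = NULL) {
  obj <- list(atom_mode = report$atom_mode,
              n_sections = report$n_sections, scheme = report$scheme,
              best = report$best,
              best_weights = as.numeric(unclass(report$best_weights)),
              entries = report$table)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(file)) {
    writeLines(js, file)
    return(invisible(js))
  }
  js
}

#' Beta-carbon reduction ratio
#'
#' Compares the best correlation ratio attainable from the full atom set
#' with the best attainable from beta-carbon (CB) atoms alone, as the
#' percentage `100 * Cr(CB) / Cr(all)`. Values near (or above) 100 indicate
#' that the reduced CB representation preserves — or, by filtering out less
#' informative atoms, improves — the structure-property correlation.
#'
#' @inheritParams find_optimal_representation
#' @return An object of class `rc_reduction`: list with `cr_subset`,
#'   `cr_total`, `ratio_percent`, and the two underlying `rc_search` reports
#'   (`search_subset`, `search_total`).
#' @export
cb_reduction_ratio <- function(traj, property, grid = lambda_grid(),
                               n_sections = 5L,
                               scheme = c("equal-count", "equal-width")) {
  scheme <- match.arg(scheme)
  cb <- select_atoms(traj, "CB")  # errors if the protein has no CB atoms
  s_all <- find_optimal_representation(traj, property, grid,
                                       n_sections = n_sections, scheme = scheme,
                                       atom_mode = "all-atoms")
  s_cb <- find_optimal_representation(cb, property, grid,
                                      n_sections = n_sections, scheme = scheme,
                                      atom_mode = "CB-only")
  cr_total <- s_all$best_result$Cr
  cr_subset <- s_cb$best_result$Cr
  structure(list(cr_subset = cr_subset, cr_total = cr_total,
                 ratio_percent = if (cr_total > 0) 100 * cr_subset / cr_total
                                 else NA_real_,
                 search_subset = s_cb, search_total = s_all),
            class = "rc_reduction")
}

#' @export
print.rc_reduction <- function(x, ...) {
  cat(sprintf("<rc_reduction> Cr(CB) = %.4g, Cr(all) = %.4g, ratio = %.2f%%\n",
              x$cr_subset, x$cr_total, x$ratio_percent))
  invisible(x)
}
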