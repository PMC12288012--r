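#' Partition PC1 into sections and summarise a series within each
#'
#' The correlation-ratio statistic works on a sectioning of the PC1 axis.
#' The default `"equal-count"` scheme uses quantile bins each holding
#' `floor(n/k)` or `ceiling(n/k)` points (ties and remainders resolved by
#' stable frame order, extras going to the lowest sections); `"equal-width"`
#' uses `k` uniform bins over the PC1 range and refuses bins with fewer
#' than two points.
#'
#' @param pc1 Numeric vector (typically standardized PC1 scores).
#' @param series Numeric vector of the same length: the scored quantity.
#' @param n_sections Number of sections `k` (default 5, i.e. quintiles —
#'   20 percent of the data points per section).
#' @param scheme `"equal-count"` (default) or `"equal-width"`.
#' @return An object of class `rc_sections`: list with `n_sections`, `edges`
#'   (length `k+1` boundaries on the PC1 axis), `means`, `centers` (mean PC1
#'   per section), `variances` (sample variance, denominator `n-1`),
#'   `counts`, and `assignment` (section index per frame).
#' @export
make_sections <- function(pc1, series, n_sections = 5L,
                          scheme = c("equal-count", "equal-width")) {
  scheme <- match.arg(scheme)
  series <- property_values(series)
  stopifnot(length(pc1) == length(series), is_count(n_sections), n_sections >= 1)
  n <- length(pc1)
  k <- as.integer(n_sections)
  if (n < 2L * k) stop("need at least 2 points per section (n >= 2k)")
  if (scheme == "equal-count") {
    ord <- order(pc1)  # stable: ties keep frame order
    sizes <- rep(n %/% k, k)
    rem <- n %% k
    if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
    assignment <- integer(n)
    assignment[ord] <- rep.int(seq_len(k), sizes)
    s <- pc1[ord]
    cum <- cumsum(sizes)
    interior <- (s[cum[-k]] + s[cum[-k] + 1L]) / 2
    edges <- c(s[1], interior, s[n])
  } else {
    edges <- seq(min(pc1), max(pc1), length.out = k + 1L)
    assignment <- findInterval(pc1, edges, rightmost.closed = TRUE,
                               all.inside = TRUE)
    counts <- tabulate(assignment, nbins = k)
    if (any(counts < 2L)) {
      rc_stop(paste0("equal-width sectioning leaves ", sum(counts < 2L),
                     " section(s) with < 2 points; use scheme = 'equal-count'"),
              "rc_sparse_section")
    }
  }
  stats <- section_stats(assignment, k, pc1, series)
  structure(c(list(n_sections = k, edges = edges, scheme = scheme,
                   assignment = assignment), stats),
            class = "rc_sections")
}

# Per-section summaries for a (possibly different) series on a fixed partition.
section_stats <- function(assignment, k, pc1, series) {
  counts <- tabulate(assignment, nbins = k)
  means <- vapply(seq_len(k), function(i) mean(series[assignment == i]), 0)
  variances <- vapply(seq_len(k), function(i) stats::var(series[assignment == i]), 0)
  centers <- vapply(seq_len(k), function(i) mean(pc1[assignment == i]), 0)
  list(means = means, variances = variances, centers = centers, counts = counts)
}

#' Correlation ratio between PC1 and a per-frame series
#'
#' Scores how strongly a scalar series tracks PC1. PC1 is standardized to
#' zero mean and unit variance (so values are comparable across kernel
#' weight settings), partitioned into `n_sections` sections, and an ordinary
#' least-squares line is fitted to the per-section points
#' `(mean PC1, mean series)`. With slope magnitude `S`, coefficient of
#' determination `R2` of that fit, and `V` the mean of the per-section
#' sample variances of the series, the statistic is
#' \deqn{C_r = S \cdot R^2 / \sqrt{\max(V, \epsilon)}, \quad \epsilon = 10^{-12}.}
#' `S` is taken as the absolute slope so that equally strong decreasing
#' relationships score the same as increasing ones; `Cr` is invariant to
#' positive rescaling of the series, which is what makes per-residue angle
#' scores comparable.
#'
#' @inheritParams make_sections
#' @param pc1 Numeric vector of PC1 scores, or an `rc_embedding`.
#' @param standardize Standardize PC1 first (default `TRUE`). Raw-PC1 fits
#'   are available for completeness but are not comparable across kernels.
#' @param sections Optional `rc_sections` whose partition (built from the
#'   same standardized PC1) is reused; the per-section summaries are
#'   recomputed for `series`.
#' @return An object of class `rc_cr`: list with `S`, `R2`, `V`, `Cr`,
#'   `sections`, `n_sections`, `scheme`.
#' @export
correlation_ratio <- function(pc1, series, n_sections = 5L,
                              scheme = c("equal-count", "equal-width"),
                              standardize = TRUE, sections = NULL) {
  scheme <- match.arg(scheme)
  if (inherits(pc1, "rc_embedding")) pc1 <- pc1$pc1
  series <- property_values(series)
  stopifnot(length(pc1) == length(series))
  k <- as.integer(n_sections)
  if (k < 3L) {
    rc_stop("need at least 3 sections to fit a line", "rc_underdetermined_fit")
  }
  if (standardize) {
    s <- stats::sd(pc1)
    if (!is.finite(s) || s == 0) {
      rc_stop("PC1 has zero variance", "rc_degenerate_abscissa")
    }
    pc1 <- (pc1 - mean(pc1)) / s
  }
  if (is.null(sections)) {
    sec <- make_sections(pc1, series, n_sections = k, scheme = scheme)
  } else {
    stopifnot(inherits(sections, "rc_sections"),
              length(sections$assignment) == length(pc1))
    st <- section_stats(sections$assignment, sections$n_sections, pc1, series)
    sec <- sections
    sec[names(st)] <- st
    k <- sec$n_sections
  }
  if (stats::sd(sec$centers) == 0) {
    rc_stop("section centers are degenerate on the PC1 axis",
            "rc_degenerate_abscissa")
  }
  slope <- stats::cov(sec$centers, sec$means) / stats::var(sec$centers)
  R2 <- if (stats::sd(sec$means) == 0) 0 else
    stats::cor(sec$centers, sec$means)^2
  S <- abs(slope)
  V <- mean(sec$variances)
  Cr <- S * R2 / sqrt(max(V, 1e-12))
  structure(list(S = S, R2 = R2, V = V, Cr = Cr, sections = sec,
                 n_sections = k, scheme = sec$scheme,
                 standardized = standardize),
            class = "rc_cr")
}

#' @export
print.rc_cr <- function(x, ...) {
  cat(sprintf("<rc_cr> Cr = %.4g  (S = %.4g, R2 = %.4f, V = %.4g; %d %s sections)\n",
              x$Cr, x$S, x$R2, x$V, x$n_sections, x$scheme))
  invisible(x)
}

#' Serialize a correlation-ratio result to JSON
#'
#' @param x An `rc_cr`.
#' @param file Optional path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `file`).
#' @export
cr_to_json <- function(x, file = NULL) {
  stopifnot(inherits(x, "rc_cr"))
  obj <- list(S = x$S, R2 = x$R2, V = x$V, Cr = x$Cr,
              n_sections = x$n_sections, scheme = x$scheme,
              edges = x$sections$edges, means = x$sections$means,
              counts = x$sections$counts)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(file)) {
    writeLines(js, file)
    return(invisible(js))
  }
  js
}
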