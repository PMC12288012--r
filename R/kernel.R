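#' Kernel weight triple on the simplex
#'
#' The angular kernel is a convex combination of three squared-trigonometric
#' terms; its weights \eqn{(\lambda_1,\lambda_2,\lambda_3)} must each lie in
#' \[0, 1\] and sum to 1.
#'
#' @param lambda1,lambda2,lambda3 Dimensionless weights.
#' @return An object of class `rc_weights` (named numeric of length 3).
#' @export
kernel_weights <- function(lambda1, lambda2, lambda3) {
  w <- c(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3)
  if (any(!is.finite(w)) || any(w < -1e-12) || any(w > 1 + 1e-12)) {
    stop("each kernel weight must lie in [0, 1]")
  }
  if (abs(sum(w) - 1) > 1e-12) {
    stop("kernel weights must sum to 1 (got ", format(sum(w)), ")")
  }
  structure(pmin(pmax(w, 0), 1), class = "rc_weights")
}

#' Enumerate the kernel-weight grid
#'
#' All ordered triples drawn from `{0, step, 2*step, ..., 1}` that sum to 1,
#' in lexicographic order. The default `step = 0.25` gives the 15-point grid
#' used for the representation search.
#'
#' @param step Grid spacing; `1/step` must be a positive integer.
#' @return A list of [kernel_weights()] objects.
#' @examples
#' length(lambda_grid(0.25))  # 15
#' @export
lambda_grid <- function(step = 0.25) {
  if (!is.numeric(step) || length(step) != 1L || step <= 0 || step > 1 ||
      abs(1 / step - round(1 / step)) > 1e-9) {
    rc_stop("step must lie in (0, 1] with 1/step a positive integer",
            "rc_invalid_step")
  }
  vals <- seq(0, 1, by = step)
  g <- expand.grid(lambda3 = vals, lambda2 = vals, lambda1 = vals)
  g <- g[, c("lambda1", "lambda2", "lambda3")]
  g <- g[abs(rowSums(g) - 1) < 1e-9, , drop = FALSE]
  g <- g[order(g$lambda1, g$lambda2, g$lambda3), , drop = FALSE]
  lapply(seq_len(nrow(g)),
         function(i) kernel_weights(g$lambda1[i], g$lambda2[i], g$lambda3[i]))
}

#' Angular kernel feature map
#'
#' For every atom in every frame computes
#' \deqn{K = \lambda_1 \cos^2(x/r) + \lambda_2 \cos^2(y/r) + \lambda_3 \sin^2(z/r)}
#' where \eqn{(x,y,z)} is the atom position in the aligned frame and
#' \eqn{r=\sqrt{x^2+y^2+z^2}} its distance from the origin. The ratios
#' \eqn{x/r, y/r, z/r} are dimensionless direction cosines in \[-1, 1\] used
#' directly as radian arguments, so every kernel term — and hence every
#' feature, the weights being a convex combination — lies in \[0, 1\].
#'
#' @param traj An aligned `rc_trajectory` (the origin is meaningful; see
#'   [align_frames()]).
#' @param weights A [kernel_weights()] triple.
#' @param r_min Guard radius: any atom closer than this to the origin raises
#'   a degenerate-position error (default `1e-6` Angstrom).
#' @return An object of class `rc_features`: list with `values`
#'   (`n_frames x n_atoms` matrix), `atoms`, `frame_ids`, `weights`.
#' @export
kernel_transform <- function(traj, weights, r_min = 1e-6) {
  if (!inherits(weights, "rc_weights")) {
    weights <- kernel_weights(weights[1], weights[2], weights[3])
  }
  nf <- n_frames(traj)
  na <- n_atoms(traj)
  x <- matrix(traj$coords[, , 1], nrow = nf, ncol = na)
  y <- matrix(traj$coords[, , 2], nrow = nf, ncol = na)
  z <- matrix(traj$coords[, , 3], nrow = nf, ncol = na)
  r <- sqrt(x^2 + y^2 + z^2)
  if (any(r < r_min)) {
    bad <- which(r < r_min, arr.ind = TRUE)[1, ]
    rc_stop(sprintf("atom %d in frame %d lies at the origin (r < %g)",
                    bad[2], bad[1], r_min),
            "rc_degenerate_position")
  }
  v <- weights[1] * cos(x / r)^2 +
       weights[2] * cos(y / r)^2 +
       weights[3] * sin(z / r)^2
  structure(list(values = v, atoms = traj$atoms,
                 frame_ids = traj$frame_ids, weights = weights),
            class = "rc_features")
}

#' 2D PCA embedding of a kernel feature matrix
#'
#' Columns (atoms) are mean-centred — not variance-scaled, since kernel
#' features already share the \[0, 1\] scale — and projected onto the top two
#' eigenvectors of the feature covariance. The sign of each loading vector
#' is fixed so that its largest-magnitude entry is positive, making the
#' embedding reproducible across runs and platforms.
#'
#' @param features An `rc_features` object, or a bare numeric matrix
#'   (`n_frames x n_atoms`).
#' @return An object of class `rc_embedding`: list with `pc1`, `pc2`
#'   (per-frame scores), `explained_variance` (top-2 covariance eigenvalues),
#'   `loadings` (`n_atoms x 2`, orthonormal), `eigenvalues` (all),
#'   `frame_ids`, `atoms`.
#' @export
pca_embed <- function(features) {
  X <- if (inherits(features, "rc_features")) features$values else as.matrix(features)
  if (nrow(X) < 3L) stop("need at least 3 frames for a 2D embedding")
  if (ncol(X) < 2L) stop("need at least 2 atoms for a 2D embedding")
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  eig <- p$sdev^2
  if (length(eig) < 2L || eig[2] <= 1e-18) {
    rc_stop("feature matrix has rank < 2 after centring", "rc_degenerate_features")
  }
  scores <- p$x[, 1:2, drop = FALSE]
  load <- p$rotation[, 1:2, drop = FALSE]
  for (j in 1:2) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(
    pc1 = scores[, 1], pc2 = scores[, 2],
    explained_variance = eig[1:2],
    loadings = load,
    eigenvalues = eig,
    frame_ids = if (inherits(features, "rc_features")) features$frame_ids
                else seq_len(nrow(X)),
    atoms = if (inherits(features, "rc_features")) features$atoms else NULL
  ), class = "rc_embedding")
}

#' @export
print.rc_embedding <- function(x, ...) {
  tot <- sum(x$eigenvalues)
  cat(sprintf("<rc_embedding> %d frames; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              length(x$pc1), 100 * x$explained_variance[1] / tot,
              100 * x$explained_variance[2] / tot))
  invisible(x)
}

#' Scatter an embedding coloured by a property
#'
#' Base-graphics convenience plot of PC1/PC2 coloured by a per-frame scalar.
#'
#' @param x An `rc_embedding`.
#' @param property Optional `rc_property` or numeric vector for colouring.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.rc_embedding <- function(x, property = NULL, ...) {
  col <- "grey30"
  if (!is.null(property)) {
    v <- property_values(property)
    pal <- grDevices::hcl.colors(64, "Viridis")
    col <- pal[cut(v, 64, labels = FALSE, include.lowest = TRUE)]
  }
  graphics::plot(x$pc1, x$pc2, col = col, pch = 16, cex = 0.5,
                 xlab = "PC1", ylab = "PC2", ...)
  invisible(x)
}
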