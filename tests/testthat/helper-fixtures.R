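# Small trajectory builders used across the suite.

# Trajectory from an explicit coordinate array and minimal metadata.
make_traj <- function(coords, atom_name, residue_index = seq_along(atom_name) - 1L,
                      residue_name = "ALA", chain_id = "A") {
  trajectory(coords, data.frame(
    atom_name = atom_name,
    residue_index = residue_index,
    residue_name = residue_name,
    chain_id = chain_id,
    stringsAsFactors = FALSE
  ))
}

# One-frame Gly-Ala dipeptide: glycine has no CB.
gly_ala_traj <- function() {
  coords <- array(0, dim = c(1, 7, 3))
  coords[1, , ] <- matrix(c(
    10.0, 0.0, 0.0,   # GLY N
    11.5, 0.2, 0.1,   # GLY CA
    12.2, 1.5, 0.0,   # GLY C
    13.5, 1.6, 0.2,   # ALA N
    14.3, 2.8, 0.3,   # ALA CA
    15.8, 2.6, 0.1,   # ALA C
    14.0, 3.9, 1.3    # ALA CB
  ), ncol = 3, byrow = TRUE)
  make_traj(coords,
            atom_name = c("N", "CA", "C", "N", "CA", "C", "CB"),
            residue_index = c(0L, 0L, 0L, 1L, 1L, 1L, 1L),
            residue_name = c(rep("GLY", 3), rep("ALA", 4)))
}

# Random trajectory with coordinates kept well away from the origin.
random_traj <- function(n_frames, n_atoms, seed = 1) {
  set.seed(seed)
  coords <- array(stats::rnorm(n_frames * n_atoms * 3, sd = 3),
                  dim = c(n_frames, n_atoms, 3))
  coords[, , 1] <- coords[, , 1] + 15
  make_traj(coords, atom_name = rep("CA", n_atoms),
            residue_index = seq_len(n_atoms) - 1L)
}

# Elementary rotation matrices for brute-force superposition oracles.
rot_z <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                            3, 3, byrow = TRUE)
rot_y <- function(a) matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)),
                            3, 3, byrow = TRUE)

# Independent scalar-loop kernel oracle.
kernel_oracle <- function(coords, w) {
  nf <- dim(coords)[1]; na <- dim(coords)[2]
  out <- matrix(0, nf, na)
  for (f in seq_len(nf)) for (a in seq_len(na)) {
    p <- coords[f, a, ]
    r <- sqrt(sum(p^2))
    out[f, a] <- w[1] * cos(p[1] / r)^2 + w[2] * cos(p[2] / r)^2 +
      w[3] * sin(p[3] / r)^2
  }
  out
}

# Independent explicit-loop correlation-ratio oracle: standardize PC1,
# quantile-bin by stable order, average, fit by closed-form OLS.
cr_oracle <- function(pc1, series, k = 5) {
  n <- length(pc1)
  pc1 <- (pc1 - mean(pc1)) / sd(pc1)
  ord <- order(pc1)
  sizes <- rep(n %/% k, k)
  if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  stops <- cumsum(sizes)
  starts <- c(1, head(stops, -1) + 1)
  means <- centers <- vars <- numeric(k)
  for (i in seq_len(k)) {
    idx <- ord[starts[i]:stops[i]]
    means[i] <- mean(series[idx])
    centers[i] <- mean(pc1[idx])
    vars[i] <- var(series[idx])
  }
  xm <- mean(centers); ym <- mean(means)
  slope <- sum((centers - xm) * (means - ym)) / sum((centers - xm)^2)
  r2 <- sum((centers - xm) * (means - ym))^2 /
    (sum((centers - xm)^2) * sum((means - ym)^2))
  if (!is.finite(r2)) r2 <- 0
  V <- mean(vars)
  list(S = abs(slope), R2 = r2, V = V,
       Cr = abs(slope) * r2 / sqrt(max(V, 1e-12)))
}
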