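#' Specification for a synthetic conformational ensemble
#'
#' Describes an ensemble of frames in which a small set of "driver"
#' residues undergo two-state polar-angle transitions that linearly
#' determine a scalar property, while all other residues move at random —
#' the statistical skeleton of an activation or folding ensemble, with a
#' known ground truth so that every pipeline stage can be validated by
#' planted-signal recovery. No physical realism (bonds, sterics, force
#' fields) is attempted.
#'
#' Defaults describe the reference validation conditions used throughout
#' the test-suite: 30 residues, 2000 frames, 3 driver residues, 0.1 rad of
#' angular noise and 0.05 units of property noise.
#'
#' @param n_residues Number of residues (each contributes a CA and a CB atom).
#' @param n_frames Number of frames (>= 10).
#' @param driver_indices 0-based indices of the driver residues.
#' @param radius_range Range (Angstrom) from which each residue's fixed
#'   distance from the origin is drawn.
#' @param theta_states Pair of polar angles (radians, in (0, pi)): driver
#'   CA angle at latent progress 0 and 1 respectively.
#' @param latent_noise_sd SD of per-driver jitter on the latent progress
#'   variable before it is mapped to an angle.
#' @param angle_noise_sd SD (radians) of angular noise added to driver angles.
#' @param property_noise_sd SD of noise on the scalar property.
#' @param property_coefficients `(intercept, slope)` mapping latent progress
#'   to the property; the default spans 8.4 to 14.1, like an
#'   activation-distance order parameter.
#' @param azimuth_jitter_sd SD (radians) of per-frame jitter on each
#'   residue's fixed azimuth.
#' @param signal_atoms `"both"` (default): the CB rides 1.5 Angstrom off its
#'   CA, so both atom types carry the planted signal. `"cb"`: only CB atoms
#'   carry the signal and driver CAs move like noise residues — the
#'   construction for studying the CB-only reduced representation against
#'   an uninformative remainder.
#' @param rotate_frames Apply a random rigid rotation to every frame
#'   (exercises the alignment stage; default `FALSE`, i.e. frames are
#'   generated pre-aligned).
#' @param seed Integer seed; everything is deterministic given it.
#' @return An object of class `rc_synthetic_spec` (a validated list).
#' @export
synthetic_spec <- function(n_residues = 30L, n_frames = 2000L,
                           driver_indices = c(4L, 14L, 24L),
                           radius_range = c(8, 20),
                           theta_states = c(0.5, 1.4),
                           latent_noise_sd = 0,
                           angle_noise_sd = 0.1,
                           property_noise_sd = 0.05,
                           property_coefficients = c(8.4, 5.7),
                           azimuth_jitter_sd = 0.05,
                           signal_atoms = c("both", "cb"),
                           rotate_frames = FALSE,
                           seed = 1L) {
  signal_atoms <- match.arg(signal_atoms)
  stopifnot(is_count(n_residues), n_residues >= 1,
            is_count(n_frames),
            all(driver_indices == round(driver_indices)),
            all(driver_indices >= 0), all(driver_indices < n_residues),
            length(radius_range) == 2L, radius_range[1] > 0,
            radius_range[1] <= radius_range[2],
            length(theta_states) == 2L,
            all(theta_states > 0), all(theta_states < pi),
            latent_noise_sd >= 0, angle_noise_sd >= 0, property_noise_sd >= 0,
            azimuth_jitter_sd >= 0,
            length(property_coefficients) == 2L,
            is_count(seed))
  if (n_frames < 10L) {
    rc_stop("need at least 10 frames for a meaningful ensemble", "rc_too_few_frames")
  }
  structure(list(n_residues = as.integer(n_residues),
                 n_frames = as.integer(n_frames),
                 driver_indices = sort(as.integer(driver_indices)),
                 radius_range = radius_range,
                 theta_states = theta_states,
                 latent_noise_sd = latent_noise_sd,
                 angle_noise_sd = angle_noise_sd,
                 property_noise_sd = property_noise_sd,
                 property_coefficients = property_coefficients,
                 azimuth_jitter_sd = azimuth_jitter_sd,
                 signal_atoms = signal_atoms,
                 rotate_frames = rotate_frames,
                 seed = as.integer(seed)),
            class = "rc_synthetic_spec")
}

# Uniformly random rotation matrix (via QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Generate a synthetic ensemble with planted reaction coordinates
#'
#' Per frame a latent progress variable `g ~ Uniform(0, 1)` is drawn. Each
#' driver residue's CA is placed at polar angle
#' `theta_states[1] + g * diff(theta_states)` plus Gaussian angular noise,
#' at a per-residue fixed radius and azimuth (the azimuth jittered a little
#' each frame); non-driver CAs get an independent uniform polar angle in
#' `(0.2, pi - 0.2)` each frame. Every residue also carries a CB atom
#' offset 1.5 Angstrom from its CA in a per-residue fixed (slightly
#' jittered) direction, so the reduced CB representation sees the same
#' signal — unless `signal_atoms = "cb"`, in which case only the CBs carry
#' the driver signal. The scalar property is
#' `intercept + slope * g + noise`. Deterministic given `spec$seed`.
#'
#' @param spec An [synthetic_spec()].
#' @return A list with elements `trajectory` (an `rc_trajectory`),
#'   `property` (an `rc_property`), and `truth` (list: `latent`,
#'   `driver_indices`, `driver_labels`, `property_coefficients`).
#' @export
generate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "rc_synthetic_spec"))
  nr <- spec$n_residues
  nf <- spec$n_frames
  drivers <- spec$driver_indices
  is_driver <- (seq_len(nr) - 1L) %in% drivers

  with_seed(spec$seed, {
    # per-residue statics
    radius <- stats::runif(nr, spec$radius_range[1], spec$radius_range[2])
    azimuth0 <- stats::runif(nr, 0, 2 * pi)
    cb_dir <- matrix(stats::rnorm(3 * nr), nr, 3)
    cb_dir <- cb_dir / sqrt(rowSums(cb_dir^2))

    # per-frame latent progress and property
    g <- stats::runif(nf)
    prop <- spec$property_coefficients[1] + spec$property_coefficients[2] * g +
      stats::rnorm(nf, 0, spec$property_noise_sd)

    th_lo <- spec$theta_states[1]
    th_span <- spec$theta_states[2] - spec$theta_states[1]
    driver_theta <- function() {
      gg <- g + if (spec$latent_noise_sd > 0)
        stats::rnorm(nf, 0, spec$latent_noise_sd) else 0
      pmin(pi - 0.05, pmax(0.05,
        th_lo + gg * th_span + stats::rnorm(nf, 0, spec$angle_noise_sd)))
    }
    noise_theta <- function() stats::runif(nf, 0.2, pi - 0.2)

    coords <- array(0, dim = c(nf, 2L * nr, 3L))
    for (i in seq_len(nr)) {
      ca_signal <- is_driver[i] && spec$signal_atoms == "both"
      cb_signal <- is_driver[i]
      theta_sig <- if (is_driver[i]) driver_theta() else NULL
      theta_ca <- if (ca_signal) theta_sig else noise_theta()
      phi <- azimuth0[i] + stats::rnorm(nf, 0, spec$azimuth_jitter_sd)
      ca <- cbind(radius[i] * sin(theta_ca) * cos(phi),
                  radius[i] * sin(theta_ca) * sin(phi),
                  radius[i] * cos(theta_ca))
      if (spec$signal_atoms == "cb" && is_driver[i]) {
        # CB independently placed at the signal angle; CA stays noise
        phi_cb <- azimuth0[i] + stats::rnorm(nf, 0, spec$azimuth_jitter_sd)
        cb <- cbind(radius[i] * sin(theta_sig) * cos(phi_cb),
                    radius[i] * sin(theta_sig) * sin(phi_cb),
                    radius[i] * cos(theta_sig))
      } else {
        d <- matrix(rep(cb_dir[i, ], each = nf), nf, 3) +
          matrix(stats::rnorm(3 * nf, 0, 0.05), nf, 3)
        d <- d / sqrt(rowSums(d^2))
        cb <- ca + 1.5 * d
      }
      coords[, 2L * i - 1L, ] <- ca
      coords[, 2L * i, ] <- cb
    }
    if (spec$rotate_frames) {
      for (f in seq_len(nf)) {
        R <- random_rotation()
        coords[f, , ] <- coords[f, , ] %*% t(R)
      }
    }

    atoms <- data.frame(
      atom_name = rep(c("CA", "CB"), nr),
      residue_index = rep(seq_len(nr) - 1L, each = 2L),
      residue_name = "ALA",
      chain_id = "A",
      author_resno = rep(seq_len(nr), each = 2L),
      stringsAsFactors = FALSE
    )
    traj <- trajectory(coords, atoms)
    list(trajectory = traj,
         property = property_series(prop, name = "planted_property",
                                    units = "angstrom"),
         truth = list(latent = g,
                      driver_indices = drivers,
                      driver_labels = unique(
                        traj$atoms$residue_label[traj$atoms$residue_index %in% drivers]),
                      property_coefficients = spec$property_coefficients))
  })
}

#' Write the canonical synthetic fixture file set
#'
#' Writes `model.pdb` (multi-model PDB), `property.csv` (frame_id, value)
#' and `truth.json` (latent variable, driver indices, coefficients) into a
#' directory.
#'
#' @param ensemble Result of [generate_ensemble()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(pdb = file.path(dir, "model.pdb"),
             property = file.path(dir, "property.csv"),
             truth = file.path(dir, "truth.json"))
  write_trajectory_pdb(ensemble$trajectory, paths["pdb"])
  write_property_csv(ensemble$property, paths["property"],
                     frame_ids = ensemble$trajectory$frame_ids)
  writeLines(jsonlite::toJSON(ensemble$truth, auto_unbox = TRUE, digits = NA),
             paths["truth"])
  invisible(paths)
}
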