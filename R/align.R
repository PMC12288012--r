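#' Rigid-body superposition of all frames onto a reference
#'
#' Each frame is superposed onto the reference by the optimal least-squares
#' rotation and translation (Kabsch) computed on the backbone subset and
#' applied to all atoms. With `recentre = TRUE` (the default) the reference
#' is first translated so that its backbone centroid sits at the origin;
#' that origin is the one used by the angular kernel and the per-residue
#' polar angles downstream, which makes those features invariant to how the
#' input happened to be positioned.
#'
#' @param traj An `rc_trajectory`.
#' @param reference A one-frame `rc_trajectory` sharing the atom ordering of
#'   `traj`, or a frame position into `traj` (default: first frame).
#' @param backbone Atom names used for the fit (default `c("N","CA","C")`);
#'   the transform is applied to every atom.
#' @param recentre Move the reference backbone centroid to the origin first.
#' @return The aligned `rc_trajectory`.
#' @export
align_frames <- function(traj, reference = 1L, backbone = c("N", "CA", "C"),
                         recentre = TRUE) {
  if (is.numeric(reference)) reference <- get_frame(traj, reference)
  stopifnot(inherits(reference, "rc_trajectory"), n_frames(reference) == 1L)
  if (!all(reference$atoms$atom_name == traj$atoms$atom_name)) {
    rc_stop("reference does not share the trajectory's atom ordering",
            "rc_structural_inconsistency")
  }
  bb <- which(traj$atoms$atom_name %in% backbone)
  if (length(bb) < 3L) {
    rc_stop("fewer than 3 backbone atoms; superposition is underdetermined",
            "rc_underdetermined_superposition")
  }
  ref <- reference$coords[1, , ]
  if (recentre) ref <- sweep(ref, 2L, colMeans(ref[bb, , drop = FALSE]))
  fixed <- as.vector(t(ref))
  mobile <- matrix(as.vector(aperm(traj$coords, c(3L, 2L, 1L))),
                   nrow = n_frames(traj), byrow = TRUE)
  inds <- bio3d::atom2xyz(bb)
  fitted <- bio3d::fit.xyz(fixed, mobile, fixed.inds = inds, mobile.inds = inds)
  if (is.null(dim(fitted))) fitted <- matrix(fitted, nrow = 1L)
  coords <- aperm(array(t(fitted), dim = c(3L, n_atoms(traj), n_frames(traj))),
                  c(3L, 2L, 1L))
  trajectory(coords, traj$atoms, frame_ids = traj$frame_ids)
}

#' Construct a per-frame scalar property series
#'
#' @param values Numeric vector, one value per frame; must be finite.
#' @param name Short name, e.g. `"rmsd"` or `"h3h6_distance"`.
#' @param units Unit string, e.g. `"angstrom"`.
#' @return An object of class `rc_property`.
#' @export
property_series <- function(values, name = "property", units = "") {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("property values must be finite")
  structure(list(values = values, name = name, units = units),
            class = "rc_property")
}

#' @export
print.rc_property <- function(x, ...) {
  cat(sprintf("<rc_property> %s [%s], %d frames, range %.3g..%.3g\n",
              x$name, x$units, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

# Accept either an rc_property or a bare numeric vector.
property_values <- function(property) {
  if (inherits(property, "rc_property")) property$values else as.numeric(property)
}

#' Per-frame RMSD to a reference structure
#'
#' Root-mean-square deviation of the selected atoms from the reference,
#' measured in the shared coordinate frame: this function does not superpose
#' (align once with [align_frames()] first, so properties and angular
#' features live in one frame).
#'
#' @param traj An aligned `rc_trajectory`.
#' @param reference One-frame `rc_trajectory` or frame position (default 1).
#' @param atom_names Optional atom-name filter; `NULL` uses every atom.
#' @return An `rc_property` named `"rmsd"` in Angstrom.
#' @export
compute_rmsd <- function(traj, reference = 1L, atom_names = NULL) {
  if (is.numeric(reference)) reference <- get_frame(traj, reference)
  stopifnot(inherits(reference, "rc_trajectory"), n_frames(reference) == 1L)
  sel <- seq_len(n_atoms(traj))
  if (!is.null(atom_names)) {
    sel <- which(traj$atoms$atom_name %in% atom_names)
    if (length(sel) == 0L) {
      rc_stop("RMSD atom selection matches nothing", "rc_empty_selection")
    }
  }
  d2 <- 0
  for (k in 1:3) {
    m <- matrix(traj$coords[, sel, k], ncol = length(sel))
    d2 <- d2 + sweep(m, 2L, reference$coords[1, sel, k])^2
  }
  property_series(sqrt(rowMeans(d2)), name = "rmsd", units = "angstrom")
}

#' Per-frame distance between two named atoms
#'
#' Euclidean distance between `atom_name` of `residue_a` and of `residue_b`
#' in every frame — e.g. the Calpha contact distance between the helix-3 and
#' helix-6 residues (R131, L272) used as the activation order parameter of
#' the beta-2 adrenergic receptor.
#'
#' @param traj An `rc_trajectory`.
#' @param residue_a,residue_b Residue selectors: an internal 0-based index,
#'   `"131"`/`"R131"` (author numbering), or `"A:131"` (chain-qualified).
#' @param atom_name Atom to measure between (default `"CA"`).
#' @return An `rc_property` in Angstrom.
#' @export
compute_pair_distance <- function(traj, residue_a, residue_b, atom_name = "CA") {
  ia <- resolve_residue(traj, residue_a)
  ib <- resolve_residue(traj, residue_b)
  row_of <- function(ridx, sel) {
    hit <- which(traj$atoms$residue_index == ridx & traj$atoms$atom_name == atom_name)
    if (length(hit) == 0L) {
      rc_stop(paste0("residue selector '", sel, "' has no atom ", atom_name),
              "rc_selector_resolution")
    }
    hit[1]
  }
  a <- row_of(ia, residue_a)
  b <- row_of(ib, residue_b)
  A <- matrix(traj$coords[, a, ], ncol = 3L)
  B <- matrix(traj$coords[, b, ], ncol = 3L)
  d <- sqrt(rowSums((A - B)^2))
  la <- traj$atoms$residue_label[a]
  lb <- traj$atoms$residue_label[b]
  property_series(d, name = paste(atom_name, la, lb, sep = "_"),
                  units = "angstrom")
}

#' Write / read a property series as CSV
#'
#' Two columns, `frame_id` and `value`.
#'
#' @param property An `rc_property`.
#' @param file Path.
#' @param frame_ids Optional frame identifiers (default sequential).
#' @return `file` invisibly; `read_property_csv` returns an `rc_property`.
#' @export
write_property_csv <- function(property, file, frame_ids = NULL) {
  v <- property_values(property)
  if (is.null(frame_ids)) frame_ids <- seq_along(v)
  utils::write.csv(data.frame(frame_id = frame_ids, value = v),
                   file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_property_csv
#' @param name,units Metadata for the series read back.
#' @export
read_property_csv <- function(file, name = "property", units = "") {
  df <- utils::read.csv(file)
  stopifnot(all(c("frame_id", "value") %in% names(df)))
  property_series(df$value, name = name, units = units)
}
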