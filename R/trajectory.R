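#' Construct a trajectory object
#'
#' A trajectory is a multi-frame coordinate ensemble with per-atom metadata.
#' Every frame shares the same atoms in the same order; coordinates are in
#' Angstrom in a common (ideally aligned) frame of reference.
#'
#' @param coords Numeric array of dimension `n_frames x n_atoms x 3` (Angstrom).
#'   A single frame may be given as an `n_atoms x 3` matrix.
#' @param atoms Data frame with one row per atom and columns `atom_name`
#'   (PDB atom name, e.g. `"CA"`), `residue_index` (0-based sequential residue
#'   number used internally), `residue_name` (three-letter code), `chain_id`,
#'   and `author_resno` (the residue number from the source file, kept for
#'   reporting). A `residue_label` column (e.g. `"R131"`) is derived if absent.
#' @param frame_ids Integer identifiers for frames; defaults to `1:n_frames`.
#'
#' @return An object of class `rc_trajectory`: a list with elements `coords`,
#'   `atoms` and `frame_ids`.
#' @seealso [read_structures()], [select_atoms()], [align_frames()]
#' @export
trajectory <- function(coords, atoms, frame_ids = NULL) {
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1L, nrow(coords), ncol(coords)))
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (dim(coords)[1] < 1L) rc_stop("trajectory has zero frames", "rc_empty_input")
  if (dim(coords)[2] < 1L) rc_stop("trajectory has zero atoms", "rc_empty_input")
  if (any(!is.finite(coords))) {
    rc_stop("non-finite coordinates in trajectory", "rc_structural_inconsistency")
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("atom_name", "residue_index", "residue_name", "chain_id")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) != dim(coords)[2]) {
    rc_stop("atoms table does not match coordinate array", "rc_structural_inconsistency")
  }
  if (any(!nzchar(atoms$atom_name))) stop("empty atom_name in atoms table")
  if (any(atoms$residue_index < 0)) stop("residue_index must be >= 0")
  if (is.null(atoms$author_resno)) atoms$author_resno <- atoms$residue_index + 1L
  if (is.null(atoms$residue_label)) {
    atoms$residue_label <- paste0(residue_one_letter(atoms$residue_name),
                                  atoms$author_resno)
  }
  if (is.null(frame_ids)) frame_ids <- seq_len(dim(coords)[1])
  stopifnot(length(frame_ids) == dim(coords)[1])
  structure(list(coords = coords, atoms = atoms,
                 frame_ids = as.integer(frame_ids)),
            class = "rc_trajectory")
}

#' Number of frames / atoms in a trajectory
#' @param traj An `rc_trajectory`.
#' @return Integer count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$coords)[2]

#' @export
print.rc_trajectory <- function(x, ...) {
  cat(sprintf("<rc_trajectory> %d frames x %d atoms, %d residues\n",
              n_frames(x), n_atoms(x), length(unique(x$atoms$residue_index))))
  invisible(x)
}

#' Extract a single frame as a one-frame trajectory
#'
#' @param traj An `rc_trajectory`.
#' @param frame Frame position (1-based).
#' @return A one-frame `rc_trajectory`, typically used as an alignment or
#'   RMSD reference.
#' @export
get_frame <- function(traj, frame) {
  stopifnot(is_count(frame), frame >= 1, frame <= n_frames(traj))
  trajectory(traj$coords[frame, , , drop = FALSE], traj$atoms,
             frame_ids = traj$frame_ids[frame])
}

#' Read multi-frame structures into a trajectory
#'
#' Reads one or more multi-model PDB files (standard `ATOM`/`MODEL`/`ENDMDL`
#' records) or a topology PDB plus a DCD coordinate trajectory. All models
#' must share atom count and ordering. Residues are renumbered to a
#' contiguous 0-based internal scheme (insertion codes folded in); the
#' author numbering is kept in the `author_resno` column for reporting.
#' Only the first alternate location of each atom is kept.
#'
#' @param paths Character vector of file paths. For
#'   `format = "topology+trajectory"` supply `c(topology.pdb, coords.dcd)`.
#' @param format `"pdb"` (multi-model PDB, frames concatenated over files,
#'   the guaranteed path) or `"topology+trajectory"` (requires a DCD file).
#' @return An [trajectory()] object with frames in file order.
#' @export
read_structures <- function(paths, format = c("pdb", "topology+trajectory")) {
  format <- match.arg(format)
  stopifnot(length(paths) >= 1L, all(file.exists(paths)))
  if (format == "topology+trajectory") {
    stopifnot(length(paths) == 2L)
    top <- bio3d::read.pdb(paths[1], multi = FALSE, rm.alt = TRUE, verbose = FALSE)
    if (!grepl("\\.dcd$", paths[2], ignore.case = TRUE)) {
      stop("only DCD coordinate trajectories are supported alongside a topology PDB")
    }
    xyz <- bio3d::read.dcd(paths[2], verbose = FALSE)
    if (ncol(xyz) != length(top$xyz)) {
      rc_stop(sprintf("trajectory atom count (%d) does not match topology (%d)",
                      ncol(xyz) / 3, length(top$xyz) / 3),
              "rc_structural_inconsistency")
    }
    return(pdb_to_trajectory(top$atom, xyz))
  }
  atom_ref <- NULL
  xyz_all <- NULL
  for (p in paths) {
    pdb <- tryCatch(
      bio3d::read.pdb(p, multi = TRUE, rm.alt = TRUE, verbose = FALSE),
      error = function(e) rc_stop(paste0("cannot parse ", p, ": ", conditionMessage(e)),
                                  "rc_empty_input"))
    atom <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
    if (nrow(atom) == 0L) rc_stop(paste0("no atoms in ", p), "rc_empty_input")
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
    if (is.null(atom_ref)) {
      atom_ref <- atom
    } else if (nrow(atom) != nrow(atom_ref) ||
               !all(atom$elety == atom_ref$elety) ||
               !all(atom$resno == atom_ref$resno)) {
      rc_stop(paste0("atom records in ", p,
                     " are inconsistent with the first file"),
              "rc_structural_inconsistency")
    }
    if (ncol(xyz) != 3L * nrow(atom_ref)) {
      rc_stop(paste0("model in ", p, " has an inconsistent atom count"),
              "rc_structural_inconsistency")
    }
    xyz_all <- rbind(xyz_all, xyz)
  }
  pdb_to_trajectory(atom_ref, xyz_all)
}

# Convert a bio3d atom table + xyz matrix (frames x 3*atoms) to rc_trajectory.
pdb_to_trajectory <- function(atom, xyz) {
  nf <- nrow(xyz)
  na <- nrow(atom)
  coords <- aperm(array(t(xyz), dim = c(3L, na, nf)), c(3L, 2L, 1L))
  ins <- if (!is.null(atom$insert)) ifelse(is.na(atom$insert), "", atom$insert) else ""
  key <- paste(atom$chain, atom$resno, ins, sep = "|")
  ridx <- match(key, unique(key)) - 1L
  atoms <- data.frame(
    atom_name = atom$elety,
    residue_index = ridx,
    residue_name = atom$resid,
    chain_id = ifelse(is.na(atom$chain), "", atom$chain),
    author_resno = atom$resno,
    stringsAsFactors = FALSE
  )
  trajectory(coords, atoms)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Coordinates are written in the fixed-width PDB format (three decimals,
#' i.e. a 5e-4 Angstrom quantum per axis), one `MODEL` per frame.
#'
#' @param traj An `rc_trajectory`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, file) {
  xyz <- matrix(as.vector(aperm(traj$coords, c(3L, 2L, 1L))),
                nrow = n_frames(traj), byrow = TRUE)
  bio3d::write.pdb(file = file, xyz = xyz,
                   resno = traj$atoms$author_resno,
                   resid = traj$atoms$residue_name,
                   elety = traj$atoms$atom_name,
                   chain = traj$atoms$chain_id)
  invisible(file)
}

#' Select atoms by PDB atom name
#'
#' Returns the sub-trajectory of atoms whose name is in `atom_names`,
#' preserving frame and atom order and all residue metadata. Typical use is
#' `select_atoms(traj, "CB")` for the reduced beta-carbon representation
#' (glycine, which has no CB, simply drops out).
#'
#' @param traj An `rc_trajectory`.
#' @param atom_names Character vector of atom names, e.g. `c("N","CA","C")`.
#' @return An `rc_trajectory`.
#' @export
select_atoms <- function(traj, atom_names) {
  stopifnot(is.character(atom_names), length(atom_names) >= 1L)
  keep <- traj$atoms$atom_name %in% atom_names
  if (!any(keep)) {
    rc_stop(paste0("no atoms match selection {",
                   paste(atom_names, collapse = ","), "}"),
            "rc_empty_selection")
  }
  trajectory(traj$coords[, keep, , drop = FALSE],
             traj$atoms[keep, , drop = FALSE],
             frame_ids = traj$frame_ids)
}

#' Randomly sample frames without replacement
#'
#' Uniform sampling without replacement, deterministic given `seed`;
#' sampled frames are returned in ascending original order. The caller's
#' RNG state is left untouched.
#'
#' @param traj An `rc_trajectory`.
#' @param n Number of frames to keep (`1 <= n <= n_frames`).
#' @param seed Integer seed.
#' @return An `rc_trajectory` with `n` frames.
#' @export
sample_frames <- function(traj, n, seed) {
  stopifnot(is_count(n), n >= 1)
  if (n > n_frames(traj)) {
    rc_stop(sprintf("requested %d frames but trajectory has %d", n, n_frames(traj)),
            "rc_request_exceeds_supply")
  }
  idx <- sort(with_seed(seed, sample.int(n_frames(traj), n)))
  trajectory(traj$coords[idx, , , drop = FALSE], traj$atoms,
             frame_ids = traj$frame_ids[idx])
}

# Resolve a residue selector to the internal 0-based residue index.
# Accepted forms: an integer (internal index); "131" or "R131" (author
# numbering, optional one-letter or three-letter residue-name prefix);
# "A:131" (chain-qualified author numbering).
resolve_residue <- function(traj, sel) {
  at <- traj$atoms
  if (is.numeric(sel)) {
    if (!sel %in% at$residue_index) {
      rc_stop(paste0("no residue with internal index ", sel), "rc_selector_resolution")
    }
    return(as.integer(sel))
  }
  stopifnot(is.character(sel), length(sel) == 1L)
  chain <- NA_character_
  body <- sel
  if (grepl(":", sel, fixed = TRUE)) {
    parts <- strsplit(sel, ":", fixed = TRUE)[[1]]
    chain <- parts[1]
    body <- parts[2]
  }
  resno <- suppressWarnings(as.integer(gsub("^[A-Za-z]+", "", body)))
  if (is.na(resno)) {
    rc_stop(paste0("cannot parse residue selector '", sel, "'"), "rc_selector_resolution")
  }
  hit <- at$author_resno == resno
  if (!is.na(chain)) hit <- hit & at$chain_id == chain
  idx <- unique(at$residue_index[hit])
  if (length(idx) == 0L) {
    rc_stop(paste0("residue selector '", sel, "' matches nothing"),
            "rc_selector_resolution")
  }
  if (length(idx) > 1L) {
    rc_stop(paste0("residue selector '", sel, "' is ambiguous (",
                   length(idx), " residues); qualify with 'chain:resno'"),
            "rc_selector_resolution")
  }
  idx
}
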