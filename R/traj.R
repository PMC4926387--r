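# Trajectory analysis: contact persistence against the 4-A cutoff, RMSD
# with least-squares superposition, per-residue RMSF. Trajectories are
# multi-model PDB (exported snapshots); the dynamics engine that produced
# them is out of scope.

#' Construct a trajectory from frames
#'
#' @param frames list of structures with identical atom sets.
#' @param frame_interval frame spacing in ps (metadata; default NA).
#' @return object of class `xd_trajectory`.
#' @export
new_trajectory <- function(frames, frame_interval = NA_real_) {
  stopifnot(length(frames) >= 1, all(vapply(frames, is_structure, TRUE)))
  n0 <- nrow(frames[[1]]$atoms)
  k0 <- residue_keys(frames[[1]], unique_only = FALSE)
  for (f in frames[-1]) {
    if (nrow(f$atoms) != n0 ||
        !identical(residue_keys(f, unique_only = FALSE), k0)) {
      stop("all frames must share the same atoms and residue keys", call. = FALSE)
    }
  }
  structure(list(frames = frames, frame_interval = frame_interval),
            class = "xd_trajectory")
}

#' Read a multi-model PDB as a trajectory
#' @param text PDB content or file path.
#' @param frame_interval frame spacing in ps (metadata).
#' @return `xd_trajectory`.
#' @export
read_trajectory <- function(text, frame_interval = NA_real_) {
  new_trajectory(read_pdb(text), frame_interval)
}

#' @export
print.xd_trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d frame(s), %d atoms%s>\n",
              length(x$frames), nrow(x$frames[[1]]$atoms),
              if (is.na(x$frame_interval)) "" else
                sprintf(", %g ps/frame", x$frame_interval)))
  invisible(x)
}

# Resolve an atom selection within a frame: a predicate on the atom
# data.frame, a character vector of residue keys, or a single residue name.
resolve_selection <- function(frame, sel, label) {
  idx <- if (is.function(sel)) {
    which(sel(frame$atoms))
  } else if (is.character(sel) && all(grepl(":", sel))) {
    which(residue_keys(frame, unique_only = FALSE) %in% sel)
  } else if (is.character(sel)) {
    which(frame$atoms$res_name %in% sel)
  } else if (is.numeric(sel)) {
    as.integer(sel)
  } else {
    stop("unsupported selection for ", label, call. = FALSE)
  }
  idx <- idx[frame$atoms$is_heavy[idx]]
  if (length(idx) == 0L) {
    stop(sprintf("selection '%s' matches no heavy atoms", label), call. = FALSE)
  }
  idx
}

#' Per-frame minimum distance between a residue group and a ligand selection
#'
#' @param traj trajectory.
#' @param residues residue keys (or a selection) defining the protein group.
#' @param ligand_sel selection for the ligand group (residue name,
#'   residue keys, predicate function or atom indices).
#' @return object of class `xd_distance_series`: list with `values`
#'   (per-frame minimum heavy-atom distance, Angstrom) and the labels.
#' @export
min_distance_series <- function(traj, residues, ligand_sel) {
  values <- vapply(traj$frames, function(fr) {
    ri <- resolve_selection(fr, residues, "residues")
    li <- resolve_selection(fr, ligand_sel, "ligand")
    min(cross_dist(atom_coords(fr)[ri, , drop = FALSE],
                   atom_coords(fr)[li, , drop = FALSE]))
  }, 0)
  structure(list(values = values,
                 residues = residues, ligand = ligand_sel),
            class = "xd_distance_series")
}

#' Fraction of frames in which a contact is maintained
#'
#' Fraction of frames whose minimum distance is at or below `cutoff`
#' (closed boundary); 1.0 means the contact is maintained throughout the
#' trajectory.
#'
#' @param series `xd_distance_series` (or a bare numeric vector).
#' @param cutoff contact cutoff in Angstrom (default 4.0).
#' @return fraction in [0, 1].
#' @export
contact_persistence <- function(series, cutoff = 4.0) {
  v <- if (inherits(series, "xd_distance_series")) series$values else series
  if (length(v) == 0L) stop("empty distance series", call. = FALSE)
  mean(v <= cutoff + 1e-12)
}

#' Per-frame RMSD against a reference after superposition
#'
#' Each frame's selected atoms are superposed onto the reference selection
#' by the least-squares rigid fit (proper rotation only) before the RMSD
#' is computed.
#'
#' @param traj trajectory.
#' @param reference reference structure (defaults to the first frame).
#' @param selection atom selection (default: C-alpha atoms; see
#'   [min_distance_series()] for accepted forms).
#' @return numeric vector of per-frame RMSDs (Angstrom).
#' @export
rmsd_series <- function(traj, reference = traj$frames[[1]],
                        selection = function(a) a$name == "CA") {
  ref_idx <- resolve_selection(reference, selection, "selection")
  ref <- atom_coords(reference)[ref_idx, , drop = FALSE]
  ref_c <- sweep(ref, 2, colMeans(ref))
  vapply(traj$frames, function(fr) {
    idx <- resolve_selection(fr, selection, "selection")
    if (length(idx) != length(ref_idx)) {
      stop("selection does not match the reference atoms", call. = FALSE)
    }
    x <- atom_coords(fr)[idx, , drop = FALSE]
    xc <- sweep(x, 2, colMeans(x))
    rot <- kabsch_rotation(ref_c, xc)
    sqrt(mean(rowSums((xc %*% rot - ref_c)^2)))
  }, 0)
}

#' Per-residue root-mean-square fluctuation
#'
#' For each selected residue, the root-mean-square deviation of its
#' C-alpha position around its trajectory-mean position (no superposition;
#' feed pre-aligned frames for internal fluctuations).
#'
#' @param traj trajectory.
#' @param selection residue filter applied to C-alpha atoms (default all).
#' @return named numeric vector (residue key -> RMSF, Angstrom).
#' @export
rmsf <- function(traj, selection = NULL) {
  fr1 <- traj$frames[[1]]
  ca <- which(fr1$atoms$name == "CA")
  if (!is.null(selection)) {
    keep <- resolve_selection(fr1, selection, "selection")
    ca <- intersect(ca, keep)
  }
  if (length(ca) == 0L) stop("no C-alpha atoms selected", call. = FALSE)
  keys <- residue_keys(fr1, unique_only = FALSE)[ca]
  xs <- lapply(traj$frames, function(fr) atom_coords(fr)[ca, , drop = FALSE])
  arr <- simplify2array(xs)                  # atoms x 3 x frames
  mean_pos <- apply(arr, c(1, 2), mean)
  dev2 <- vapply(seq_along(xs), function(t) rowSums((xs[[t]] - mean_pos)^2),
                 numeric(length(ca)))
  out <- sqrt(rowMeans(matrix(dev2, nrow = length(ca))))
  names(out) <- keys
  out
}
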