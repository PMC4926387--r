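# Blind rigid-body protein-protein docking.
#
# The receptor is represented by a probe-potential grid: at every lattice
# node the softened Lennard-Jones potential (plus a screened-Coulomb field)
# summed over receptor heavy atoms. For each orientation of the ligand
# protein, lattice translations of the ligand centroid are scanned by
# summing the grid field at the (nearest-node) ligand atom positions; the
# best candidates are then re-scored exactly with pairwise sums and locally
# refined by coordinate descent in translation and orientation.

#' Rigid-docking configuration
#'
#' @param n_orientations size of the quasi-uniform orientation set
#'   (default 60, the icosahedral rotation group).
#' @param grid_spacing translation lattice spacing in Angstrom (default 1).
#' @param n_keep number of solutions recorded (default 100).
#' @param cluster_threshold ligand C-alpha RMSD threshold (A) for greedy
#'   clustering of solutions (default 3).
#' @param n_report_clusters clusters whose leaders are reported (default 10).
#' @param electrostatic_weight small weight on the screened Coulomb term in
#'   the final score (default 0.1).
#' @param lj softened Lennard-Jones parameters ([soft_lj_params()]).
#' @param pair_cutoff pairwise interaction cutoff in Angstrom (default 8).
#' @param margin margin (A) added around the receptor bounding box for the
#'   translation scan (default 10).
#' @param refine logical, run local coordinate-descent refinement.
#' @return list of class `xd_rigid_config`.
#' @export
rigid_dock_config <- function(n_orientations = 60L, grid_spacing = 1.0,
                              n_keep = 100L, cluster_threshold = 3.0,
                              n_report_clusters = 10L,
                              electrostatic_weight = 0.1,
                              lj = soft_lj_params(), pair_cutoff = 8.0,
                              margin = 10.0, refine = TRUE) {
  stopifnot(n_orientations >= 1, grid_spacing > 0, n_keep >= 1,
            cluster_threshold > 0, n_report_clusters >= 1,
            electrostatic_weight >= 0, pair_cutoff > 0, margin >= 0)
  structure(list(n_orientations = as.integer(n_orientations),
                 grid_spacing = grid_spacing, n_keep = as.integer(n_keep),
                 cluster_threshold = cluster_threshold,
                 n_report_clusters = as.integer(n_report_clusters),
                 electrostatic_weight = electrostatic_weight, lj = lj,
                 pair_cutoff = pair_cutoff, margin = margin,
                 refine = isTRUE(refine)),
            class = "xd_rigid_config")
}

rigid_ctx <- function(s) {
  types <- assign_atom_types(s)
  heavy <- s$atoms$is_heavy
  list(coords = atom_coords(s)[heavy, , drop = FALSE],
       charge = types$charge[heavy])
}

# Exact pairwise score for placed coordinates.
rigid_score_xyz <- function(rec, lig_xyz, lig_charge, cfg) {
  d2 <- cross_dist2(lig_xyz, rec$coords)
  cut2 <- cfg$pair_cutoff^2
  pair <- which(d2 <= cut2)
  if (length(pair) == 0L) return(0)
  r <- sqrt(d2[pair])
  e <- sum(soft_lj(r, cfg$lj))
  if (cfg$electrostatic_weight > 0) {
    li <- (pair - 1L) %% nrow(lig_xyz) + 1L
    ti <- (pair - 1L) %/% nrow(lig_xyz) + 1L
    qprod <- lig_charge[li] * rec$charge[ti]
    el <- qprod != 0
    if (any(el)) {
      # same short-range clamp as the receptor field grid
      re <- pmax(r[el], 0.5)
      e <- e + cfg$electrostatic_weight *
        sum(332.0636 * qprod[el] / (4 * re^2))
    }
  }
  e
}

#' Rigid protein-protein interaction score
#'
#' Sum of the softened Lennard-Jones potential over intermolecular
#' heavy-atom pairs within the pair cutoff, plus a small-weighted screened
#' Coulomb term over charged pairs.
#'
#' @param receptor,ligand structures placed in a common frame.
#' @param cfg configuration from [rigid_dock_config()].
#' @return energy (score units).
#' @export
rigid_score <- function(receptor, ligand, cfg = rigid_dock_config()) {
  rec <- rigid_ctx(receptor)
  lig <- rigid_ctx(ligand)
  rigid_score_xyz(rec, lig$coords, lig$charge, cfg)
}

# Potential grids over the receptor box: soft-LJ field and (optionally)
# the screened-Coulomb field per unit probe charge.
receptor_grids <- function(rec, box, cfg) {
  h <- cfg$grid_spacing
  gx <- seq(box$min[1], box$max[1] + h / 2, by = h)
  gy <- seq(box$min[2], box$max[2] + h / 2, by = h)
  gz <- seq(box$min[3], box$max[3] + h / 2, by = h)
  nx <- length(gx); ny <- length(gy); nz <- length(gz)
  vlj <- array(0, c(nx, ny, nz))
  vel <- if (cfg$electrostatic_weight > 0) array(0, c(nx, ny, nz)) else NULL
  cut <- cfg$pair_cutoff
  for (a in seq_len(nrow(rec$coords))) {
    p <- rec$coords[a, ]
    ix <- which(abs(gx - p[1]) <= cut)
    iy <- which(abs(gy - p[2]) <= cut)
    iz <- which(abs(gz - p[3]) <= cut)
    if (!length(ix) || !length(iy) || !length(iz)) next
    d2 <- outer(outer((gx[ix] - p[1])^2, (gy[iy] - p[2])^2, "+"),
                (gz[iz] - p[3])^2, "+")
    r <- sqrt(d2)
    m <- r <= cut
    add <- array(0, dim(r))
    if (cfg$lj$alpha == 0 && any(m & r == 0)) {
      # standard 12-6 LJ diverges on a node exactly on the atom: mark as a
      # hard clash in the coarse field
      add[m & r == 0] <- 1e9
      m <- m & r > 0
    }
    add[m] <- soft_lj(r[m], cfg$lj)
    vlj[ix, iy, iz] <- vlj[ix, iy, iz] + add
    if (!is.null(vel) && rec$charge[a] != 0) {
      adde <- array(0, dim(r))
      rc <- pmax(r[m], 0.5)  # clamp the field inside the clash core
      adde[m] <- 332.0636 * rec$charge[a] / (4 * rc^2)
      vel[ix, iy, iz] <- vel[ix, iy, iz] + adde
    }
  }
  list(gx = gx, gy = gy, gz = gz, vlj = vlj, vel = vel)
}

pad_grid <- function(v, lo, hi) {
  d <- dim(v)
  p <- array(0, d + lo + hi)
  p[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3])] <- v
  p
}

#' Blind rigid-body docking of two structures
#'
#' Scans every orientation of the quasi-uniform set against all ligand
#' centroid translations on a lattice covering the receptor bounding box
#' plus a margin, using the receptor probe-potential grid for the coarse
#' energies; the best candidates are exact-scored with [rigid_score()] and
#' refined by coordinate descent (translation steps halving from the grid
#' spacing to spacing/8, orientation steps halving from 10 to 1.25
#' degrees). Solutions are returned sorted ascending by energy, with ties
#' broken towards lower orientation index then lexicographic translation,
#' and clustered with [cluster_solutions()].
#'
#' @param receptor,ligand structures (heavy atoms are used).
#' @param cfg configuration from [rigid_dock_config()].
#' @return object of class `xd_rigid_result`: list with `solutions` (each
#'   holding `rotation`, `translation`, `energy`, `rank`, `cluster_id`),
#'   `summary` data.frame, `ligand`, `receptor`, `cfg`.
#' @export
rigid_dock <- function(receptor, ligand, cfg = rigid_dock_config()) {
  if (!is_structure(receptor) || !is_structure(ligand)) {
    stop("receptor and ligand must be structures", call. = FALSE)
  }
  rec <- rigid_ctx(receptor)
  lig <- rigid_ctx(ligand)
  if (nrow(rec$coords) == 0L || nrow(lig$coords) == 0L) {
    stop("empty structure", call. = FALSE)
  }
  box <- structure_bbox(receptor, margin = cfg$margin)
  grids <- receptor_grids(rec, box, cfg)
  h <- cfg$grid_spacing
  rots <- orientation_set(cfg$n_orientations)
  ctr <- colMeans(lig$coords)
  offsets0 <- sweep(lig$coords, 2, ctr)
  nx <- length(grids$gx); ny <- length(grids$gy); nz <- length(grids$gz)

  cand <- list()
  for (oi in seq_along(rots)) {
    off <- offsets0 %*% t(rots[[oi]])
    k <- round(off / h)
    lo <- pmax(0, -apply(k, 2, min))
    hi <- pmax(0, apply(k, 2, max))
    plj <- pad_grid(grids$vlj, lo, hi)
    pel <- if (!is.null(grids$vel)) pad_grid(grids$vel, lo, hi) else NULL
    e <- array(0, c(nx, ny, nz))
    for (a in seq_len(nrow(k))) {
      sl <- plj[lo[1] + k[a, 1] + seq_len(nx),
                lo[2] + k[a, 2] + seq_len(ny),
                lo[3] + k[a, 3] + seq_len(nz)]
      e <- e + sl
      if (!is.null(pel) && lig$charge[a] != 0) {
        sle <- pel[lo[1] + k[a, 1] + seq_len(nx),
                   lo[2] + k[a, 2] + seq_len(ny),
                   lo[3] + k[a, 3] + seq_len(nz)]
        e <- e + cfg$electrostatic_weight * lig$charge[a] * sle
      }
    }
    top <- order(e)[seq_len(min(cfg$n_keep, length(e)))]
    ijk <- arrayInd(top, dim(e))
    cand[[oi]] <- data.frame(orient = oi, e_approx = e[top],
                             ix = ijk[, 1], iy = ijk[, 2], iz = ijk[, 3])
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$e_approx, cand$orient, cand$ix, cand$iy, cand$iz), ]
  cand <- cand[seq_len(min(3L * cfg$n_keep, nrow(cand))), ]

  # exact scoring of candidates
  score_pose_rt <- function(rot, t) {
    xyz <- sweep(offsets0 %*% t(rot), 2, -t)
    rigid_score_xyz(rec, xyz, lig$charge, cfg)
  }
  cand$t1 <- grids$gx[cand$ix]; cand$t2 <- grids$gy[cand$iy]; cand$t3 <- grids$gz[cand$iz]
  cand$e_exact <- vapply(seq_len(nrow(cand)), function(i) {
    score_pose_rt(rots[[cand$orient[i]]], c(cand$t1[i], cand$t2[i], cand$t3[i]))
  }, 0)
  cand <- cand[order(cand$e_exact, cand$orient, cand$t1, cand$t2, cand$t3), ]
  cand <- cand[seq_len(min(cfg$n_keep, nrow(cand))), ]

  refine_one <- function(rot, t, e) {
    if (!cfg$refine) return(list(rot = rot, t = t, e = e))
    for (step in cfg$grid_spacing / c(1, 2, 4, 8)) {
      improved <- TRUE
      while (improved) {
        improved <- FALSE
        for (ax in 1:3) for (s in c(-1, 1)) {
          t2 <- t; t2[ax] <- t2[ax] + s * step
          e2 <- score_pose_rt(rot, t2)
          if (e2 < e - 1e-12) { t <- t2; e <- e2; improved <- TRUE }
        }
      }
    }
    for (ang in c(10, 5, 2.5, 1.25)) {
      improved <- TRUE
      while (improved) {
        improved <- FALSE
        for (ax in 1:3) for (s in c(-1, 1)) {
          axis <- numeric(3); axis[ax] <- 1
          rot2 <- quat_to_mat(axis_angle_quat(axis, s * ang)) %*% rot
          e2 <- score_pose_rt(rot2, t)
          if (e2 < e - 1e-12) { rot <- rot2; e <- e2; improved <- TRUE }
        }
      }
    }
    list(rot = rot, t = t, e = e)
  }

  sols <- lapply(seq_len(nrow(cand)), function(i) {
    r <- refine_one(rots[[cand$orient[i]]],
                    c(cand$t1[i], cand$t2[i], cand$t3[i]), cand$e_exact[i])
    list(rotation = r$rot, translation = r$t, energy = r$e,
         orient_index = cand$orient[i])
  })
  ord <- order(vapply(sols, `[[`, 0, "energy"),
               vapply(sols, `[[`, 0L, "orient_index"))
  sols <- sols[ord]
  for (i in seq_along(sols)) sols[[i]]$rank <- i

  res <- structure(list(solutions = sols, receptor = receptor,
                        ligand = ligand, ligand_centroid = ctr, cfg = cfg),
                   class = "xd_rigid_result")
  cl <- cluster_solutions(res, threshold = cfg$cluster_threshold)
  for (i in seq_along(sols)) res$solutions[[i]]$cluster_id <- cl[i]
  res$cluster_leaders <- attr(cl, "leaders")
  res$summary <- data.frame(
    rank = seq_along(sols),
    energy = vapply(res$solutions, `[[`, 0, "energy"),
    cluster_id = as.integer(cl)
  )
  res
}

#' @export
print.xd_rigid_result <- function(x, ...) {
  cat(sprintf("<rigid docking: %d solution(s), %d cluster(s)>\n",
              length(x$solutions), length(unique(x$summary$cluster_id))))
  print(utils::head(x$summary, 10))
  invisible(x)
}

#' Place the ligand structure according to a rigid solution
#'
#' @param result `xd_rigid_result`.
#' @param i solution rank.
#' @return transformed ligand structure.
#' @export
rigid_solution_pose <- function(result, i = 1L) {
  sol <- result$solutions[[i]]
  xyz <- atom_coords(result$ligand)
  ctr <- result$ligand_centroid
  placed <- sweep(sweep(xyz, 2, ctr) %*% t(sol$rotation), 2, -sol$translation)
  set_atom_coords(result$ligand, placed)
}

#' Greedy energy-ordered clustering of rigid solutions
#'
#' In energy order, each solution joins the first existing cluster whose
#' leader is within `threshold` ligand C-alpha RMSD (computed in the common
#' receptor frame); otherwise it founds a new cluster. Cluster ids are
#' ordered by leader energy. For ligands without C-alpha atoms all heavy
#' atoms are used.
#'
#' @param result `xd_rigid_result` (solutions must be sorted ascending by
#'   energy).
#' @param threshold RMSD threshold in Angstrom (default 3).
#' @return integer vector of cluster ids, with attribute `leaders` giving
#'   the solution index of each cluster leader.
#' @export
cluster_solutions <- function(result, threshold = 3.0) {
  sols <- result$solutions
  if (length(sols) == 0L) return(integer(0))
  en <- vapply(sols, `[[`, 0, "energy")
  if (is.unsorted(en)) stop("solutions must be sorted ascending by energy", call. = FALSE)
  lig <- result$ligand
  is_ca <- lig$atoms$name == "CA"
  sel <- if (any(is_ca)) is_ca else lig$atoms$is_heavy
  base <- atom_coords(lig)[sel, , drop = FALSE]
  ctr <- result$ligand_centroid
  coords_of <- function(sol) {
    sweep(sweep(base, 2, ctr) %*% t(sol$rotation), 2, -sol$translation)
  }
  xyzs <- lapply(sols, coords_of)
  ids <- integer(length(sols))
  leaders <- integer(0)
  for (i in seq_along(sols)) {
    placed <- FALSE
    for (ci in seq_along(leaders)) {
      if (heavy_rmsd(xyzs[[i]], xyzs[[leaders[ci]]]) <= threshold) {
        ids[i] <- ci; placed <- TRUE; break
      }
    }
    if (!placed) {
      leaders <- c(leaders, i)
      ids[i] <- length(leaders)
    }
  }
  attr(ids, "leaders") <- leaders
  ids
}

#' Interface residues of a docked protein-protein solution
#'
#' Residues of each molecule having any heavy atom within `cutoff` of any
#' heavy atom of the other molecule, in a common frame.
#'
#' @param receptor,ligand_pose structures in a common frame.
#' @param cutoff contact cutoff in Angstrom (default 4.0).
#' @return list with `receptor` and `ligand` residue-key vectors.
#' @export
interface_residues <- function(receptor, ligand_pose, cutoff = 4.0) {
  lx <- atom_coords(ligand_pose, heavy_only = TRUE)
  rx <- atom_coords(receptor, heavy_only = TRUE)
  list(receptor = contact_residues(receptor, lx, cutoff),
       ligand = contact_residues(ligand_pose, rx, cutoff))
}
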