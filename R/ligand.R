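# Ligand topology: heavy atoms + bond graph + active torsions, and the
# chromosome encoding (translation, orientation quaternion, torsion angles)
# used by the genetic algorithm.

#' Construct a ligand topology
#'
#' @param atoms atom data.frame as in [new_structure()] (heavy atoms with
#'   elements and formal charges; residue fields may be constant).
#' @param bonds data.frame with integer columns `i`, `j` (atom indices) and
#'   `order` (bond order, 1 for single).
#' @param name ligand name used in reports.
#' @param rotatable optional integer bond indices to activate; default
#'   [detect_rotatable_bonds()] with the standard torsion cap.
#' @param max_torsions cap on active torsions (default 5).
#' @return object of class `xd_ligand`.
#' @export
ligand_topology <- function(atoms, bonds, name = "ligand", rotatable = NULL,
                            max_torsions = 5L) {
  s <- new_structure(atoms)
  bonds <- as.data.frame(bonds)
  stopifnot(all(c("i", "j") %in% names(bonds)))
  if (is.null(bonds$order)) bonds$order <- 1L
  n <- nrow(s$atoms)
  stopifnot(all(bonds$i >= 1), all(bonds$j >= 1), all(bonds$i <= n),
            all(bonds$j <= n), all(bonds$i != bonds$j))
  lig <- structure(list(atoms = s$atoms, bonds = bonds, name = name,
                        rotatable = integer(0)),
                   class = "xd_ligand")
  g <- ligand_graph(lig)
  if (igraph::components(g)$no != 1L) {
    stop("ligand bond graph must be connected", call. = FALSE)
  }
  lig$rotatable <- if (is.null(rotatable)) {
    detect_rotatable_bonds(lig, max_torsions = max_torsions)
  } else {
    sort(as.integer(rotatable))
  }
  lig$moving_sets <- lapply(lig$rotatable, function(b) torsion_moving_set(lig, b))
  lig
}

#' @export
print.xd_ligand <- function(x, ...) {
  cat(sprintf("<ligand '%s': %d atoms, %d bonds, %d active torsion(s)>\n",
              x$name, nrow(x$atoms), nrow(x$bonds), length(x$rotatable)))
  invisible(x)
}

ligand_graph <- function(lig) {
  # keep isolated atoms as vertices so connectivity checks see them
  g <- igraph::make_empty_graph(n = nrow(lig$atoms), directed = FALSE)
  igraph::add_edges(g, as.vector(t(as.matrix(lig$bonds[, c("i", "j")]))))
}

#' Ligand topology as a plain structure (for scoring / writing)
#' @param lig ligand topology.
#' @param xyz optional replacement coordinates.
#' @return `xd_structure`.
#' @export
ligand_structure <- function(lig, xyz = NULL) {
  s <- new_structure(lig$atoms)
  if (!is.null(xyz)) s <- set_atom_coords(s, xyz)
  s
}

#' Detect rotatable bonds
#'
#' A bond is rotatable when it is a single bond, not part of any ring
#' (i.e. a bridge of the bond graph), and both end atoms are non-terminal
#' (degree >= 2). If more candidates exist than `max_torsions`, the bonds
#' whose rotation moves the most atoms are kept (ties broken towards the
#' lower bond index). Deterministic.
#'
#' @param lig ligand topology (or a list with `atoms` and `bonds`).
#' @param max_torsions cap on the number of active torsions.
#' @return sorted integer vector of bond indices into `lig$bonds`.
#' @export
detect_rotatable_bonds <- function(lig, max_torsions = 5L) {
  g <- ligand_graph(lig)
  if (igraph::components(g)$no != 1L) {
    stop("ligand bond graph must be connected", call. = FALSE)
  }
  deg <- igraph::degree(g)
  bridges <- igraph_bridge_ids(g)
  cand <- which(lig$bonds$order == 1L &
                deg[lig$bonds$i] >= 2L & deg[lig$bonds$j] >= 2L &
                seq_len(nrow(lig$bonds)) %in% bridges)
  if (length(cand) == 0L) return(integer(0))
  moved <- vapply(cand, function(b) length(torsion_moving_set(lig, b)$moving), 0L)
  keep <- cand[order(-moved, cand)][seq_len(min(max_torsions, length(cand)))]
  sort(keep)
}

# Edge ids of bridges (edges whose removal disconnects the graph).
igraph_bridge_ids <- function(g) {
  br <- igraph::bridges(g)
  as.integer(br)
}

# Rotation bookkeeping for bond b: the side of the bond not containing the
# root atom (atom 1) moves; the bond atom on that side is the pivot (stays
# fixed, defines the axis together with the anchor atom on the root side).
torsion_moving_set <- function(lig, b) {
  g <- ligand_graph(lig)
  i <- lig$bonds$i[b]; j <- lig$bonds$j[b]
  g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(i, j)))
  comp <- igraph::components(g2)$membership
  root_side <- comp[1L]
  if (comp[i] == root_side && comp[j] == root_side) {
    stop("bond is not a bridge", call. = FALSE)
  }
  pivot <- if (comp[i] == root_side) j else i
  anchor <- if (pivot == i) j else i
  list(moving = setdiff(which(comp != root_side), pivot),
       pivot = pivot, anchor = anchor)
}

# Pairwise bond-path separation matrix (number of bonds on shortest path).
bond_separation <- function(lig) {
  igraph::distances(ligand_graph(lig))
}

#' Construct a chromosome
#'
#' @param translation centroid displacement (Angstrom, length 3).
#' @param orientation unit quaternion (w, x, y, z).
#' @param torsions torsion angles in degrees, one per active torsion,
#'   wrapped into [-180, 180).
#' @return list of class `xd_chromosome`.
#' @export
chromosome <- function(translation = c(0, 0, 0),
                       orientation = c(1, 0, 0, 0),
                       torsions = numeric(0)) {
  stopifnot(length(translation) == 3L, length(orientation) == 4L)
  structure(list(translation = as.numeric(translation),
                 orientation = quat_normalize(as.numeric(orientation)),
                 torsions = wrap_angle(as.numeric(torsions))),
            class = "xd_chromosome")
}

#' Realise a chromosome as ligand coordinates
#'
#' Torsion rotations are applied bond by bond (ascending bond index) from
#' the root atom (atom 1) outward: the subtree on the far side of each
#' active bond rotates about the bond axis. The torsioned ligand is then
#' rotated rigidly about its centroid by the orientation quaternion and its
#' centroid displaced by the translation. The zero chromosome reproduces
#' the reference coordinates; bond lengths and angles of the non-rotated
#' geometry are preserved.
#'
#' @param lig ligand topology.
#' @param chrom chromosome; torsion count must match `lig$rotatable`.
#' @param reference_coords reference coordinates (defaults to the
#'   topology's own coordinates).
#' @return coordinate matrix (n x 3).
#' @export
apply_chromosome <- function(lig, chrom, reference_coords = NULL) {
  xyz <- if (is.null(reference_coords)) {
    as.matrix(lig$atoms[, c("x", "y", "z")])
  } else {
    as.matrix(reference_coords)
  }
  if (length(chrom$torsions) != length(lig$rotatable)) {
    stop(sprintf("chromosome has %d torsions but ligand has %d active torsions",
                 length(chrom$torsions), length(lig$rotatable)), call. = FALSE)
  }
  for (k in seq_along(lig$rotatable)) {
    ang <- chrom$torsions[k]
    if (ang == 0) next
    ms <- lig$moving_sets[[k]]
    if (length(ms$moving) == 0L) next
    origin <- xyz[ms$pivot, ]
    axis <- origin - xyz[ms$anchor, ]
    rot <- quat_to_mat(axis_angle_quat(axis, ang))
    xyz[ms$moving, ] <- sweep(sweep(xyz[ms$moving, , drop = FALSE], 2, origin) %*% t(rot),
                              2, -origin)
  }
  q <- quat_normalize(chrom$orientation)
  ctr <- colMeans(xyz)
  xyz <- sweep(sweep(xyz, 2, ctr) %*% t(quat_to_mat(q)), 2, -(ctr + chrom$translation))
  xyz
}
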