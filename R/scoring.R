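# Energy model.
#
# Two scorers share this file:
#  * the softened Lennard-Jones potential used for rigid protein-protein
#    docking (finite at r = 0 for alpha > 0, reducing to the standard 12-6
#    form as alpha -> 0), plus a screened Coulomb term; and
#  * the empirical flexible-docking score
#        E_tot = E_bind + E_pharma + E_ligpre
#    where E_bind sums piecewise-linear hydrogen-bond/steric pair wells over
#    intermolecular (and 1-4+ intramolecular) heavy-atom pairs plus an
#    out-of-box penalty, E_pharma is an optional pharmacophore bonus and
#    E_ligpre penalises unsatisfied electrostatic/hydrophilic preferences.

#' Softened Lennard-Jones parameters
#'
#' Defaults follow the typical unbound-protein calibration alpha = 0.4,
#' sigma = 0.33 nm, epsilon = 0.5, applied to all heavy atoms. `sigma` is
#' stored in the same length unit as the distances it is evaluated against;
#' for structures in Angstrom the default is 3.3 A (= 0.33 nm).
#'
#' @param alpha dimensionless softening (>= 0; 0 recovers standard 12-6 LJ).
#' @param sigma finite-size parameter, same unit as `r` (default 3.3 A).
#' @param epsilon well depth (>= 0).
#' @return list of class `xd_soft_lj`.
#' @export
soft_lj_params <- function(alpha = 0.4, sigma = 3.3, epsilon = 0.5) {
  stopifnot(alpha >= 0, sigma > 0, epsilon >= 0)
  structure(list(alpha = alpha, sigma = sigma, epsilon = epsilon),
            class = "xd_soft_lj")
}

#' Softened Lennard-Jones potential
#'
#' V(r) = 1/(alpha sigma^6 + r^6) * (4 eps sigma^12 / (alpha sigma^6 + r^6)
#' - 4 eps sigma^6). Finite everywhere for alpha > 0; at r = 0 it equals
#' 4 eps (1 - alpha) / alpha^2. For alpha = 0 and r > 0 it is the standard
#' 12-6 Lennard-Jones potential.
#'
#' @param r distances (same unit as `p$sigma`), vectorised.
#' @param p parameters from [soft_lj_params()].
#' @return energies, same length as `r`.
#' @export
soft_lj <- function(r, p = soft_lj_params()) {
  stopifnot(all(r >= 0))
  if (p$alpha == 0 && any(r == 0)) {
    stop("soft_lj singularity: r = 0 with alpha = 0", call. = FALSE)
  }
  s6 <- p$sigma^6
  x <- s6 / (p$alpha * s6 + r^6)
  4 * p$epsilon * (x * x - x)
}

#' Screened Coulomb interaction
#'
#' 332.0636 q1 q2 / (eps(r) r) with the distance-dependent dielectric
#' eps(r) = 4 r, i.e. 332.0636 q1 q2 / (4 r^2), in kcal/mol for charges in
#' elementary units and r in Angstrom.
#'
#' @param q1,q2 formal charges (e).
#' @param r distance in Angstrom (> 0), vectorised.
#' @return energy in kcal/mol.
#' @export
coulomb <- function(q1, q2, r) {
  if (any(r <= 0)) stop("coulomb singularity: r must be > 0", call. = FALSE)
  332.0636 * q1 * q2 / (4 * r * r)
}

#' Tunable constants of the empirical score
#'
#' Every knot, well depth and penalty of the flexible-docking score in one
#' place. Distances in Angstrom, energies in kcal/mol.
#'
#' @param hb_knots,hb_values hydrogen-bond well: piecewise-linear energy
#'   through these (distance, energy) knots, constant outside.
#' @param st_knots,st_values steric well, same convention.
#' @param inter_cutoff intermolecular pair cutoff for E_bind.
#' @param box_penalty E_penal value when any ligand atom leaves the box.
#' @param wp_penalty penalty magnitude for each unsatisfied ligand
#'   preference (electrostatic, hydrophilic).
#' @param wp_elec_cutoff distance within which an oppositely charged target
#'   atom satisfies the electrostatic preference.
#' @param hb_contact_max largest donor-acceptor distance counted as a formed
#'   hydrogen bond for the hydrophilic preference.
#' @param min_hb_atoms ligand donor/acceptor count that triggers the
#'   hydrophilic preference.
#' @param min_bond_sep minimum bond-path separation for intramolecular pairs.
#' @param elec_min_r floor (A) on the distance entering the screened
#'   Coulomb term of pair energies: the 4r distance-dependent dielectric is
#'   not meaningful below contact separation, and an unclamped term would
#'   let opposite formal charges collapse into unphysical fused poses. The
#'   default (2.9 A) caps a +1/-1 salt bridge near -9.9 kcal/mol.
#' @return list of class `xd_score_params`.
#' @export
score_params <- function(hb_knots = c(0, 1.5, 2.0, 2.3, 3.1, 3.6),
                         hb_values = c(5, 5, 0, -2.5, -2.5, 0),
                         st_knots = c(0, 2.0, 3.3, 3.6, 4.5, 6.0),
                         st_values = c(5, 5, 0, -0.4, -0.4, 0),
                         inter_cutoff = 6.0,
                         box_penalty = 10000,
                         wp_penalty = 5.0,
                         wp_elec_cutoff = 4.0,
                         hb_contact_max = 3.6,
                         min_hb_atoms = 3L,
                         min_bond_sep = 4L,
                         elec_min_r = 2.9) {
  stopifnot(length(hb_knots) == length(hb_values),
            length(st_knots) == length(st_values),
            !is.unsorted(hb_knots), !is.unsorted(st_knots))
  structure(list(hb_knots = hb_knots, hb_values = hb_values,
                 st_knots = st_knots, st_values = st_values,
                 inter_cutoff = inter_cutoff, box_penalty = box_penalty,
                 wp_penalty = wp_penalty, wp_elec_cutoff = wp_elec_cutoff,
                 hb_contact_max = hb_contact_max,
                 min_hb_atoms = as.integer(min_hb_atoms),
                 min_bond_sep = as.integer(min_bond_sep),
                 elec_min_r = elec_min_r),
            class = "xd_score_params")
}

piecewise <- function(r, knots, values) {
  stats::approx(knots, values, xout = r, rule = 2)$y
}

#' Pairwise interaction energy between two typed atoms
#'
#' The pair type is fixed by the two atoms' typing: donor-acceptor (either
#' direction) pairs take the hydrogen-bond well; all other pairs take the
#' steric well; when both atoms are charged a screened Coulomb term is
#' added and the pair is labelled electrostatic (unless it is already a
#' donor-acceptor pair). The energy is continuous in r.
#'
#' @param type_i,type_j one-row typing entries (see [assign_atom_types()]).
#' @param r distance in Angstrom.
#' @param params constants from [score_params()].
#' @return list with `type` ("hbond", "electrostatic" or "steric"),
#'   `distance` and `energy` (kcal/mol).
#' @export
pair_energy <- function(type_i, type_j, r, params = score_params()) {
  stopifnot(r >= 0)
  hb <- (isTRUE(type_i$donor) && isTRUE(type_j$acceptor)) ||
        (isTRUE(type_j$donor) && isTRUE(type_i$acceptor))
  qprod <- (type_i$charge %||% 0) * (type_j$charge %||% 0)
  e <- if (hb) piecewise(r, params$hb_knots, params$hb_values)
       else piecewise(r, params$st_knots, params$st_values)
  if (qprod != 0) {
    e <- e + coulomb(type_i$charge, type_j$charge, max(r, params$elec_min_r))
  }
  type <- if (hb) "hbond" else if (qprod != 0) "electrostatic" else "steric"
  list(type = type, distance = r, energy = e)
}

# Vectorised pair-energy sum used by the pose scorers. `hb` is a logical
# vector marking donor-acceptor pairs, `qprod` the product of formal
# charges; distances r in Angstrom. Coulomb is only evaluated at r > 0.
pair_energy_sum <- function(r, hb, qprod, params) {
  if (length(r) == 0L) return(0)
  e <- numeric(length(r))
  if (any(hb)) e[hb] <- piecewise(r[hb], params$hb_knots, params$hb_values)
  if (any(!hb)) e[!hb] <- piecewise(r[!hb], params$st_knots, params$st_values)
  el <- qprod != 0
  if (any(el)) {
    re <- pmax(r[el], params$elec_min_r)
    e[el] <- e[el] + 332.0636 * qprod[el] / (4 * re^2)
  }
  sum(e)
}

#' Prepare a receptor for repeated pose scoring
#'
#' Types every atom once and caches heavy-atom coordinates, typing vectors
#' and residue keys.
#'
#' @param target structure.
#' @return list of class `xd_target`.
#' @export
prepare_target <- function(target) {
  types <- assign_atom_types(target)
  heavy <- target$atoms$is_heavy
  structure(list(
    structure = target,
    coords = atom_coords(target)[heavy, , drop = FALSE],
    donor = types$donor[heavy],
    acceptor = types$acceptor[heavy],
    charge = types$charge[heavy],
    res_keys = residue_keys(target, unique_only = FALSE)[heavy],
    chain = target$atoms$chain_id[heavy]
  ), class = "xd_target")
}

as_target <- function(target) {
  if (inherits(target, "xd_target")) target else prepare_target(target)
}

#' Pharmacophore specification for the optional E_pharma term
#'
#' Hot-spot atoms on the receptor with weights and a required interaction
#' type. Disabled by default: the docking here is blind, with no prior
#' binding-site knowledge.
#'
#' @param atom_index indices into the receptor's heavy atoms.
#' @param weight pharmacophore weights w_j.
#' @param type required interaction type per hot-spot atom, "hbond" or
#'   "steric".
#' @param enabled logical; when FALSE, E_pharma = 0.
#' @return list of class `xd_pharma`.
#' @export
pharmacophore_spec <- function(atom_index = integer(0), weight = numeric(0),
                               type = character(0), enabled = FALSE) {
  stopifnot(length(atom_index) == length(weight),
            length(weight) == length(type),
            all(is.finite(weight)), all(type %in% c("hbond", "steric")))
  structure(list(atom_index = as.integer(atom_index), weight = weight,
                 type = type, enabled = isTRUE(enabled)),
            class = "xd_pharma")
}

# Ligand-side scoring context: heavy-atom typing plus the intramolecular
# pair list (bond-path separation >= min_bond_sep), from an optional
# topology.
ligand_score_ctx <- function(lig_structure, topology = NULL,
                             params = score_params()) {
  types <- assign_atom_types(lig_structure)
  heavy <- lig_structure$atoms$is_heavy
  intra <- NULL
  if (!is.null(topology)) {
    sep <- bond_separation(topology)
    idx <- which(upper.tri(sep) & sep >= params$min_bond_sep, arr.ind = TRUE)
    if (nrow(idx) > 0L) intra <- idx
  }
  list(donor = types$donor[heavy], acceptor = types$acceptor[heavy],
       charge = types$charge[heavy], intra = intra)
}

# Core scorer shared by score_pose() and the GA: takes a prepared target,
# ligand heavy-atom coordinates + typing context, and a box.
score_pose_core <- function(tgt, lig_xyz, lig_ctx, box, params,
                            pharma = NULL) {
  d2 <- cross_dist2(lig_xyz, tgt$coords)
  cut2 <- params$inter_cutoff^2
  pair <- which(d2 <= cut2)
  e_inter <- 0
  hb_contact <- FALSE
  elec_ok <- !any(lig_ctx$charge != 0)  # vacuously satisfied if uncharged
  if (length(pair) > 0L) {
    li <- (pair - 1L) %% nrow(lig_xyz) + 1L
    ti <- (pair - 1L) %/% nrow(lig_xyz) + 1L
    r <- sqrt(d2[pair])
    hb <- (lig_ctx$donor[li] & tgt$acceptor[ti]) |
          (tgt$donor[ti] & lig_ctx$acceptor[li])
    qprod <- lig_ctx$charge[li] * tgt$charge[ti]
    e_inter <- pair_energy_sum(r, hb, qprod, params)
    hb_contact <- any(hb & r <= params$hb_contact_max)
    if (!elec_ok) {
      elec_ok <- any(qprod < 0 & r <= params$wp_elec_cutoff)
    }
  }
  e_intra <- 0
  if (!is.null(lig_ctx$intra)) {
    i <- lig_ctx$intra[, 1L]; j <- lig_ctx$intra[, 2L]
    r <- sqrt(rowSums((lig_xyz[i, , drop = FALSE] - lig_xyz[j, , drop = FALSE])^2))
    hb <- (lig_ctx$donor[i] & lig_ctx$acceptor[j]) |
          (lig_ctx$donor[j] & lig_ctx$acceptor[i])
    e_intra <- pair_energy_sum(r, hb, lig_ctx$charge[i] * lig_ctx$charge[j], params)
  }
  e_penal <- 0
  if (!is.null(box)) {
    out <- lig_xyz[, 1] < box$min[1] | lig_xyz[, 1] > box$max[1] |
           lig_xyz[, 2] < box$min[2] | lig_xyz[, 2] > box$max[2] |
           lig_xyz[, 3] < box$min[3] | lig_xyz[, 3] > box$max[3]
    if (any(out)) e_penal <- params$box_penalty
  }
  e_pharma <- 0
  if (!is.null(pharma) && pharma$enabled && length(pharma$atom_index) > 0L) {
    for (k in seq_along(pharma$atom_index)) {
      j <- pharma$atom_index[k]
      r <- sqrt(d2[, j])
      if (pharma$type[k] == "hbond") {
        ok <- ((lig_ctx$donor & tgt$acceptor[j]) |
               (tgt$donor[j] & lig_ctx$acceptor)) & r <= params$hb_contact_max
      } else {
        ok <- r <= params$inter_cutoff
      }
      e_pharma <- e_pharma + pharma$weight[k] * sum(ok)
    }
  }
  wp_elec <- if (elec_ok) 0 else params$wp_penalty
  n_hbcap <- sum(lig_ctx$donor | lig_ctx$acceptor)
  wp_hb <- if (n_hbcap >= params$min_hb_atoms && !hb_contact) params$wp_penalty else 0
  breakdown(e_inter, e_intra, e_penal, e_pharma, wp_elec, wp_hb)
}

breakdown <- function(e_inter, e_intra, e_penal, e_pharma, wp_elec, wp_hb) {
  structure(list(
    e_inter = e_inter, e_intra = e_intra, e_penal = e_penal,
    e_pharma = e_pharma, wp_elec = wp_elec, wp_hb = wp_hb,
    e_total = (e_inter + e_intra + e_penal) + e_pharma + (wp_elec + wp_hb)
  ), class = "xd_score")
}

#' @export
print.xd_score <- function(x, ...) {
  cat(sprintf(paste0("E_total %.3f = E_bind(inter %.3f + intra %.3f + penal %g)",
                     " + E_pharma %.3f + E_ligpre(elec %g + hb %g)\n"),
              x$e_total, x$e_inter, x$e_intra, x$e_penal,
              x$e_pharma, x$wp_elec, x$wp_hb))
  invisible(x)
}

#' Score one ligand pose against a receptor
#'
#' Computes the empirical flexible-docking score: `e_inter` sums pair wells
#' over all target-ligand heavy-atom pairs within the intermolecular
#' cutoff; `e_intra` sums pairs of ligand atoms at bond-path separation of
#' at least `min_bond_sep` (requires `topology`); `e_penal` is the fixed
#' box penalty if any ligand atom lies outside the search box; `e_pharma`
#' is the optional pharmacophore bonus; `wp_elec`/`wp_hb` penalise a
#' charged ligand with no oppositely charged partner nearby and a
#' hydrogen-bond-capable ligand forming no hydrogen bond.
#'
#' @param target structure or prepared target from [prepare_target()].
#' @param ligand_pose structure holding the placed ligand.
#' @param box search box `list(min =, max =)` or NULL for no penalty.
#' @param pharma optional [pharmacophore_spec()].
#' @param topology optional ligand topology for the intramolecular term.
#' @param params constants from [score_params()].
#' @return score breakdown of class `xd_score`; fields satisfy
#'   `e_total = (e_inter + e_intra + e_penal) + e_pharma + (wp_elec + wp_hb)`.
#' @export
score_pose <- function(target, ligand_pose, box = NULL, pharma = NULL,
                       topology = NULL, params = score_params()) {
  tgt <- as_target(target)
  ctx <- ligand_score_ctx(ligand_pose, topology, params)
  lig_xyz <- atom_coords(ligand_pose, heavy_only = TRUE)
  score_pose_core(tgt, lig_xyz, ctx, box, params, pharma)
}
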