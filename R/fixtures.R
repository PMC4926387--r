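# Deterministic toy-structure generators: the download-free test surface.
#
# Fixtures use simplified pseudo-atom chemistry (helical C-alpha/C-beta
# traces, engineered pocket linings, idealised ligand topologies) rather
# than real amino-acid geometry: they exercise the algorithms and the I/O
# paths, not force-field realism. Every generator is bit-reproducible from
# its seed and returns its planted ground truth alongside the data.

#' Toy receptor with a planted surface pocket
#'
#' Builds a jittered alpha-helical C-alpha trace with hydrophobic
#' side-chain pseudo-atoms, then carves a concave pocket: the lining
#' residues' side chains are rewritten so that their polar tip atoms sit
#' on a compact ring of radius 2.5 A around the pocket centre, placing any
#' pocket-bound probe atom within hydrogen-bonding range of the lining
#' and, because the ring diameter is well under the 4-A contact cutoff,
#' guaranteeing that a pose occupying the pocket is in contact with every
#' lining residue. The rest of the surface is purely hydrophobic (steric
#' well depth only), so the global energy optimum for a polar probe is
#' inside the pocket by construction.
#'
#' @param seed integer RNG seed.
#' @param n_residues number of residues (>= 8).
#' @param pocket lining request: list with counts `donors`, `acceptors`,
#'   `charged_pos`, `charged_neg`. The default emulates an acidic,
#'   hydrogen-bond-rich surface site (the kind of pocket charged amino-acid
#'   excipients select on real proteins).
#' @param jitter coordinate noise sigma in Angstrom.
#' @return list with `structure` (`xd_structure`) and `pocket` (list:
#'   `residues` keys, `center`, `lining` data.frame).
#' @export
make_toy_receptor <- function(seed = 42L, n_residues = 30L,
                              pocket = list(donors = 2L, acceptors = 2L,
                                            charged_pos = 0L, charged_neg = 1L),
                              jitter = 0.1) {
  if (n_residues < 8L) stop("n_residues must be >= 8", call. = FALSE)
  pocket <- utils::modifyList(
    list(donors = 0L, acceptors = 0L, charged_pos = 0L, charged_neg = 0L),
    pocket)
  n_line <- pocket$donors + pocket$acceptors + pocket$charged_pos + pocket$charged_neg
  if (n_line < 1L) stop("pocket request must have at least one lining atom", call. = FALSE)
  if (n_line > floor(n_residues / 3)) {
    stop("infeasible pocket request: too many lining residues for the receptor size",
         call. = FALSE)
  }
  with_private_seed(seed, {
    i <- seq_len(n_residues)
    theta <- (i - 1) * 100 * pi / 180
    ca <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * (i - 1)) +
      matrix(stats::rnorm(3 * n_residues, 0, jitter), ncol = 3)
    cb_dir <- cbind(cos(theta), sin(theta), 0)
    cb <- ca + 1.5 * cb_dir

    center <- c(2.3 + 4.0, 0, 1.5 * (n_residues - 1) / 2)
    lining_idx <- order(sqrt(rowSums(sweep(ca, 2, center)^2)))[seq_len(n_line)]
    roles <- c(rep("donor", pocket$donors), rep("acceptor", pocket$acceptors),
               rep("charged_pos", pocket$charged_pos),
               rep("charged_neg", pocket$charged_neg))
    role_info <- list(
      donor = list(res = "ASN", atom = "ND2", elem = "N", q = 0L),
      acceptor = list(res = "ASN", atom = "OD1", elem = "O", q = 0L),
      charged_pos = list(res = "LYS", atom = "NZ", elem = "N", q = 1L),
      charged_neg = list(res = "ASP", atom = "OD2", elem = "O", q = -1L)
    )
    phi <- 2 * pi * (seq_len(n_line) - 1) / n_line
    tips <- cbind(center[1], center[2] + 2.5 * cos(phi), center[3] + 2.5 * sin(phi))

    rows <- list()
    lining <- data.frame()
    serial <- 0L
    for (r in i) {
      li <- match(r, lining_idx)
      res <- if (!is.na(li)) role_info[[roles[li]]]$res else "ALA"
      add <- function(name, elem, xyz, q = 0L) {
        serial <<- serial + 1L
        rows[[length(rows) + 1L]] <<- data.frame(
          serial = serial, name = name, element = elem, res_name = res,
          chain_id = "A", res_seq = r, i_code = "",
          x = xyz[1], y = xyz[2], z = xyz[3], formal_charge = q,
          is_heavy = TRUE, stringsAsFactors = FALSE)
      }
      add("CA", "C", ca[r, ])
      if (!is.na(li)) {
        # lining side chain: the polar tip atom on the inner ring plus a
        # hydrophobic rim carbon forming the concave crown of the pocket;
        # the open mouth faces +x, in-plane approaches clash with the rim
        info <- role_info[[roles[li]]]
        tip <- tips[li, ]
        rim <- center + c(1.2, 4.8 * cos(phi[li]), 4.8 * sin(phi[li]))
        add(info$atom, info$elem, tip, info$q)
        add("CG", "C", rim)
        lining <- rbind(lining, data.frame(
          residue = paste("A", info$res, r, "", sep = ":"),
          role = roles[li], atom = info$atom, stringsAsFactors = FALSE))
      } else {
        add("CB", "C", cb[r, ])
      }
    }
    s <- new_structure(do.call(rbind, rows))
    list(structure = s,
         pocket = list(residues = lining$residue, center = center,
                       lining = lining, request = pocket))
  })
}

# Manual topology builder used by make_ligand().
build_ligand <- function(name, atoms, bonds, max_torsions = 5L) {
  atoms <- do.call(rbind, lapply(atoms, function(a) {
    data.frame(name = a[[1]], element = a[[2]],
               x = a[[3]][1], y = a[[3]][2], z = a[[3]][3],
               formal_charge = if (length(a) >= 4) a[[4]] else 0L,
               stringsAsFactors = FALSE)
  }))
  atoms$res_name <- "LIG"; atoms$chain_id <- "X"; atoms$res_seq <- 1L
  atoms$i_code <- ""; atoms$is_heavy <- TRUE
  atoms$serial <- seq_len(nrow(atoms))
  bonds <- data.frame(
    i = vapply(bonds, function(x) as.integer(x[[1]]), 0L),
    j = vapply(bonds, function(x) as.integer(x[[2]]), 0L),
    order = vapply(bonds, function(x) as.integer(x[[3]]), 0L))
  ligand_topology(atoms, bonds, name = name, max_torsions = max_torsions)
}

#' Idealised excipient-class ligand topologies
#'
#' Four heavy-atom toy ligands carrying each excipient class's hallmark
#' features: `"amino-acid-like"` (charged plus several donors, 5 active
#' torsions after the cap), `"disaccharide-like"` (two rings joined by a
#' glycosidic oxygen, many donors/acceptors, 2 torsions),
#' `"polyol-like"` (linear chain, one hydroxyl per carbon, 5 torsions),
#' `"surfactant-like"` (long apolar tail with an ester-like polar head;
#' more rotatable bonds than the cap, truncated to 5).
#'
#' @param kind one of the four class names above.
#' @param max_torsions active-torsion cap (default 5).
#' @return `xd_ligand` topology.
#' @export
make_ligand <- function(kind = c("amino-acid-like", "disaccharide-like",
                                 "polyol-like", "surfactant-like"),
                        max_torsions = 5L) {
  kind <- match.arg(kind)
  b <- function(i, j, order = 1L) list(i, j, order)
  a <- function(name, elem, xyz, q = 0L) list(name, elem, xyz, q)
  switch(kind,
    "amino-acid-like" = build_ligand("amino-acid-like", list(
      a("C1", "C", c(0, 0, 0)),
      a("N1", "N", c(0.2, -1.0, 0.9), 1L),
      a("C2", "C", c(1.4, 0.5, 0)),
      a("O1", "O", c(2.4, -0.2, 0.4)),
      a("C3", "C", c(-1.2, 0.8, 0)),
      a("C4", "C", c(-2.5, 0.0, 0)),
      a("C5", "C", c(-3.8, 0.8, 0)),
      a("N2", "N", c(-5.0, 0.0, 0)),
      a("C6", "C", c(-6.3, 0.6, 0)),
      a("N3", "N", c(-7.4, -0.1, 0.2), 1L),
      a("N4", "N", c(-6.4, 1.9, -0.2))
    ), list(b(1, 2), b(1, 3), b(3, 4), b(1, 5), b(5, 6), b(6, 7), b(7, 8),
            b(8, 9), b(9, 10), b(9, 11)), max_torsions),
    "disaccharide-like" = {
      hex <- function(cx) {
        ang <- (0:5) * pi / 3
        cbind(cx + 1.45 * cos(ang), 1.45 * sin(ang), 0)
      }
      r1 <- hex(0); r2 <- hex(4.9)
      build_ligand("disaccharide-like", list(
        a("C1", "C", r1[1, ]), a("C2", "C", r1[2, ]), a("C3", "C", r1[3, ]),
        a("C4", "C", r1[4, ]), a("C5", "C", r1[5, ]), a("O5", "O", r1[6, ]),
        a("O1", "O", r1[2, ] + c(0.4, 0.9, 1.0)),
        a("O2", "O", r1[3, ] + c(-0.4, 0.9, -1.0)),
        a("O3", "O", r1[4, ] + c(-0.9, -0.4, 1.0)),
        a("OG", "O", c(2.45, 0, 0.4)),
        a("C1B", "C", r2[4, ]), a("C2B", "C", r2[5, ]), a("C3B", "C", r2[6, ]),
        a("C4B", "C", r2[1, ]), a("C5B", "C", r2[2, ]), a("O5B", "O", r2[3, ]),
        a("O1B", "O", r2[5, ] + c(0.4, -0.9, 1.0)),
        a("O2B", "O", r2[6, ] + c(0.9, 0.4, -1.0))
      ), list(b(1, 2), b(2, 3), b(3, 4), b(4, 5), b(5, 6), b(6, 1),
              b(2, 7), b(3, 8), b(4, 9), b(1, 10), b(10, 11),
              b(11, 12), b(12, 13), b(13, 14), b(14, 15), b(15, 16), b(16, 11),
              b(12, 17), b(13, 18)), max_torsions)
    },
    "polyol-like" = {
      atoms <- list(); bonds <- list()
      for (k in 1:6) {
        atoms[[length(atoms) + 1L]] <- a(paste0("C", k), "C",
                                         c(1.3 * k, 0.4 * (k %% 2), 0))
        atoms[[length(atoms) + 1L]] <- a(paste0("O", k), "O",
                                         c(1.3 * k, 0.4 * (k %% 2) + 1.2,
                                           0.3 * (-1)^k))
        bonds[[length(bonds) + 1L]] <- b(2 * k - 1, 2 * k)
        if (k > 1) bonds[[length(bonds) + 1L]] <- b(2 * k - 3, 2 * k - 1)
      }
      build_ligand("polyol-like", atoms, bonds, max_torsions)
    },
    "surfactant-like" = {
      atoms <- list(); bonds <- list()
      for (k in 1:8) {
        atoms[[length(atoms) + 1L]] <- a(paste0("C", k), "C",
                                         c(1.3 * k, 0.45 * (k %% 2), 0))
        if (k > 1) bonds[[length(bonds) + 1L]] <- b(k - 1, k)
      }
      atoms[[9]] <- a("C9", "C", c(11.7, 0.45, 0))
      atoms[[10]] <- a("O10", "O", c(11.9, 1.65, 0.4))
      atoms[[11]] <- a("O11", "O", c(12.8, -0.4, -0.2))
      atoms[[12]] <- a("C12", "C", c(14.1, 0.1, -0.3))
      atoms[[13]] <- a("O13", "O", c(15.1, -0.85, -0.2))
      bonds <- c(bonds, list(b(8, 9), b(9, 10, 2L), b(9, 11), b(11, 12),
                             b(12, 13)))
      build_ligand("surfactant-like", atoms, bonds, max_torsions)
    })
}

#' Protein pair with a planted complementary interface
#'
#' The receptor is a two-strand groove (chains H and L, 10 pseudo-residues
#' each, C-alpha atoms 3.8 A apart, strands at y = +/- 3.18 A); the ligand
#' is a shorter single strand (chain P, 6 residues) returned already
#' placed in the groove at a half-step register offset, so each ligand
#' residue packs between consecutive residues of both receptor strands
#' with every contact at the softened Lennard-Jones optimum (~3.7 A).
#' That knobs-into-holes double-contact geometry makes the planted pose
#' the global rigid-docking optimum by construction. The planted
#' interface residue sets (4-A cutoff) are returned for assertion.
#'
#' @param seed integer RNG seed.
#' @param jitter coordinate noise sigma in Angstrom.
#' @return list with `receptor`, `ligand` (placed in the planted pose) and
#'   `planted` (list `receptor`, `ligand` of residue keys).
#' @export
make_ppi_pair <- function(seed = 21L, jitter = 0.05) {
  with_private_seed(seed, {
    strand <- function(chain, y, n, z0, res) {
      z <- z0 + 3.8 * (seq_len(n) - 1)
      data.frame(serial = seq_len(n), name = "CA", element = "C",
                 res_name = res, chain_id = chain, res_seq = seq_len(n),
                 i_code = "",
                 x = stats::rnorm(n, 0, jitter),
                 y = y + stats::rnorm(n, 0, jitter),
                 z = z + stats::rnorm(n, 0, jitter),
                 formal_charge = 0L, is_heavy = TRUE,
                 stringsAsFactors = FALSE)
    }
    rec_df <- rbind(strand("H", 3.18, 10L, 0, "GLY"),
                    strand("L", -3.18, 10L, 0, "GLY"))
    rec_df$serial <- seq_len(nrow(rec_df))
    receptor <- new_structure(rec_df)
    lig_df <- strand("P", 0, 6L, 3.8 * 2 + 1.9, "GLY")
    ligand <- new_structure(lig_df)
    planted <- interface_residues(receptor, ligand, cutoff = 4.0)
    list(receptor = receptor, ligand = ligand, planted = planted)
  })
}

#' Synthetic trajectory around a docked pose
#'
#' Builds a multi-frame trajectory of the receptor-ligand complex with
#' Gaussian positional noise. With `hold_contact = TRUE` the ligand is
#' translated along the closest-approach axis whenever the minimum
#' residue-ligand distance would exceed 4 A, so the contact persists in
#' every frame; with `hold_contact = FALSE` the ligand is driven beyond
#' the cutoff for the second half of the frames (first `ceiling(n/2)`
#' frames in contact), giving a persistence of exactly
#' `ceiling(n/2)/n`.
#'
#' @param base receptor structure.
#' @param ligand_pose placed ligand structure (e.g. from a docking pose).
#' @param n_frames number of frames (>= 1).
#' @param noise_sigma per-coordinate Gaussian noise (A).
#' @param hold_contact keep the contact in every frame.
#' @param seed RNG seed.
#' @param residues receptor residue keys defining the monitored contact
#'   (default: the pose's 4-A contact residues).
#' @return `xd_trajectory` with attribute `contact_residues`.
#' @export
make_trajectory <- function(base, ligand_pose, n_frames = 20L,
                            noise_sigma = 0.05, hold_contact = TRUE,
                            seed = 7L, residues = NULL) {
  stopifnot(n_frames >= 1)
  if (is.null(residues)) {
    residues <- contact_residues(base, ligand_pose, cutoff = 4.0)
  }
  if (length(residues) == 0L) stop("pose has no contact residues to monitor", call. = FALSE)
  n_rec <- nrow(base$atoms)
  lig_atoms <- ligand_pose$atoms
  lig_atoms$chain_id <- "X"
  lig_atoms$serial <- n_rec + seq_len(nrow(lig_atoms))
  combined <- new_structure(rbind(base$atoms, lig_atoms))
  keys <- residue_keys(combined, unique_only = FALSE)
  rec_idx <- which(keys %in% residues & combined$atoms$is_heavy)
  lig_idx <- n_rec + which(lig_atoms$is_heavy)
  in_contact_frames <- ceiling(n_frames / 2)
  with_private_seed(seed, {
    frames <- lapply(seq_len(n_frames), function(f) {
      xyz <- atom_coords(combined) +
        matrix(stats::rnorm(3 * nrow(combined$atoms), 0, noise_sigma), ncol = 3)
      adjust <- function(xyz, target, at_most) {
        for (it in 1:8) {
          d2 <- cross_dist2(xyz[rec_idx, , drop = FALSE],
                            xyz[lig_idx, , drop = FALSE])
          d <- sqrt(min(d2))
          done <- if (at_most) d <= target else d >= target
          if (done) break
          pr <- arrayInd(which.min(d2), dim(d2))
          axis <- xyz[lig_idx[pr[2]], ] - xyz[rec_idx[pr[1]], ]
          axis <- axis / sqrt(sum(axis^2))
          xyz[lig_idx, ] <- sweep(xyz[lig_idx, , drop = FALSE], 2,
                                  -(target - d) * axis)
        }
        xyz
      }
      if (hold_contact || f <= in_contact_frames) {
        d <- min(cross_dist2(xyz[rec_idx, , drop = FALSE],
                             xyz[lig_idx, , drop = FALSE]))
        if (sqrt(d) > 4.0) xyz <- adjust(xyz, 3.5, at_most = TRUE)
      } else {
        xyz <- adjust(xyz, 6.0, at_most = FALSE)
      }
      st <- set_atom_coords(combined, xyz)
      st$model_id <- f
      st
    })
    tr <- new_trajectory(frames, frame_interval = 5)
    attr(tr, "contact_residues") <- residues
    tr
  })
}
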