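# Shared builders and independent brute-force oracles. Oracles are written
# from the definitions, not by calling the implementation under test.

atom_df <- function(name, element, x, y, z, res_name = "LIG",
                    chain_id = "X", res_seq = 1L, q = 0L) {
  data.frame(serial = seq_along(name), name = name, element = element,
             res_name = res_name, chain_id = chain_id, res_seq = res_seq,
             i_code = "", x = x, y = y, z = z, formal_charge = q,
             is_heavy = TRUE, stringsAsFactors = FALSE)
}

one_atom <- function(element = "C", xyz = c(0, 0, 0), q = 0L,
                     res_name = "LIG", name = paste0(element, "1")) {
  new_structure(atom_df(name, element, xyz[1], xyz[2], xyz[3],
                        res_name = res_name, q = q))
}

# Random multi-residue structure: n_res residues of 1-3 heavy atoms in a box.
random_structure <- function(seed, n_res = 20, spread = 15) {
  set.seed(seed)
  rows <- list()
  serial <- 0L
  elements <- c("C", "N", "O")
  for (r in seq_len(n_res)) {
    base <- runif(3, 0, spread)
    for (k in seq_len(sample(1:3, 1))) {
      serial <- serial + 1L
      rows[[serial]] <- data.frame(
        serial = serial, name = paste0("A", k),
        element = sample(elements, 1), res_name = "UNK",
        chain_id = sample(c("A", "B"), 1), res_seq = r, i_code = "",
        x = base[1] + rnorm(1), y = base[2] + rnorm(1), z = base[3] + rnorm(1),
        formal_charge = 0L, is_heavy = TRUE, stringsAsFactors = FALSE)
    }
  }
  new_structure(do.call(rbind, rows))
}

# O(N*M) reference scan for contact residues (closed cutoff).
bf_contact_residues <- function(target, probe, cutoff = 4.0) {
  a <- target$atoms[target$atoms$is_heavy, ]
  keys <- paste(a$chain_id, a$res_name, a$res_seq, a$i_code, sep = ":")
  hits <- character(0)
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(probe))) {
      d <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) - probe[j, ])^2))
      if (d <= cutoff) { hits <- c(hits, keys[i]); break }
    }
  }
  unique(hits)
}

# Reference rigid score: all heavy pairs within cutoff, softened LJ plus
# the small-weight screened Coulomb with the 0.5 A clamp.
bf_rigid_score <- function(rec, lig, cfg) {
  ra <- rec$atoms[rec$atoms$is_heavy, ]
  la <- lig$atoms[lig$atoms$is_heavy, ]
  rq <- assign_atom_types(rec)$charge[rec$atoms$is_heavy]
  lq <- assign_atom_types(lig)$charge[lig$atoms$is_heavy]
  e <- 0
  for (i in seq_len(nrow(la))) for (j in seq_len(nrow(ra))) {
    r <- sqrt(sum((c(la$x[i], la$y[i], la$z[i]) - c(ra$x[j], ra$y[j], ra$z[j]))^2))
    if (r <= cfg$pair_cutoff) {
      e <- e + soft_lj(r, cfg$lj)
      if (lq[i] * rq[j] != 0) {
        e <- e + cfg$electrostatic_weight *
          332.0636 * lq[i] * rq[j] / (4 * max(r, 0.5)^2)
      }
    }
  }
  e
}

# Small ligand: linear four-heavy-atom chain (one central rotatable bond).
chain4_ligand <- function() {
  ligand_topology(
    atom_df(c("C1", "C2", "C3", "C4"), rep("C", 4),
            x = c(0, 1.5, 2.25, 3.75), y = c(0, 0, 1.3, 1.3), z = rep(0, 4)),
    data.frame(i = 1:3, j = 2:4, order = 1L), name = "chain4")
}

# Receptor with a single hydrogen-bond acceptor atom at the origin and a
# hydrophobic atom far away (keeps scoring isolated to one pair).
acceptor_target <- function() {
  new_structure(atom_df(c("O", "CA"), c("O", "C"),
                        x = c(0, 50), y = c(0, 50), z = c(0, 50),
                        res_name = "GLY", chain_id = "A", res_seq = c(1L, 2L)))
}

small_ga_cfg <- function(seed = 1L, population = 60L, generations = 3L,
                         n_solutions = 3L) {
  ga_config(population = population, generations = generations,
            n_solutions = n_solutions, refine_iterations = 5L, seed = seed)
}

small_receptor <- function(seed = 42L) {
  make_toy_receptor(seed = seed, n_residues = 12L,
                    pocket = list(donors = 1L, acceptors = 1L,
                                  charged_pos = 0L, charged_neg = 0L))
}
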