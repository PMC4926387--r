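# Energy terms: softened LJ, screened Coulomb, atom typing, pair wells and
# the pose-score decomposition.

test_that("soft_lj reproduces the 12-6 limit and its closed forms", {
  p0 <- soft_lj_params(alpha = 0, sigma = 3.3, epsilon = 0.5)
  expect_equal(soft_lj(3.3, p0), 0)
  expect_equal(soft_lj(2^(1 / 6) * 3.3, p0), -0.5)

  # alpha -> 0 recovers the standard LJ across a fine grid; the oracle is
  # the textbook form written in sigma^6/r^6 so the comparison is not
  # dominated by floating-point noise at the r^-12 wall
  r <- seq(0.2 * 3.3, 4 * 3.3, length.out = 1000)
  x <- 3.3^6 / r^6
  std <- 4 * 0.5 * (x * x - x)
  expect_lt(max(abs(soft_lj(r, p0) - std)), 1e-9)

  # value at r = 0 is 4 eps (1 - alpha) / alpha^2, independent of sigma
  expect_equal(soft_lj(0, soft_lj_params(0.4, 3.3, 0.5)), 7.5)
  expect_equal(soft_lj(0, soft_lj_params(0.4, 0.33, 0.5)), 7.5)
  expect_error(soft_lj(0, p0), "singularity")
})

test_that("soft_lj has a single minimum for alpha in [0, 1)", {
  r <- seq(0.05, 4 * 3.3, length.out = 2000)
  for (alpha in c(0, 0.2, 0.4, 0.8)) {
    v <- soft_lj(r[r > ifelse(alpha == 0, 0.2, 0)],
                 soft_lj_params(alpha, 3.3, 0.5))
    dv <- diff(v)
    sign_changes <- sum(diff(sign(dv[dv != 0])) != 0)
    expect_lte(sign_changes, 1)       # decreasing then increasing
    expect_lt(min(v), 0)
  }
})

test_that("coulomb evaluates the screened form", {
  expect_equal(coulomb(0, 1, 3), 0)
  expect_equal(coulomb(1, -1, 4), -332.0636 / 64)
  expect_equal(coulomb(1, 1, 4), -coulomb(-1, 1, 4))
  expect_error(coulomb(1, 1, 0), "singularity")
})

test_that("assign_atom_types follows the residue templates", {
  s <- new_structure(atom_df(
    c("N", "CA", "C", "O", "CB", "NH1", "NH2", "NE", "OD2"),
    c("N", "C", "C", "O", "C", "N", "N", "N", "O"),
    x = 1:9, y = 0, z = 0,
    res_name = c(rep("ALA", 5), rep("ARG", 3), "ASP"),
    chain_id = "A", res_seq = c(1, 1, 1, 1, 1, 2, 2, 2, 3)))
  t <- assign_atom_types(s)
  expect_true(t$acceptor[4]); expect_false(t$donor[4])       # backbone O
  expect_true(all(t$donor[6:8]))                             # guanidinium N
  expect_true(all(t$charged[6:7])); expect_equal(t$charge[6:7], c(1L, 1L))
  expect_true(t$hydrophobic[5]); expect_false(t$donor[5])    # aliphatic C
  expect_equal(t$charge[9], -1L)                             # Asp carboxylate
  pro <- new_structure(atom_df("N", "N", 0, 0, 0, res_name = "PRO",
                               chain_id = "A", res_seq = 1L))
  expect_false(assign_atom_types(pro)$donor[1])
  expect_warning(assign_atom_types(one_atom("XX")), "unknown element")
})

test_that("pair_energy realises the documented wells and stays continuous", {
  don <- list(donor = TRUE, acceptor = FALSE, charge = 0)
  acc <- list(donor = FALSE, acceptor = TRUE, charge = 0)
  apolar <- list(donor = FALSE, acceptor = FALSE, charge = 0)

  hb <- pair_energy(don, acc, 2.7)
  expect_equal(hb$type, "hbond"); expect_equal(hb$energy, -2.5)
  expect_equal(pair_energy(acc, don, 2.7)$energy, -2.5)   # symmetric
  expect_equal(pair_energy(don, acc, 3.6)$energy, 0)
  st <- pair_energy(apolar, apolar, 4.0)
  expect_equal(st$type, "steric"); expect_equal(st$energy, -0.4)

  # continuity at every knot of both wells
  p <- score_params()
  for (k in unique(c(p$hb_knots, p$st_knots))) {
    lo <- pair_energy(don, acc, max(k - 1e-6, 0))$energy
    hi <- pair_energy(don, acc, k + 1e-6)$energy
    expect_lt(abs(hi - lo), 1e-4)
    lo <- pair_energy(apolar, apolar, max(k - 1e-6, 0))$energy
    hi <- pair_energy(apolar, apolar, k + 1e-6)$energy
    expect_lt(abs(hi - lo), 1e-4)
  }

  # charged pair adds the clamped Coulomb term, labelled electrostatic
  pos <- list(donor = FALSE, acceptor = FALSE, charge = 1)
  neg <- list(donor = FALSE, acceptor = FALSE, charge = -1)
  el <- pair_energy(pos, neg, 4.0)
  expect_equal(el$type, "electrostatic")
  expect_equal(el$energy, -0.4 + coulomb(1, -1, 4.0))
  short <- pair_energy(pos, neg, 1.0)
  expect_equal(short$energy,
               pair_energy(list(donor = FALSE, acceptor = FALSE, charge = 0),
                           neg, 1.0)$energy + coulomb(1, -1, p$elec_min_r))
})

test_that("score_pose isolates a single hydrogen bond", {
  tgt <- acceptor_target()
  probe <- one_atom("N", c(2.7, 0, 0))   # generic N: donor+acceptor, uncharged
  sc <- score_pose(tgt, probe)
  expect_equal(sc$e_inter, -2.5)
  expect_equal(sc$e_total, -2.5)
  expect_equal(sc$e_penal, 0)
})

test_that("score_pose charges the fixed box penalty", {
  tgt <- acceptor_target()
  probe <- one_atom("N", c(2.7, 0, 0))
  box <- list(min = c(10, 10, 10), max = c(20, 20, 20))
  sc <- score_pose(tgt, probe, box = box)
  expect_equal(sc$e_penal, 10000)
  expect_equal(sc$e_total, sc$e_inter + sc$e_intra + 10000 +
                 sc$e_pharma + sc$wp_elec + sc$wp_hb)
})

test_that("e_inter equals the all-pairs brute-force sum", {
  rec <- random_structure(3, n_res = 12)
  set.seed(3)
  lig_atoms <- atom_df(paste0("L", 1:10),
                       sample(c("C", "N", "O"), 10, replace = TRUE),
                       x = runif(10, 0, 15), y = runif(10, 0, 15),
                       z = runif(10, 0, 15))
  lig <- new_structure(lig_atoms)
  sc <- score_pose(rec, lig)

  tt <- assign_atom_types(rec); lt <- assign_atom_types(lig)
  rx <- atom_coords(rec); lx <- atom_coords(lig)
  e <- 0
  p <- score_params()
  for (i in seq_len(nrow(lx))) for (j in seq_len(nrow(rx))) {
    r <- sqrt(sum((lx[i, ] - rx[j, ])^2))
    if (r <= p$inter_cutoff) {
      e <- e + pair_energy(lt[i, ], tt[j, ], r, p)$energy
    }
  }
  expect_equal(sc$e_inter, e, tolerance = 1e-12)
})

test_that("the score decomposition identity holds over random poses", {
  rec <- random_structure(8, n_res = 10)
  lig <- make_ligand("amino-acid-like")
  box <- list(min = c(0, 0, 0), max = c(15, 15, 15))
  set.seed(11)
  for (k in 1:10) {
    ch <- chromosome(runif(3, -5, 20), rnorm(4),
                     runif(length(lig$rotatable), -180, 180))
    pose <- ligand_structure(lig, apply_chromosome(lig, ch))
    sc <- score_pose(rec, pose, box = box, topology = lig)
    expect_identical(sc$e_total,
                     (sc$e_inter + sc$e_intra + sc$e_penal) +
                       sc$e_pharma + (sc$wp_elec + sc$wp_hb))
  }
})
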