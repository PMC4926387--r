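# Trajectory analysis: distances, persistence, RMSD/RMSF.

two_body_frames <- function(gaps) {
  lapply(seq_along(gaps), function(i) {
    new_structure(atom_df(c("CA", "L1"), c("C", "C"),
                          x = c(0, gaps[i]), y = 0, z = 0,
                          res_name = c("GLY", "LIG"),
                          chain_id = c("A", "X"), res_seq = c(1L, 2L)))
  })
}

test_that("min_distance_series reports per-frame minima", {
  tr <- new_trajectory(two_body_frames(c(3, 3)))
  s <- min_distance_series(tr, "A:GLY:1:", "LIG")
  expect_equal(s$values, c(3, 3))

  tr2 <- new_trajectory(two_body_frames(c(3, 5)))
  expect_equal(min_distance_series(tr2, "A:GLY:1:", "LIG")$values, c(3, 5))

  expect_error(min_distance_series(tr, "A:GLY:9:", "LIG"), "matches no")

  # brute-force oracle on a noisy 20-frame fixture
  r <- small_receptor()
  lig <- make_ligand("polyol-like")
  pose <- ligand_structure(lig)
  pose <- set_atom_coords(pose, sweep(atom_coords(pose), 2,
                                      -(r$pocket$center - colMeans(atom_coords(pose)))))
  tr3 <- make_trajectory(r$structure, pose, n_frames = 20L, seed = 7L,
                         noise_sigma = 0.2)
  res_keys <- attr(tr3, "contact_residues")
  s3 <- min_distance_series(tr3, res_keys, "LIG")
  for (f in c(1, 7, 20)) {
    fr <- tr3$frames[[f]]
    keys <- residue_keys(fr, unique_only = FALSE)
    ri <- which(keys %in% res_keys & fr$atoms$is_heavy)
    li <- which(fr$atoms$res_name == "LIG" & fr$atoms$is_heavy)
    mn <- Inf
    for (i in ri) for (j in li) {
      mn <- min(mn, sqrt(sum((atom_coords(fr)[i, ] - atom_coords(fr)[j, ])^2)))
    }
    expect_equal(s3$values[f], mn, tolerance = 1e-12)
  }
})

test_that("contact_persistence uses a closed cutoff and is monotone", {
  expect_equal(contact_persistence(rep(3, 10)), 1.0)
  expect_equal(contact_persistence(rep(c(3, 5), 5)), 0.5)
  expect_equal(contact_persistence(c(4.0, 5.0)), 0.5)   # boundary included
  expect_error(contact_persistence(numeric(0)), "empty")

  set.seed(1)
  v <- runif(50, 2, 7)
  ps <- vapply(seq(2, 7, by = 0.5), function(ct) contact_persistence(v, ct), 0)
  expect_true(all(diff(ps) >= 0))
})

test_that("rmsd_series is zero for identical or rigidly moved frames", {
  r <- small_receptor()
  base <- r$structure
  rot <- orientation_set(12)[[5]]
  frames <- list(base,
                 transform_structure(base, diag(3), c(4, -2, 1)),
                 transform_structure(base, rot, c(1, 2, 3)))
  tr <- new_trajectory(frames)
  rs <- rmsd_series(tr, selection = function(a) a$name == "CA")
  expect_equal(rs, c(0, 0, 0), tolerance = 1e-9)

  # superposed RMSD never exceeds the raw coordinate RMSD
  noisy <- lapply(1:4, function(i) {
    set.seed(i)
    shifted <- transform_structure(base, diag(3), rnorm(3))
    set_atom_coords(shifted, atom_coords(shifted) +
                      matrix(rnorm(3 * nrow(base$atoms), 0, 0.3), ncol = 3))
  })
  trn <- new_trajectory(noisy)
  fitted <- rmsd_series(trn, reference = base)
  ca <- base$atoms$name == "CA"
  raw <- vapply(noisy, function(fr) {
    sqrt(mean(rowSums((atom_coords(fr)[ca, ] - atom_coords(base)[ca, ])^2)))
  }, 0)
  expect_true(all(fitted <= raw + 1e-9))
})

test_that("rmsf matches the closed form on a two-frame fixture", {
  f1 <- new_structure(atom_df(c("CA", "CA"), c("C", "C"),
                              x = c(0, 10), y = 0, z = 0,
                              res_name = "GLY", chain_id = "A", res_seq = 1:2))
  f2 <- f1
  f2$atoms$x[2] <- 10 + 2   # displace residue 2 by 2 A in one frame
  tr <- new_trajectory(list(f1, f2))
  out <- rmsf(tr)
  expect_equal(unname(out["A:GLY:1:"]), 0)
  expect_equal(unname(out["A:GLY:2:"]), 1)   # deviations (+/- 1) around mean
})

test_that("synthetic trajectories realise their planted persistence", {
  r <- small_receptor()
  lig <- make_ligand("polyol-like")
  pose <- ligand_structure(lig)
  pose <- set_atom_coords(pose, sweep(atom_coords(pose), 2,
                                      -(r$pocket$center - colMeans(atom_coords(pose)))))

  hold <- make_trajectory(r$structure, pose, n_frames = 10L,
                          hold_contact = TRUE, seed = 5L)
  s <- min_distance_series(hold, attr(hold, "contact_residues"), "LIG")
  expect_equal(contact_persistence(s), 1.0)

  drift <- make_trajectory(r$structure, pose, n_frames = 20L,
                           hold_contact = FALSE, seed = 5L)
  sd <- min_distance_series(drift, attr(drift, "contact_residues"), "LIG")
  expect_equal(contact_persistence(sd), 0.5)

  still <- make_trajectory(r$structure, pose, n_frames = 5L,
                           noise_sigma = 0, hold_contact = TRUE, seed = 5L)
  for (f in 2:5) {
    expect_identical(atom_coords(still$frames[[f]]),
                     atom_coords(still$frames[[1]]))
  }
})
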