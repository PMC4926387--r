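# Orientation sets, rigid scoring, the docking search, solution clustering
# and interface extraction.

test_that("orientation_set returns valid quasi-uniform rotation sets", {
  expect_identical(orientation_set(1), list(diag(3)))
  os <- orientation_set(60)
  expect_length(os, 60L)
  ok <- vapply(os, function(m) {
    max(abs(crossprod(m) - diag(3))) < 1e-8 && abs(det(m) - 1) < 1e-8
  }, TRUE)
  expect_true(all(ok))

  # brute-force pairwise geodesic scan; for n = 60 the theoretical uniform
  # minimum separation is the icosahedral group's 72 degrees
  ang <- function(a, b) {
    acos(min(1, max(-1, (sum(diag(crossprod(a, b))) - 1) / 2)))
  }
  mn <- Inf
  for (i in 1:59) for (j in (i + 1):60) mn <- min(mn, ang(os[[i]], os[[j]]))
  expect_gte(mn * 180 / pi, 0.8 * 72)

  # generic n: valid, deterministic, identity first
  o17a <- orientation_set(17); o17b <- orientation_set(17)
  expect_identical(o17a, o17b)
  expect_equal(o17a[[1]], diag(3))
  expect_true(all(vapply(o17a, function(m) abs(det(m) - 1) < 1e-8, TRUE)))
  expect_error(orientation_set(0), ">= 1")
})

test_that("rigid_score matches closed forms and the brute-force oracle", {
  cfg <- rigid_dock_config(lj = soft_lj_params(alpha = 0, sigma = 3.3,
                                               epsilon = 0.5))
  a <- one_atom("C", c(0, 0, 0)); b <- one_atom("C", c(2^(1 / 6) * 3.3, 0, 0))
  expect_equal(rigid_score(a, b, cfg), -0.5)
  far <- one_atom("C", c(50, 0, 0))
  expect_equal(rigid_score(a, far, cfg), 0)

  cfg2 <- rigid_dock_config()
  r1 <- random_structure(11, n_res = 10)
  r2 <- transform_structure(random_structure(12, n_res = 10),
                            diag(3), c(6, 0, 0))
  expect_equal(rigid_score(r1, r2, cfg2), bf_rigid_score(r1, r2, cfg2),
               tolerance = 1e-10)
})

test_that("rigid_dock finds the single-pair optimum and respects n_keep", {
  cfg <- rigid_dock_config(n_orientations = 1L,
                           lj = soft_lj_params(alpha = 0, sigma = 3.3,
                                               epsilon = 0.5))
  rec <- one_atom("C", c(0, 0, 0))
  lig <- one_atom("C", c(10, 0, 0))
  res <- rigid_dock(rec, lig, cfg)
  sep <- sqrt(sum(atom_coords(rigid_solution_pose(res, 1))^2))
  expect_lt(abs(sep - 2^(1 / 6) * 3.3), cfg$grid_spacing / 2)

  res1 <- rigid_dock(rec, lig, rigid_dock_config(n_orientations = 1L, n_keep = 1L))
  expect_length(res1$solutions, 1L)
  expect_error(rigid_dock(rec, new_structure(lig$atoms[0, , drop = FALSE])),
               "at least one atom")
})

test_that("rigid_dock output is sorted and beats the coarse exhaustive oracle", {
  pair <- make_ppi_pair(seed = 21L)
  cfg <- rigid_dock_config(n_orientations = 12L, grid_spacing = 2.0,
                           n_keep = 40L, margin = 8.0)
  res <- rigid_dock(pair$receptor, pair$ligand, cfg)
  en <- res$summary$energy
  expect_true(!is.unsorted(en))

  # independent coarse oracle: exact pairwise score at every lattice pose
  rots <- orientation_set(12L)
  rx <- atom_coords(pair$receptor, heavy_only = TRUE)
  lx <- atom_coords(pair$ligand, heavy_only = TRUE)
  ctr <- colMeans(lx)
  off0 <- sweep(lx, 2, ctr)
  gx <- seq(min(rx[, 1]) - 8, max(rx[, 1]) + 8 + 1, by = 2)
  gy <- seq(min(rx[, 2]) - 8, max(rx[, 2]) + 8 + 1, by = 2)
  gz <- seq(min(rx[, 3]) - 8, max(rx[, 3]) + 8 + 1, by = 2)
  best <- Inf
  n_poses <- 0L
  for (rot in rots) {
    off <- off0 %*% t(rot)
    # factorised per-axis distances: for each atom pair, r^2(t) splits into
    # per-axis quadratic terms over the translation lattice
    for (tx in gx) for (ty in gy) {
      dx2 <- outer(off[, 1] + tx, rx[, 1], "-")^2 +
             outer(off[, 2] + ty, rx[, 2], "-")^2
      for (tz in gz) {
        d2 <- dx2 + outer(off[, 3] + tz, rx[, 3], "-")^2
        n_poses <- n_poses + 1L
        pr <- d2[d2 <= 64]
        if (length(pr)) {
          e <- sum(soft_lj(sqrt(pr), cfg$lj))
          if (e < best) best <- e
        }
      }
    }
  }
  expect_lte(n_poses, 1e5)   # oracle stays desk-scale
  expect_lte(en[1], best + 1e-6)
})

test_that("cluster_solutions replays the greedy leader rule", {
  pair <- make_ppi_pair(seed = 4L)
  cfg <- rigid_dock_config(n_orientations = 12L, grid_spacing = 1.5,
                           n_keep = 25L)
  res <- rigid_dock(pair$receptor, pair$ligand, cfg)
  ids <- res$summary$cluster_id
  expect_true(all(ids >= 1))
  expect_lte(length(unique(ids)), length(res$solutions))

  # independent replay of the rule on the placed C-alpha coordinates
  coords <- lapply(seq_along(res$solutions), function(i) {
    atom_coords(rigid_solution_pose(res, i))
  })
  replay <- integer(length(coords)); leaders <- integer(0)
  for (i in seq_along(coords)) {
    hit <- 0L
    for (ci in seq_along(leaders)) {
      rmsd <- sqrt(mean(rowSums((coords[[i]] - coords[[leaders[ci]]])^2)))
      if (rmsd <= cfg$cluster_threshold) { hit <- ci; break }
    }
    if (hit == 0L) { leaders <- c(leaders, i); hit <- length(leaders) }
    replay[i] <- hit
  }
  expect_identical(as.integer(ids), replay)

  # degenerate cases
  res$solutions <- res$solutions[c(1, 1, 1)]
  expect_equal(as.integer(cluster_solutions(res, threshold = 3)), c(1L, 1L, 1L))
  res$solutions <- res$solutions[1:2]
  res$solutions[[2]]$translation <- res$solutions[[2]]$translation + 50
  res$solutions[[2]]$energy <- res$solutions[[1]]$energy + 1
  expect_equal(as.integer(cluster_solutions(res, threshold = 3)), c(1L, 2L))
  res$solutions[[2]]$energy <- res$solutions[[1]]$energy - 5
  expect_error(cluster_solutions(res), "sorted")
})

test_that("interface_residues is symmetric and matches brute force", {
  a <- random_structure(9, n_res = 8)
  b <- transform_structure(random_structure(10, n_res = 8), diag(3), c(10, 0, 0))
  iface <- interface_residues(a, b)
  swapped <- interface_residues(b, a)
  expect_setequal(iface$receptor, swapped$ligand)
  expect_setequal(iface$ligand, swapped$receptor)
  expect_setequal(iface$receptor,
                  bf_contact_residues(a, atom_coords(b, heavy_only = TRUE)))
  expect_setequal(iface$ligand,
                  bf_contact_residues(b, atom_coords(a, heavy_only = TRUE)))

  far <- transform_structure(b, diag(3), c(500, 0, 0))
  empty <- interface_residues(a, far)
  expect_length(empty$receptor, 0)
  expect_length(empty$ligand, 0)

  one <- new_structure(atom_df("CA", "C", 0, 0, 0, res_name = "GLY",
                               chain_id = "A"))
  two <- new_structure(atom_df("CA", "C", 3.5, 0, 0, res_name = "GLY",
                               chain_id = "B"))
  pairi <- interface_residues(one, two)
  expect_identical(pairi$receptor, "A:GLY:1:")
  expect_identical(pairi$ligand, "B:GLY:1:")
})
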