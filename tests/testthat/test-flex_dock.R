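# Ligand topology handling, chromosome realisation and the genetic
# algorithm's contracts.

test_that("detect_rotatable_bonds applies the single/acyclic/non-terminal rule", {
  two <- ligand_topology(atom_df(c("C1", "C2"), c("C", "C"),
                                 x = c(0, 1.5), y = 0, z = 0),
                         data.frame(i = 1, j = 2, order = 1L))
  expect_length(two$rotatable, 0)

  ch4 <- chain4_ligand()
  expect_identical(ch4$rotatable, 2L)   # only the central bond

  # independent enumeration for the arginine-like topology: single-order
  # bridge bonds between atoms of degree >= 2
  lig <- make_ligand("amino-acid-like", max_torsions = 99L)
  deg <- tabulate(c(lig$bonds$i, lig$bonds$j), nbins = nrow(lig$atoms))
  connected_without <- function(b) {
    n <- nrow(lig$atoms)
    adj <- lapply(seq_len(n), function(i) integer(0))
    for (k in seq_len(nrow(lig$bonds))) {
      if (k == b) next
      i <- lig$bonds$i[k]; j <- lig$bonds$j[k]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
    seen <- logical(n); queue <- 1L; seen[1] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    all(seen)
  }
  oracle <- which(vapply(seq_len(nrow(lig$bonds)), function(b) {
    lig$bonds$order[b] == 1L && deg[lig$bonds$i[b]] >= 2 &&
      deg[lig$bonds$j[b]] >= 2 && !connected_without(b)
  }, TRUE))
  expect_setequal(lig$rotatable, oracle)
  capped <- make_ligand("amino-acid-like", max_torsions = 5L)
  expect_length(capped$rotatable, min(5L, length(oracle)))

  disconnected <- atom_df(c("C1", "C2", "C3"), rep("C", 3), x = c(0, 1.5, 9), y = 0, z = 0)
  expect_error(ligand_topology(disconnected, data.frame(i = 1, j = 2, order = 1L)),
               "connected")
})

test_that("apply_chromosome is exact for the zero chromosome and rigid bonds", {
  lig <- make_ligand("surfactant-like")
  ref <- unname(as.matrix(lig$atoms[, c("x", "y", "z")]))
  zero <- chromosome(torsions = rep(0, length(lig$rotatable)))
  expect_equal(unname(apply_chromosome(lig, zero)), ref, tolerance = 1e-12)

  set.seed(9)
  bl <- function(x) sqrt(rowSums((x[lig$bonds$i, ] - x[lig$bonds$j, ])^2))
  for (k in 1:5) {
    ch <- chromosome(rnorm(3, 0, 5), rnorm(4),
                     runif(length(lig$rotatable), -180, 180))
    x <- apply_chromosome(lig, ch)
    expect_lt(max(abs(bl(x) - bl(ref))), 1e-6)
  }

  expect_error(apply_chromosome(lig, chromosome(torsions = 0)), "torsions")
})

test_that("a 180-degree torsion matches analytic dihedral geometry", {
  lig <- chain4_ligand()
  ref <- as.matrix(lig$atoms[, c("x", "y", "z")])
  rot <- apply_chromosome(lig, chromosome(torsions = 180))
  # independent oracle: rotate atom 4 about the C2->C3 axis by 180 degrees
  axis <- ref[3, ] - ref[2, ]; axis <- axis / sqrt(sum(axis^2))
  v <- ref[4, ] - ref[3, ]
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  rodrigues <- v * cos(pi) + cross3(axis, v) * sin(pi) +
    axis * sum(axis * v) * (1 - cos(pi))
  expected4 <- ref[3, ] + rodrigues
  # implementation recentres after torsions; compare internal geometry
  d14 <- function(x) sqrt(sum((x[4, ] - x[1, ])^2))
  expect_equal(d14(rot), sqrt(sum((expected4 - ref[1, ])^2)), tolerance = 1e-9)
  expect_false(isTRUE(all.equal(d14(rot), d14(ref))))
})

test_that("ga_dock is reproducible, monotone and respects its bounds", {
  rec <- small_receptor()
  lig <- make_ligand("polyol-like")
  cfg <- small_ga_cfg(seed = 4L)

  a <- ga_dock(rec$structure, lig, cfg)
  b <- ga_dock(rec$structure, lig, cfg)
  expect_identical(lapply(a$poses, `[[`, "coords"),
                   lapply(b$poses, `[[`, "coords"))
  expect_identical(vapply(a$poses, function(p) p$score$e_total, 0),
                   vapply(b$poses, function(p) p$score$e_total, 0))

  expect_true(all(diff(a$best_by_generation) <= 1e-12))

  en <- vapply(a$poses, function(p) p$score$e_total, 0)
  expect_true(!is.unsorted(en))
  expect_true(all(abs(en) <= cfg$energy_bound))

  if (length(a$poses) >= 2) {
    for (i in 1:(length(a$poses) - 1)) for (j in (i + 1):length(a$poses)) {
      heavy <- lig$atoms$is_heavy
      expect_gte(excidock:::heavy_rmsd(a$poses[[i]]$coords[heavy, ],
                                       a$poses[[j]]$coords[heavy, ]),
                 cfg$site_rmsd)
    }
  }

  g0 <- ga_dock(rec$structure, lig,
                small_ga_cfg(seed = 4L, generations = 0L))
  expect_gte(length(g0$poses), 1L)
  expect_length(g0$best_by_generation, 1L)
  expect_error(ga_config(generations = -1L), "generations")
})

test_that("dock_panel derives distinct per-ligand seeds and keeps order", {
  rec <- small_receptor()
  ligs <- list(a = make_ligand("polyol-like"), b = make_ligand("amino-acid-like"))
  cfg <- small_ga_cfg(seed = 10L)
  out <- dock_panel(rec$structure, ligs, cfg)
  expect_named(out, c("a", "b"))
  expect_equal(vapply(out, `[[`, 0L, "seed"), c(a = 11L, b = 12L))

  cfg1 <- cfg; cfg1$seed <- 11L
  solo <- ga_dock(rec$structure, ligs$a, cfg1)
  expect_identical(lapply(out$a$poses, `[[`, "coords"),
                   lapply(solo$poses, `[[`, "coords"))
  expect_error(dock_panel(rec$structure, list(), cfg), "empty")
})
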