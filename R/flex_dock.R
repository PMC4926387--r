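# Blind flexible-ligand docking over the whole protein surface.
#
# A generational genetic algorithm optimises the empirical score over
# translation, rigid orientation and active torsions. The search box is the
# receptor bounding box plus a margin, so no binding-site prior enters the
# search. After the final generation the population is deduplicated into
# distinct binding sites by greedy leader clustering on heavy-atom RMSD.

#' Genetic-algorithm configuration for flexible docking
#'
#' Defaults follow the accurate-docking regime for small-excipient screens:
#' population 800 evolved for 10 generations to yield 10 reported
#' solutions, at most 100 distinct binding sites, a 5-torsion ligand
#' flexibility cap and a 100 kcal/mol magnitude bound on reported energies
#' (scores beyond that magnitude are unphysical and discarded).
#'
#' @param population population size (> 0).
#' @param generations number of generations (>= 0; 0 scores the seeded
#'   initial population only).
#' @param n_solutions number of poses returned.
#' @param max_sites maximum number of distinct binding sites retained.
#' @param energy_bound magnitude cap on reported e_total (kcal/mol).
#' @param max_torsions rotatable-bond cap applied to the ligand.
#' @param crossover_rate,mutation_rate,elitism GA operator settings
#'   (tournament size is fixed at 2).
#' @param site_rmsd heavy-atom RMSD (A) below which two poses are the same
#'   binding site.
#' @param box_margin margin (A) added to the receptor bounding box to form
#'   the search box.
#' @param refine_iterations cap on local-refinement sweeps applied to each
#'   reported solution after the GA (0 disables refinement). Refinement is
#'   a deterministic coordinate descent over translation, orientation and
#'   torsions; it can only lower a pose's energy.
#' @param seed RNG seed; every run is fully reproducible from it.
#' @return list of class `xd_ga_config`.
#' @export
ga_config <- function(population = 800L, generations = 10L,
                      n_solutions = 10L, max_sites = 100L,
                      energy_bound = 100, max_torsions = 5L,
                      crossover_rate = 0.7, mutation_rate = 0.1,
                      elitism = 2L, site_rmsd = 2.0, box_margin = 5.0,
                      refine_iterations = 120L, seed = 1L) {
  stopifnot(population > 0, n_solutions >= 1, max_sites >= 1,
            energy_bound > 0, crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1, elitism >= 0)
  if (generations < 0) stop("generations must be >= 0", call. = FALSE)
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 n_solutions = as.integer(n_solutions),
                 max_sites = as.integer(max_sites),
                 energy_bound = energy_bound,
                 max_torsions = as.integer(max_torsions),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elitism = as.integer(elitism),
                 site_rmsd = site_rmsd, box_margin = box_margin,
                 refine_iterations = as.integer(refine_iterations),
                 seed = as.integer(seed)),
            class = "xd_ga_config")
}

# Mutation scales: 1 A translation, 15 deg orientation, 30 deg torsion.
GA_SIGMA_T <- 1.0
GA_SIGMA_O <- 15
GA_SIGMA_TOR <- 30

random_chromosome <- function(box, ref_centroid, n_tor) {
  point <- box$min + stats::runif(3) * (box$max - box$min)
  chromosome(translation = point - ref_centroid,
             orientation = random_quat(),
             torsions = stats::runif(n_tor, -180, 180))
}

# Surface-shell seeding: place the ligand centroid a short random distance
# off a random receptor heavy atom. Blind (no binding-site prior) but
# concentrates the initial population where contacts are possible, as
# whole-surface docking engines do.
surface_chromosome <- function(tgt, box, ref_centroid, n_tor) {
  a <- tgt$coords[sample.int(nrow(tgt$coords), 1L), ]
  dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
  point <- pmin(pmax(a + stats::runif(1, 3.0, 6.0) * dir, box$min), box$max)
  chromosome(translation = point - ref_centroid,
             orientation = random_quat(),
             torsions = stats::runif(n_tor, -180, 180))
}

crossover_chromosomes <- function(a, b) {
  u <- stats::runif(1)
  chromosome(
    translation = a$translation + u * (b$translation - a$translation),
    orientation = quat_slerp(a$orientation, b$orientation, u),
    torsions = wrap_angle(a$torsions + u * wrap_angle(b$torsions - a$torsions))
  )
}

mutate_chromosome <- function(c, rate) {
  t <- c$translation
  for (ax in 1:3) if (stats::runif(1) < rate) t[ax] <- t[ax] + stats::rnorm(1, 0, GA_SIGMA_T)
  q <- c$orientation
  if (stats::runif(1) < rate) {
    axis <- stats::rnorm(3)
    q <- quat_mult(axis_angle_quat(axis, stats::rnorm(1, 0, GA_SIGMA_O)), q)
  }
  tor <- c$torsions
  for (k in seq_along(tor)) {
    if (stats::runif(1) < rate) tor[k] <- tor[k] + stats::rnorm(1, 0, GA_SIGMA_TOR)
  }
  chromosome(t, q, tor)
}

#' Blind flexible docking of one ligand by genetic algorithm
#'
#' Minimises the empirical pose score over the whole receptor surface
#' (search box = receptor bounding box + `box_margin`). Tournament
#' selection of size 2, arithmetic crossover on translation, spherical
#' interpolation on orientation, per-gene Gaussian mutation and elitism.
#' After the final generation, the population is sorted by energy, scores
#' with magnitude above `energy_bound` are discarded, poses are thinned to
#' distinct binding sites (greedy leader clustering, heavy-atom RMSD
#' threshold `site_rmsd`), at most `max_sites` sites are retained and the
#' best `n_solutions` are returned. Fully reproducible from `cfg$seed`.
#'
#' @param target structure or prepared target.
#' @param ligand ligand topology from [ligand_topology()] or [make_ligand()].
#' @param cfg configuration from [ga_config()].
#' @param params score constants from [score_params()].
#' @return object of class `xd_pose_list`: list with `poses` (each a list
#'   holding `coords`, `structure`, `chromosome`, `score`), `best_by_generation`,
#'   `ligand`, `box`, `seed`.
#' @export
ga_dock <- function(target, ligand, cfg = ga_config(), params = score_params()) {
  tgt <- as_target(target)
  box <- structure_bbox(tgt$structure, margin = cfg$box_margin)
  ctx <- ligand_score_ctx(ligand_structure(ligand), ligand, params)
  ref <- as.matrix(ligand$atoms[, c("x", "y", "z")])
  heavy <- ligand$atoms$is_heavy
  ref_centroid <- colMeans(ref)
  n_tor <- length(ligand$rotatable)

  eval_chrom <- function(ch) {
    xyz <- apply_chromosome(ligand, ch, ref)
    sc <- score_pose_core(tgt, xyz[heavy, , drop = FALSE], ctx, box, params)
    list(chrom = ch, xyz = xyz, score = sc)
  }

  # deterministic coordinate descent on one chromosome (bounded sweeps)
  refine_chrom <- function(p, max_iter) {
    if (max_iter <= 0L) return(p)
    best <- p
    for (it in seq_len(max_iter)) {
      improved <- FALSE
      ch <- best$chrom
      for (step in c(1.0, 0.5, 0.25)) for (ax in 1:3) for (s in c(-1, 1)) {
        t2 <- ch$translation; t2[ax] <- t2[ax] + s * step
        cand <- eval_chrom(chromosome(t2, ch$orientation, ch$torsions))
        if (cand$score$e_total < best$score$e_total - 1e-9) {
          best <- cand; ch <- best$chrom; improved <- TRUE
        }
      }
      for (ang in c(20, 10, 5)) for (ax in 1:3) for (s in c(-1, 1)) {
        axis <- numeric(3); axis[ax] <- 1
        q2 <- quat_mult(axis_angle_quat(axis, s * ang), ch$orientation)
        cand <- eval_chrom(chromosome(ch$translation, q2, ch$torsions))
        if (cand$score$e_total < best$score$e_total - 1e-9) {
          best <- cand; ch <- best$chrom; improved <- TRUE
        }
      }
      for (k in seq_along(ch$torsions)) for (dtor in c(-30, 30, -15, 15)) {
        tor2 <- ch$torsions; tor2[k] <- tor2[k] + dtor
        cand <- eval_chrom(chromosome(ch$translation, ch$orientation, tor2))
        if (cand$score$e_total < best$score$e_total - 1e-9) {
          best <- cand; ch <- best$chrom; improved <- TRUE
        }
      }
      if (!improved) break
    }
    best
  }

  with_private_seed(cfg$seed, {
    # half the initial population uniform in the box, half on the surface
    pop <- lapply(seq_len(cfg$population), function(i) {
      ch <- if (i %% 2L == 0L) {
        surface_chromosome(tgt, box, ref_centroid, n_tor)
      } else {
        random_chromosome(box, ref_centroid, n_tor)
      }
      eval_chrom(ch)
    })
    energies <- vapply(pop, function(p) p$score$e_total, 0)
    best_by_gen <- min(energies)
    for (gen in seq_len(cfg$generations)) {
      ord <- order(energies)
      elite <- pop[ord[seq_len(min(cfg$elitism, length(pop)))]]
      offspring <- vector("list", cfg$population - length(elite))
      for (k in seq_along(offspring)) {
        pick <- function() {
          ij <- sample.int(cfg$population, 2L, replace = TRUE)
          if (energies[ij[1]] <= energies[ij[2]]) pop[[ij[1]]] else pop[[ij[2]]]
        }
        pa <- pick(); pb <- pick()
        child <- if (stats::runif(1) < cfg$crossover_rate) {
          crossover_chromosomes(pa$chrom, pb$chrom)
        } else {
          pa$chrom
        }
        offspring[[k]] <- eval_chrom(mutate_chromosome(child, cfg$mutation_rate))
      }
      pop <- c(elite, offspring)
      energies <- vapply(pop, function(p) p$score$e_total, 0)
      best_by_gen <- c(best_by_gen, min(energies))
    }

    ord <- order(energies)
    keep_idx <- ord[abs(energies[ord]) <= cfg$energy_bound]
    leaders <- list()
    for (i in keep_idx) {
      xi <- pop[[i]]$xyz[heavy, , drop = FALSE]
      dup <- FALSE
      for (ld in leaders) {
        if (heavy_rmsd(xi, ld$xyz[heavy, , drop = FALSE]) <= cfg$site_rmsd) {
          dup <- TRUE; break
        }
      }
      if (!dup) {
        leaders[[length(leaders) + 1L]] <- pop[[i]]
        if (length(leaders) >= cfg$max_sites) break
      }
    }
    if (length(leaders) == 0L) {
      warning("no pose survived the energy bound; returning empty pose list",
              call. = FALSE)
    }
    leaders <- leaders[seq_len(min(cfg$n_solutions, length(leaders)))]
    # polish the reported solutions; refinement only lowers energies, and
    # poses that converge onto the same site are re-deduplicated
    if (cfg$refine_iterations > 0L && length(leaders) > 0L) {
      leaders <- lapply(leaders, refine_chrom, max_iter = cfg$refine_iterations)
      leaders <- leaders[order(vapply(leaders, function(p) p$score$e_total, 0))]
      dedup <- list()
      for (p in leaders) {
        xi <- p$xyz[heavy, , drop = FALSE]
        if (!any(vapply(dedup, function(d)
          heavy_rmsd(xi, d$xyz[heavy, , drop = FALSE]) <= cfg$site_rmsd, TRUE))) {
          dedup[[length(dedup) + 1L]] <- p
        }
      }
      leaders <- dedup
    }
    poses <- lapply(seq_along(leaders), function(i) {
      p <- leaders[[i]]
      list(id = i,
           coords = p$xyz,
           structure = ligand_structure(ligand, p$xyz),
           chromosome = p$chrom,
           score = p$score)
    })
    structure(list(poses = poses,
                   best_by_generation = best_by_gen,
                   ligand = ligand$name, box = box, seed = cfg$seed),
              class = "xd_pose_list")
  })
}

#' @export
print.xd_pose_list <- function(x, ...) {
  cat(sprintf("<%d docking pose(s) for '%s' (seed %d)>\n",
              length(x$poses), x$ligand, x$seed))
  for (p in x$poses) {
    cat(sprintf("  pose %d: e_total %.3f\n", p$id, p$score$e_total))
  }
  invisible(x)
}

#' Dock a panel of ligands
#'
#' Runs [ga_dock()] once per ligand with per-ligand seeds derived
#' deterministically from `cfg$seed` plus the ligand index; input order is
#' preserved in the output.
#'
#' @param target structure or prepared target.
#' @param ligands non-empty list of ligand topologies (names are taken
#'   from the topologies when the list is unnamed).
#' @param cfg base configuration from [ga_config()].
#' @param params score constants.
#' @return named list of `xd_pose_list`, one per ligand.
#' @export
dock_panel <- function(target, ligands, cfg = ga_config(), params = score_params()) {
  if (length(ligands) == 0L) stop("ligand panel must not be empty", call. = FALSE)
  tgt <- as_target(target)
  nms <- names(ligands) %||% vapply(ligands, function(l) l$name, "")
  if (is.null(names(ligands))) nms <- vapply(ligands, function(l) l$name, "")
  out <- lapply(seq_along(ligands), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i
    pl <- ga_dock(tgt, ligands[[i]], cfg_i, params)
    pl$ligand <- nms[i]   # panel name labels the excipient in reports
    pl
  })
  names(out) <- nms
  out
}
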