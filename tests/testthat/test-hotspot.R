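# Interaction maps, spot assignment and hotspot consolidation.

test_that("interaction_map classifies contact types deterministically", {
  tgt <- new_structure(atom_df(
    c("O", "OD2", "CB"), c("O", "O", "C"),
    x = c(0, 20, 40), y = 0, z = 0,
    res_name = c("GLY", "ASP", "ALA"), chain_id = "A", res_seq = 1:3))

  hb <- interaction_map(tgt, one_atom("N", c(2.9, 0, 0)))
  expect_equal(hb$type, "hbond")
  expect_equal(hb$residue, "A:GLY:1:")
  expect_equal(hb$distance, 2.9)

  elec <- interaction_map(tgt, one_atom("N", c(23.2, 0, 0), q = 1L))
  elec <- elec[elec$residue == "A:ASP:2:", ]
  expect_equal(elec$type, "electrostatic")

  hyd <- interaction_map(tgt, one_atom("C", c(43.4, 0, 0)))
  expect_equal(hyd$type, "hydrophobic")
  expect_equal(hyd$residue, "A:ALA:3:")

  # map entries always nest inside the 4-A contact set
  r <- make_toy_receptor(seed = 3L, n_residues = 14L,
                         pocket = list(donors = 2L, acceptors = 1L))
  probe <- one_atom("N", r$pocket$center)
  m <- interaction_map(r$structure, probe)
  expect_true(all(m$residue %in%
                    contact_residues(r$structure, atom_coords(probe))))
  expect_true(all(m$distance <= 3.5))
})

feat <- function(excipient, id, e, contacts, centroid) {
  list(excipient = excipient, pose_id = id, e_total = e,
       contacts = contacts, centroid = centroid)
}

test_that("assign_spots groups by shared residues or proximity, transitively", {
  f <- list(
    feat("x", 1L, -5, c("A:GLY:1:", "A:GLY:2:"), c(0, 0, 0)),
    feat("x", 2L, -4, c("A:GLY:2:", "A:GLY:3:"), c(30, 0, 0)),   # shares res 2
    feat("x", 3L, -3, c("A:GLY:9:"), c(31, 0, 0)),               # near pose 2
    feat("x", 4L, -8, c("A:GLY:20:"), c(100, 0, 0))              # isolated
  )
  sp <- assign_spots(f)
  expect_equal(sp[1], sp[2])          # shared residue
  expect_equal(sp[2], sp[3])          # centroid proximity
  expect_equal(sp[1], sp[3])          # transitivity
  expect_false(sp[4] == sp[1])
  # labels ordered by best member energy: isolated pose has e -8 -> spot 1
  expect_equal(sp[4], 1L)

  two <- assign_spots(list(
    feat("x", 1L, -5, "A:GLY:1:", c(0, 0, 0)),
    feat("x", 2L, -4, "A:GLY:9:", c(30, 0, 0))))
  expect_equal(sort(unique(two)), c(1L, 2L))
  expect_error(assign_spots(list()), "at least one")
})

test_that("spot_table is sorted by energy within excipient", {
  f <- list(
    feat("arg", 1L, -15.5, "A:GLY:1:", c(0, 0, 0)),
    feat("arg", 2L, -25.0, "A:GLY:1:", c(1, 0, 0)),
    feat("arg", 3L, -19.8, "A:GLY:9:", c(30, 0, 0)),
    feat("arg", 4L, -15.9, "A:GLY:20:", c(60, 0, 0)),
    feat("arg", 5L, -22.7, "A:GLY:21:", c(61, 0, 0))
  )
  tab <- spot_table(f)
  expect_equal(nrow(tab), 5L)
  expect_equal(length(unique(tab$spot)), 3L)
  expect_true(all(diff(tab$e_total) >= 0))

  one <- spot_table(f[1])
  expect_equal(nrow(one), 1L)
})

test_that("consolidate_hotspots merges across excipients and partitions poses", {
  shared <- c("A:ASN:5:", "A:ASN:6:")
  mk <- function(exc, e, contacts, centroid) {
    excidock:::make_spot(list(feat(exc, 1L, e, contacts, centroid)))
  }
  # three excipients sharing a pocket -> exactly one hotspot
  spots <- list(list(mk("a", -10, shared, c(0, 0, 0))),
                list(mk("b", -12, shared[1], c(1, 0, 0))),
                list(mk("c", -8, c(shared[2], "A:GLY:9:"), c(2, 0, 0))))
  hs <- consolidate_hotspots(spots)
  expect_length(hs, 1L)
  expect_setequal(hs[[1]]$excipients, c("a", "b", "c"))
  expect_equal(hs[[1]]$best_energy, -12)
  expect_setequal(hs[[1]]$residues, c(shared, "A:GLY:9:"))

  # disjoint spots stay separate, ordered by best energy
  spots2 <- list(list(mk("a", -10, "A:GLY:1:", c(0, 0, 0))),
                 list(mk("b", -12, "A:GLY:30:", c(100, 0, 0))),
                 list(mk("c", -8, "A:GLY:60:", c(200, 0, 0))))
  hs2 <- consolidate_hotspots(spots2)
  expect_length(hs2, 3L)
  expect_equal(vapply(hs2, `[[`, 0, "best_energy"), c(-12, -10, -8))
  expect_equal(vapply(hs2, `[[`, 0L, "id"), 1:3)

  # every member pose appears in exactly one hotspot
  members <- do.call(rbind, lapply(hs2, `[[`, "members"))
  expect_equal(nrow(members), 3L)
  expect_false(any(duplicated(members[, c("excipient", "pose_id")])))

  # idempotence: consolidating the output changes nothing
  hs3 <- consolidate_hotspots(hs2)
  expect_equal(lapply(hs3, `[[`, "residues"), lapply(hs2, `[[`, "residues"))
  expect_equal(vapply(hs3, `[[`, 0, "best_energy"),
               vapply(hs2, `[[`, 0, "best_energy"))
})

test_that("hotspot residue sets are the union of member contact sets", {
  r <- small_receptor()
  lig <- make_ligand("polyol-like")
  pl <- ga_dock(r$structure, lig, small_ga_cfg(seed = 2L))
  sp <- excipient_spots(r$structure, pl)
  hs <- consolidate_hotspots(list(sp))
  feats <- excidock:::pose_features(r$structure, pl)
  all_contacts <- sort(unique(unlist(lapply(feats, `[[`, "contacts"))))
  expect_setequal(sort(unique(unlist(lapply(hs, `[[`, "residues")))), all_contacts)
  n_members <- sum(vapply(hs, function(h) nrow(h$members), 0L))
  expect_equal(n_members, length(pl$poses))
})

test_that("residue_ranges compresses runs per chain", {
  keys <- c("H:LYS:43:", "H:SER:44:", "H:GLY:45:", "H:VAL:46:", "H:TRP:47:",
            "H:ARG:67:", "L:ILE:1:", "L:THR:3:", "L:TRP:5:")
  rng <- residue_ranges(keys)
  expect_equal(unname(rng["H"]), "Lys43-Trp47, Arg67")
  expect_equal(unname(rng["L"]), "Ile1-Trp5")  # gaps of one are bridged
  expect_equal(residue_ranges("A:ALA:7:"), c(A = "Ala7"))
})
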