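# From ranked poses to interaction maps, binding spots and consolidated
# cross-excipient hotspots.

#' Typed interaction map of one pose
#'
#' For every receptor-residue / ligand heavy-atom pair within `cutoff`,
#' the contact is classified: oppositely charged atoms are electrostatic
#' (a salt bridge outranks its hydrogen-bond reading); otherwise a
#' donor-acceptor pair at 2.0-3.5 A is a hydrogen bond; anything else is
#' hydrophobic. One entry is kept per (residue, type), at the minimum
#' distance.
#'
#' @param target structure or prepared target.
#' @param pose placed ligand structure.
#' @param cutoff map cutoff in Angstrom (default 3.5).
#' @param hb_min,hb_max donor-acceptor distance window for hydrogen bonds.
#' @return data.frame with `residue`, `type`, `distance`, sorted by
#'   residue appearance then type.
#' @export
interaction_map <- function(target, pose, cutoff = 3.5,
                            hb_min = 2.0, hb_max = 3.5) {
  tgt <- as_target(target)
  types <- assign_atom_types(pose)
  heavy <- pose$atoms$is_heavy
  lx <- atom_coords(pose)[heavy, , drop = FALSE]
  ld <- types$donor[heavy]; la <- types$acceptor[heavy]; lq <- types$charge[heavy]
  d2 <- cross_dist2(lx, tgt$coords)
  pair <- which(d2 <= cutoff^2 + 1e-12)
  if (length(pair) == 0L) {
    return(data.frame(residue = character(0), type = character(0),
                      distance = numeric(0)))
  }
  li <- (pair - 1L) %% nrow(lx) + 1L
  ti <- (pair - 1L) %/% nrow(lx) + 1L
  r <- sqrt(d2[pair])
  elec <- lq[li] * tgt$charge[ti] < 0
  hb <- !elec & ((ld[li] & tgt$acceptor[ti]) | (tgt$donor[ti] & la[li])) &
        r >= hb_min & r <= hb_max
  type <- ifelse(hb, "hbond", ifelse(elec, "electrostatic", "hydrophobic"))
  df <- data.frame(residue = tgt$res_keys[ti], type = type, distance = r,
                   stringsAsFactors = FALSE)
  df <- df[order(df$distance), ]
  df <- df[!duplicated(df[, c("residue", "type")]), ]
  df[order(match(df$residue, tgt$res_keys), df$type), , drop = FALSE]
}

pose_centroid <- function(p) colMeans(p$coords[, , drop = FALSE])

# Build the per-pose summaries (contact set, centroid, energy) that the
# spot/hotspot machinery consumes.
pose_features <- function(target, pose_list, cutoff = 4.0) {
  lapply(pose_list$poses, function(p) {
    list(excipient = pose_list$ligand,
         pose_id = p$id,
         e_total = p$score$e_total,
         contacts = contact_residues(if (inherits(target, "xd_target"))
           target$structure else target, p$coords, cutoff),
         centroid = colMeans(p$coords))
  })
}

#' Group poses into binding spots
#'
#' Two poses are connected when they share at least one contact residue or
#' their ligand centroids are within `merge_distance`; spots are the
#' connected components, labelled in order of best (lowest) member energy.
#'
#' @param features list of pose feature lists (from [pose_features()]),
#'   each with `contacts`, `centroid`, `e_total`.
#' @param merge_distance centroid merge distance in Angstrom (default 8).
#' @return integer vector of spot labels, one per pose.
#' @export
assign_spots <- function(features, merge_distance = 8.0) {
  n <- length(features)
  if (n == 0L) stop("need at least one pose", call. = FALSE)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    share <- length(intersect(features[[i]]$contacts, features[[j]]$contacts)) > 0
    near <- sqrt(sum((features[[i]]$centroid - features[[j]]$centroid)^2)) <= merge_distance
    adj[i, j] <- adj[j, i] <- share || near
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  # order labels by best member energy
  best <- tapply(vapply(features, `[[`, 0, "e_total"), comp, min)
  relabel <- match(comp, as.integer(names(sort(best))))
  as.integer(relabel)
}

#' Tabulate poses with spot labels
#'
#' @param features pose feature list (see [assign_spots()]).
#' @param spots integer spot labels from [assign_spots()].
#' @return data.frame (excipient, pose_id, e_total, spot) sorted by
#'   excipient then ascending energy.
#' @export
spot_table <- function(features, spots = assign_spots(features)) {
  df <- data.frame(
    excipient = vapply(features, `[[`, "", "excipient"),
    pose_id = vapply(features, `[[`, 0L, "pose_id"),
    e_total = vapply(features, `[[`, 0, "e_total"),
    spot = spots,
    stringsAsFactors = FALSE
  )
  df[order(df$excipient, df$e_total), , drop = FALSE]
}

# A spot object: member poses of one excipient (or, after consolidation,
# several) plus its residue union and centroids.
make_spot <- function(members) {
  structure(list(
    members = data.frame(
      excipient = vapply(members, `[[`, "", "excipient"),
      pose_id = vapply(members, `[[`, 0L, "pose_id"),
      e_total = vapply(members, `[[`, 0, "e_total"),
      stringsAsFactors = FALSE
    ),
    residues = sort(unique(unlist(lapply(members, `[[`, "contacts")))),
    centroids = do.call(rbind, lapply(members, `[[`, "centroid")),
    excipients = sort(unique(vapply(members, `[[`, "", "excipient"))),
    best_energy = min(vapply(members, `[[`, 0, "e_total"))
  ), class = "xd_spot")
}

#' Spots of one excipient's pose list
#'
#' @param target receptor structure or prepared target.
#' @param pose_list `xd_pose_list` from [ga_dock()].
#' @param contact_cutoff contact cutoff (A) for residue sets.
#' @param merge_distance centroid merge distance (A).
#' @return list of `xd_spot` objects ordered by best energy.
#' @export
excipient_spots <- function(target, pose_list, contact_cutoff = 4.0,
                            merge_distance = 8.0) {
  feats <- pose_features(target, pose_list, contact_cutoff)
  if (length(feats) == 0L) return(list())
  labels <- assign_spots(feats, merge_distance)
  lapply(sort(unique(labels)), function(l) make_spot(feats[labels == l]))
}

#' Consolidate per-excipient spots into cross-excipient hotspots
#'
#' Spots (from any number of excipients) are merged with the same
#' connectivity rule used within an excipient: two spots join when they
#' share a contact residue or any pair of member-pose centroids lies
#' within `merge_distance`. Each consolidated hotspot records its member
#' poses, the union of contact residues, the excipients represented and
#' the best (lowest) member energy; hotspots are ordered by best energy.
#' The operation is idempotent: consolidating its own output changes
#' nothing.
#'
#' @param per_excipient_spots list of spot lists (one per excipient), or a
#'   flat list of `xd_spot` objects.
#' @param merge_distance centroid merge distance in Angstrom (default 8).
#' @return list of `xd_hotspot` objects.
#' @export
consolidate_hotspots <- function(per_excipient_spots, merge_distance = 8.0) {
  if (length(per_excipient_spots) == 0L) stop("need at least one excipient", call. = FALSE)
  flat <- if (inherits(per_excipient_spots[[1]], "xd_spot") ||
              inherits(per_excipient_spots[[1]], "xd_hotspot")) {
    per_excipient_spots
  } else {
    unlist(per_excipient_spots, recursive = FALSE)
  }
  n <- length(flat)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    share <- length(intersect(flat[[i]]$residues, flat[[j]]$residues)) > 0
    near <- min(cross_dist(flat[[i]]$centroids, flat[[j]]$centroids)) <= merge_distance
    adj[i, j] <- adj[j, i] <- share || near
  }
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))$membership
  groups <- unname(split(seq_len(n), comp))
  hs <- lapply(groups, function(idx) {
    members <- do.call(rbind, lapply(flat[idx], `[[`, "members"))
    structure(list(
      id = NA_integer_,
      members = members[order(members$e_total), , drop = FALSE],
      residues = sort(unique(unlist(lapply(flat[idx], `[[`, "residues")))),
      centroids = do.call(rbind, lapply(flat[idx], `[[`, "centroids")),
      excipients = sort(unique(unlist(lapply(flat[idx], `[[`, "excipients")))),
      best_energy = min(vapply(flat[idx], `[[`, 0, "best_energy"))
    ), class = c("xd_hotspot", "xd_spot"))
  })
  hs <- unname(hs[order(vapply(hs, `[[`, 0, "best_energy"))])
  for (i in seq_along(hs)) hs[[i]]$id <- i
  hs
}

#' @export
print.xd_hotspot <- function(x, ...) {
  cat(sprintf("Hotspot %s: best E %.2f kcal/mol, excipients: %s\n",
              x$id, x$best_energy, paste(x$excipients, collapse = ", ")))
  cat("  residues: ", paste(residue_ranges(x$residues), collapse = "; "), "\n")
  invisible(x)
}

#' Compress residue keys into per-chain ranges
#'
#' Sorted residue numbers within each chain are compressed into maximal
#' runs allowing gaps of at most one, rendered like `"Lys43-Trp47"`.
#'
#' @param keys character residue keys.
#' @return named character vector, one entry per chain.
#' @export
residue_ranges <- function(keys) {
  if (length(keys) == 0L) return(character(0))
  df <- parse_residue_key(keys)
  df <- df[order(df$chain_id, df$res_seq), ]
  titlecase <- function(x) paste0(substr(x, 1, 1), tolower(substr(x, 2, nchar(x))))
  out <- c()
  for (ch in unique(df$chain_id)) {
    sub <- df[df$chain_id == ch, ]
    runs <- cumsum(c(1, diff(sub$res_seq) > 2))
    txt <- vapply(split(seq_len(nrow(sub)), runs), function(idx) {
      a <- sub[idx[1], ]; b <- sub[idx[length(idx)], ]
      if (a$res_seq == b$res_seq) {
        paste0(titlecase(a$res_name), a$res_seq)
      } else {
        paste0(titlecase(a$res_name), a$res_seq, "-", titlecase(b$res_name), b$res_seq)
      }
    }, "")
    out[ch] <- paste(txt, collapse = ", ")
  }
  out
}

#' Render hotspots as a report table
#'
#' @param hotspots list from [consolidate_hotspots()].
#' @return data.frame with one row per member pose: hotspot id, excipient,
#'   pose id, e_total, and the hotspot's per-chain residue ranges.
#' @export
hotspot_table <- function(hotspots) {
  do.call(rbind, lapply(hotspots, function(h) {
    rng <- residue_ranges(h$residues)
    data.frame(
      hotspot = h$id,
      excipient = h$members$excipient,
      pose_id = h$members$pose_id,
      e_total = h$members$e_total,
      residue_ranges = paste(paste0(names(rng), ": ", rng), collapse = " | "),
      stringsAsFactors = FALSE
    )
  }))
}
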