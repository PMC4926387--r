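# Compare excipient hotspots with protein-protein docking interfaces.

#' Hotspot / interface overlap reports
#'
#' For each protein-protein docking solution, counts the residues shared
#' between every hotspot and the receptor-side interface set, the overlap
#' fraction (count / hotspot size), whether the hotspot matches (at least
#' one shared residue), and which chain contributes more interface
#' residues.
#'
#' @param hotspots list of hotspots from [consolidate_hotspots()].
#' @param interfaces list of interface sets, one per docking solution,
#'   each as returned by [interface_residues()] (or a bare character
#'   vector taken as the receptor side).
#' @param universe optional character vector of valid residue keys of the
#'   receptor; keys outside it raise an error (guards against mixing
#'   structures).
#' @return list of reports of class `xd_interface_report`, one per
#'   solution: `solution`, `receptor_side`, `ligand_side`, `chain_counts`,
#'   and `overlaps` data.frame (hotspot, count, fraction, matched).
#' @export
overlap_report <- function(hotspots, interfaces, universe = NULL) {
  stopifnot(length(hotspots) >= 1)
  lapply(seq_along(interfaces), function(si) {
    iface <- interfaces[[si]]
    rec_side <- if (is.list(iface)) iface$receptor else iface
    lig_side <- if (is.list(iface)) iface$ligand %||% character(0) else character(0)
    if (!is.null(universe)) {
      bad <- setdiff(rec_side, universe)
      if (length(bad) > 0L) {
        stop("interface residues not present in the hotspot structure: ",
             paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
      }
    }
    ov <- do.call(rbind, lapply(hotspots, function(h) {
      cnt <- length(intersect(h$residues, rec_side))
      data.frame(hotspot = h$id, count = cnt,
                 fraction = if (length(h$residues)) cnt / length(h$residues) else 0,
                 matched = cnt >= 1L)
    }))
    chains <- parse_residue_key(rec_side)$chain_id
    chain_counts <- if (length(chains)) table(chains) else table(character(0))
    structure(list(solution = si, receptor_side = rec_side,
                   ligand_side = lig_side,
                   chain_counts = chain_counts, overlaps = ov),
              class = "xd_interface_report")
  })
}

#' @export
print.xd_interface_report <- function(x, ...) {
  m <- x$overlaps$hotspot[x$overlaps$matched]
  cat(sprintf("solution %d: %d interface residue(s); matching hotspots: %s\n",
              x$solution, length(x$receptor_side),
              if (length(m)) paste(m, collapse = ", ") else "none"))
  invisible(x)
}

#' Summarise hotspot matches per docking solution
#'
#' One row per solution: the chain with the higher number of interface
#' residues and the matched hotspot ids.
#'
#' @param reports list from [overlap_report()].
#' @return data.frame (solution, dominant_chain, matched_hotspots,
#'   n_interface_residues).
#' @export
summarize_matches <- function(reports) {
  stopifnot(length(reports) >= 1)
  do.call(rbind, lapply(reports, function(r) {
    dom <- if (length(r$chain_counts)) {
      names(r$chain_counts)[which.max(r$chain_counts)]
    } else {
      NA_character_
    }
    m <- r$overlaps$hotspot[r$overlaps$matched]
    data.frame(solution = r$solution,
               dominant_chain = dom,
               matched_hotspots = if (length(m)) paste(m, collapse = ", ") else "none",
               n_interface_residues = length(r$receptor_side),
               stringsAsFactors = FALSE)
  }))
}
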