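# SDF ligand input (bond orders come for free, unlike PDB without CONECT).

#' Read a ligand topology from an SDF/MOL file
#'
#' Parses the first molecule of an SDF file (via the ChemmineR package)
#' into a ligand topology: heavy atoms, bonds with orders, and rotatable
#' bonds detected with the standard rule. Formal charges are taken from
#' the MDL atom-block charge code.
#'
#' @param path SDF/MOL file path.
#' @param name ligand name (defaults to the file name).
#' @param max_torsions active-torsion cap (default 5).
#' @return `xd_ligand` topology.
#' @export
read_ligand_sdf <- function(path, name = NULL, max_torsions = 5L) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("reading SDF ligands requires the ChemmineR package", call. = FALSE)
  }
  set <- ChemmineR::read.SDFset(path)
  sdf <- set[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- toupper(sub("_.*$", "", rownames(ab)))
  # MDL charge codes: 1..7 -> +3 +2 +1 0(radical) -1 -2 -3; ChemmineR
  # stores the atom-line charge field as column C6
  code <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, nrow(ab))
  q <- integer(length(code))
  q[code %in% 1:3] <- 4L - as.integer(code[code %in% 1:3])
  q[code %in% 5:7] <- 4L - as.integer(code[code %in% 5:7])
  atoms <- data.frame(
    serial = seq_len(nrow(ab)), name = paste0(elem, seq_len(nrow(ab))),
    element = elem, res_name = "LIG", chain_id = "X", res_seq = 1L,
    i_code = "", x = ab[, 1], y = ab[, 2], z = ab[, 3],
    formal_charge = q, is_heavy = !(elem %in% c("H", "D")),
    stringsAsFactors = FALSE)
  bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                      order = as.integer(bb[, 3]))
  # drop hydrogens and reindex bonds onto heavy atoms
  keep <- which(atoms$is_heavy)
  remap <- match(seq_len(nrow(atoms)), keep)
  bonds <- bonds[bonds$i %in% keep & bonds$j %in% keep, , drop = FALSE]
  bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
  atoms <- atoms[keep, , drop = FALSE]
  atoms$serial <- seq_len(nrow(atoms))
  ligand_topology(atoms, bonds,
                  name = name %||% sub("\\.(sdf|mol)$", "", basename(path)),
                  max_torsions = max_torsions)
}
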