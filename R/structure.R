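# Structure data model and PDB input/output.
#
# A structure is a plain list with an `atoms` data.frame (one row per atom)
# and a `model_id`. Columns follow PDB author conventions: serial, name,
# element, res_name, chain_id, res_seq, i_code, x/y/z (Angstrom),
# formal_charge, is_heavy. Atoms of one residue are contiguous.

#' Construct a structure object
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `res_name`, `chain_id`, `res_seq`, `i_code`, `x`, `y`, `z`,
#'   `formal_charge`, `is_heavy`. Missing bookkeeping columns are filled
#'   with defaults.
#' @param model_id integer model number (multi-model input).
#' @return object of class `xd_structure`.
#' @export
new_structure <- function(atoms, model_id = 1L) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (nrow(atoms) < 1L) stop("a structure needs at least one atom", call. = FALSE)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$i_code)) atoms$i_code <- ""
  if (is.null(atoms$formal_charge)) atoms$formal_charge <- 0L
  if (is.null(atoms$element)) stop("atoms need an element column", call. = FALSE)
  atoms$i_code[is.na(atoms$i_code)] <- ""
  atoms$element <- toupper(trimws(atoms$element))
  if (any(!nzchar(atoms$element))) stop("element symbols must be non-empty", call. = FALSE)
  atoms$is_heavy <- !(atoms$element %in% c("H", "D"))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("coordinates must be finite", call. = FALSE)
  structure(list(atoms = atoms, model_id = as.integer(model_id)),
            class = "xd_structure")
}

#' @export
print.xd_structure <- function(x, ...) {
  cat(sprintf("<structure: %d atoms, %d residues, %d chain(s), model %d>\n",
              nrow(x$atoms), length(unique(residue_uid(x))),
              length(unique(x$atoms$chain_id)), x$model_id))
  invisible(x)
}

is_structure <- function(x) inherits(x, "xd_structure")

#' Atom coordinates as a matrix
#' @param s structure.
#' @param heavy_only drop hydrogens.
#' @return numeric matrix (n x 3).
#' @export
atom_coords <- function(s, heavy_only = FALSE) {
  a <- s$atoms
  if (heavy_only) a <- a[a$is_heavy, , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- NULL
  m
}

#' Replace the coordinates of a structure
#' @param s structure.
#' @param xyz numeric matrix (n x 3) matching the atom count.
#' @return the structure with updated coordinates.
#' @export
set_atom_coords <- function(s, xyz) {
  stopifnot(nrow(xyz) == nrow(s$atoms))
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

# Residue identity strings. `residue_uid` identifies a residue within one
# structure (chain/number/insertion); `residue_key` adds the residue name
# and is the user-facing set element ("A:ASP:41:").
residue_uid <- function(s) {
  a <- s$atoms
  paste(a$chain_id, a$res_seq, a$i_code, sep = "|")
}

#' Residue keys for every atom (or the unique residues) of a structure
#' @param s structure.
#' @param unique_only return each residue once, in order of appearance.
#' @return character vector of keys `"chain:resname:resseq:icode"`.
#' @export
residue_keys <- function(s, unique_only = TRUE) {
  a <- s$atoms
  k <- paste(a$chain_id, a$res_name, a$res_seq, a$i_code, sep = ":")
  if (unique_only) k[!duplicated(k)] else k
}

#' Split a residue key back into its fields
#' @param key character vector of keys from [residue_keys()].
#' @return data.frame with chain_id, res_name, res_seq, i_code.
#' @export
parse_residue_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  data.frame(
    chain_id = vapply(parts, `[`, "", 1L),
    res_name = vapply(parts, `[`, "", 2L),
    res_seq = as.integer(vapply(parts, `[`, "", 3L)),
    i_code = vapply(parts, function(p) if (length(p) >= 4L) p[4L] else "", ""),
    stringsAsFactors = FALSE
  )
}

# --- PDB reading ------------------------------------------------------------

#' Read PDB content into one structure per model
#'
#' Parses ATOM and HETATM records (fixed-column PDB). A file with MODEL
#' blocks yields one structure per block; otherwise a single structure.
#' Alternate locations are resolved by keeping blank or 'A' altLoc only.
#'
#' @param text PDB content as a single string / character vector of lines,
#'   or a path to a PDB file.
#' @return list of `xd_structure` objects.
#' @export
read_pdb <- function(text) {
  lines <- pdb_text_lines(text)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("PDB parse error: no ATOM/HETATM records found", call. = FALSE)
  # validate coordinate fields up front so errors carry a line number
  for (ln in which(is_atom)) {
    for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
      raw <- trimws(substr(lines[ln], fld[1], fld[2]))
      if (!nzchar(raw) || is.na(suppressWarnings(as.numeric(raw)))) {
        stop(sprintf("PDB parse error at line %d: non-numeric coordinate field '%s'",
                     ln, raw), call. = FALSE)
      }
    }
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  multi <- any(grepl("^MODEL", lines))
  pdb <- bio3d::read.pdb(tmp, multi = multi, rm.alt = TRUE, verbose = FALSE)
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$elesy[is.na(at$elesy)] <- ""
  elem <- toupper(trimws(at$elesy))
  guess <- toupper(substr(gsub("[0-9'\"]", "", trimws(at$elety)), 1, 1))
  elem[!nzchar(elem)] <- guess[!nzchar(elem)]
  fc <- rep(0L, nrow(at))
  has_q <- !is.na(at$charge) & nzchar(trimws(at$charge))
  if (any(has_q)) {
    q <- trimws(at$charge[has_q])
    sgn <- ifelse(grepl("-", q), -1L, 1L)
    mag <- suppressWarnings(as.integer(gsub("[^0-9]", "", q)))
    mag[is.na(mag)] <- 0L
    fc[has_q] <- sgn * mag
  }
  base <- data.frame(
    serial = at$eleno, name = trimws(at$elety), element = elem,
    res_name = trimws(at$resid), chain_id = at$chain, res_seq = at$resno,
    i_code = at$insert, x = at$x, y = at$y, z = at$z,
    formal_charge = fc, stringsAsFactors = FALSE
  )
  base$chain_id[is.na(base$chain_id)] <- " "
  n_models <- if (multi) nrow(pdb$xyz) else 1L
  lapply(seq_len(n_models), function(m) {
    b <- base
    if (multi) {
      xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
      b$x <- xyz[, 1]; b$y <- xyz[, 2]; b$z <- xyz[, 3]
    }
    new_structure(b, model_id = m)
  })
}

pdb_text_lines <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    return(readLines(text, warn = FALSE))
  }
  unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
}

# --- PDB writing ------------------------------------------------------------

#' Write a structure (or several models) as PDB text
#'
#' Fixed-width PDB output; round-trips through [read_pdb()] preserving atom
#' count, residue keys and coordinates to 3 decimals.
#'
#' @param s an `xd_structure`, or a list of them (written as MODEL blocks).
#' @param file optional path; when given the text is also written to disk.
#' @return PDB text as a single string (invisibly when `file` is given).
#' @export
write_pdb <- function(s, file = NULL) {
  models <- if (is_structure(s)) list(s) else s
  stopifnot(length(models) >= 1L, all(vapply(models, is_structure, TRUE)))
  blocks <- vapply(models, format_pdb_model, "")
  txt <- if (length(models) == 1L) {
    paste0(blocks[[1]], "END\n")
  } else {
    paste0(paste0(sprintf("MODEL     %4d\n", seq_along(blocks)), blocks,
                  "ENDMDL\n", collapse = ""), "END\n")
  }
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
}

format_pdb_model <- function(s) {
  a <- s$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (any(abs(xyz) >= 10000)) {
    stop("PDB format error: coordinate magnitude >= 10000 A does not fit fixed-width columns",
         call. = FALSE)
  }
  std_res <- a$res_name %in% names(residue_templates())
  rec <- ifelse(std_res, "ATOM  ", "HETATM")
  name4 <- vapply(seq_len(nrow(a)), function(i) {
    nm <- a$name[i]
    if (nchar(nm) >= 4L) substr(nm, 1, 4) else sprintf(" %-3s", nm)
  }, "")
  qs <- ifelse(a$formal_charge == 0, "  ",
               sprintf("%d%s", abs(a$formal_charge),
                       ifelse(a$formal_charge > 0, "+", "-")))
  lines <- sprintf(
    "%s%5d %s%s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s%2s",
    rec, a$serial %% 100000L, name4, " ", a$res_name,
    substr(paste0(a$chain_id, " "), 1, 1), a$res_seq,
    substr(paste0(a$i_code, " "), 1, 1),
    a$x, a$y, a$z, 1, 0, sprintf("%2s", a$element), qs
  )
  paste0(paste0(lines, collapse = "\n"), "\n")
}

# --- geometry ---------------------------------------------------------------

#' Rigidly transform a structure
#'
#' Maps every coordinate x to `rotation %*% x + translation`.
#'
#' @param s structure.
#' @param rotation 3x3 proper rotation matrix (orthonormal, det +1).
#' @param translation length-3 numeric vector (Angstrom).
#' @return transformed structure.
#' @export
transform_structure <- function(s, rotation = diag(3), translation = c(0, 0, 0)) {
  if (!is_rotation_matrix(rotation)) {
    stop("rotation must be orthonormal with determinant +1", call. = FALSE)
  }
  xyz <- atom_coords(s)
  set_atom_coords(s, sweep(xyz %*% t(rotation), 2, -translation))
}

#' C-alpha RMSD between two structures in a common frame
#'
#' Root-mean-square deviation over matched C-alpha atoms without
#' superposition: both structures are assumed to share the receptor frame,
#' as in docking-solution clustering.
#'
#' @param a,b structures with matching C-alpha sets (matched by
#'   chain/residue number/insertion code).
#' @return RMSD in Angstrom.
#' @export
ca_rmsd <- function(a, b) {
  ca_a <- a$atoms$name == "CA"
  ca_b <- b$atoms$name == "CA"
  ka <- residue_uid(a)[ca_a]; kb <- residue_uid(b)[ca_b]
  if (length(ka) == 0L) stop("no C-alpha atoms to compare", call. = FALSE)
  miss <- union(setdiff(ka, kb), setdiff(kb, ka))
  if (length(miss) > 0L || anyDuplicated(ka) || anyDuplicated(kb)) {
    stop("C-alpha sets do not match; unmatched residues: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  xa <- atom_coords(a)[ca_a, , drop = FALSE]
  xb <- atom_coords(b)[ca_b, , drop = FALSE][match(ka, kb), , drop = FALSE]
  sqrt(mean(rowSums((xa - xb)^2)))
}

# RMSD over all heavy atoms, same ordered atom set, no superposition.
heavy_rmsd <- function(xa, xb) {
  sqrt(mean(rowSums((xa - xb)^2)))
}

#' Receptor residues in contact with a set of probe points
#'
#' A residue is reported when the minimum distance between any of its heavy
#' atoms and any probe point is less than or equal to `cutoff` (closed
#' boundary).
#'
#' @param target structure.
#' @param probe_coords numeric matrix (n x 3) of probe points, or a
#'   structure whose heavy atoms are used.
#' @param cutoff contact distance in Angstrom (default 4.0).
#' @return character vector of residue keys (see [residue_keys()]), in
#'   order of appearance in the structure; empty probe set gives an empty
#'   result.
#' @export
contact_residues <- function(target, probe_coords, cutoff = 4.0) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0) {
    stop("cutoff must be a positive distance", call. = FALSE)
  }
  if (is_structure(probe_coords)) probe_coords <- atom_coords(probe_coords, heavy_only = TRUE)
  probe_coords <- matrix(as.numeric(probe_coords), ncol = 3)
  if (nrow(probe_coords) == 0L) return(character(0))
  heavy <- target$atoms$is_heavy
  xyz <- atom_coords(target)[heavy, , drop = FALSE]
  keys <- residue_keys(target, unique_only = FALSE)[heavy]
  d2 <- cross_dist2(xyz, probe_coords)
  hit <- apply(d2, 1, min) <= cutoff^2 + 1e-12
  keys_hit <- keys[hit]
  keys_hit[!duplicated(keys_hit)]
}

# Axis-aligned bounding box of a structure (+ optional margin).
structure_bbox <- function(s, margin = 0) {
  xyz <- atom_coords(s, heavy_only = TRUE)
  list(min = apply(xyz, 2, min) - margin, max = apply(xyz, 2, max) + margin)
}
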