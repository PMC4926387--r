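# Deterministic donor/acceptor/hydrophobic/charged typing for protein and
# generic ligand heavy atoms. Hydrogens never enter scoring geometry; typing
# encodes each heavy atom's hydrogen-bearing capacity instead.

# Side-chain typing templates for the 20 standard amino acids.
# Entries: atom name -> c(donor, acceptor, charge). Backbone handled
# separately (N donor except proline, O/OXT acceptor).
residue_templates <- function() {
  t1 <- function(...) list(...)
  list(
    ALA = t1(),
    GLY = t1(),
    VAL = t1(), LEU = t1(), ILE = t1(), PHE = t1(), MET = t1(), PRO = t1(),
    SER = t1(OG  = c(1, 1, 0)),
    THR = t1(OG1 = c(1, 1, 0)),
    TYR = t1(OH  = c(1, 1, 0)),
    CYS = t1(),
    TRP = t1(NE1 = c(1, 0, 0)),
    ASN = t1(OD1 = c(0, 1, 0), ND2 = c(1, 0, 0)),
    GLN = t1(OE1 = c(0, 1, 0), NE2 = c(1, 0, 0)),
    # carboxylates: both oxygens accept; the delocalised negative charge is
    # carried on OD2/OE2 (single integer formal charge per residue)
    ASP = t1(OD1 = c(0, 1, 0), OD2 = c(0, 1, -1)),
    GLU = t1(OE1 = c(0, 1, 0), OE2 = c(0, 1, -1)),
    LYS = t1(NZ  = c(1, 0, 1)),
    # guanidinium: all three nitrogens donate; the delocalised cation is
    # represented on the two terminal nitrogens
    ARG = t1(NE  = c(1, 0, 0), NH1 = c(1, 0, 1), NH2 = c(1, 0, 1)),
    # histidine neutral by default: both ring nitrogens can donate or accept
    HIS = t1(ND1 = c(1, 1, 0), NE2 = c(1, 1, 0))
  )
}

#' Assign interaction types to every atom of a structure
#'
#' Deterministic template rules: standard amino-acid atoms are typed from
#' per-residue tables (backbone N donor except proline, backbone O/OXT
#' acceptor, side chains per template, formal charges Asp/Glu -1 and
#' Lys/Arg +1 with histidine neutral); atoms of non-standard residues are
#' typed generically by element (N/O donor+acceptor, C/S/P hydrophobic)
#' with charges taken from the structure's `formal_charge` column. Unknown
#' elements are typed hydrophobic with a warning.
#'
#' @param s structure.
#' @return data.frame with one row per atom: logical `donor`, `acceptor`,
#'   `hydrophobic`, `charged` and integer `charge`.
#' @export
assign_atom_types <- function(s) {
  a <- s$atoms
  n <- nrow(a)
  donor <- acceptor <- logical(n)
  charge <- integer(n)
  tmpl <- residue_templates()
  is_std <- a$res_name %in% names(tmpl)
  known_elem <- a$element %in% c("C", "N", "O", "S", "P", "H", "D", "F", "CL", "BR", "I")
  if (any(a$is_heavy & !known_elem)) {
    warning("unknown element(s) typed as hydrophobic: ",
            paste(unique(a$element[a$is_heavy & !known_elem]), collapse = ", "),
            call. = FALSE)
  }
  for (i in seq_len(n)) {
    if (!a$is_heavy[i]) next
    if (is_std[i]) {
      nm <- a$name[i]
      if (nm == "N") {
        donor[i] <- a$res_name[i] != "PRO"
      } else if (nm %in% c("O", "OXT")) {
        acceptor[i] <- TRUE
      } else {
        hit <- tmpl[[a$res_name[i]]][[nm]]
        if (!is.null(hit)) {
          donor[i] <- hit[1] == 1
          acceptor[i] <- hit[2] == 1
          charge[i] <- hit[3]
        }
      }
    } else if (a$element[i] %in% c("N", "O")) {
      donor[i] <- TRUE
      acceptor[i] <- TRUE
      charge[i] <- a$formal_charge[i]
    } else {
      charge[i] <- a$formal_charge[i]
    }
  }
  hydrophobic <- a$is_heavy & !donor & !acceptor & charge == 0
  data.frame(donor = donor, acceptor = acceptor, hydrophobic = hydrophobic,
             charged = charge != 0L, charge = charge)
}
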