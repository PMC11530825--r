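# Atom-name conventions for the four ribonucleotides (PDB v3 names).
# The base/backbone dichotomy drives both the specific/nonspecific
# contact classification and the four-group energy decomposition:
# a contact or energy term is "specific" only when both atoms sit on
# nucleobases; anything touching the sugar-phosphate backbone is
# "nonspecific".

BACKBONE_HEAVY <- c("P", "OP1", "OP2", "OP3",
                    "O5'", "C5'", "C4'", "O4'", "C3'", "O3'",
                    "C2'", "C1'")
BACKBONE_H <- c("H5'", "H5''", "H4'", "H3'", "H2'", "H2''",
                "H1'", "HO2'", "HO5'", "HO3'")
O2PRIME <- c("O2'", "HO2'")

BASE_HEAVY <- list(
  A = c("N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4"),
  G = c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4"),
  C = c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"),
  U = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6")
)
BASE_H <- list(
  A = c("H8", "H61", "H62", "H2"),
  G = c("H8", "H1", "H21", "H22"),
  C = c("H41", "H42", "H5", "H6"),
  U = c("H3", "H5", "H6")
)

# Hydrogen-bond chemistry of the base edges. Donor hydrogens are listed
# so the donor-H...acceptor angle criterion can be applied when the
# ensemble carries hydrogens.
BASE_DONORS <- list(
  A = c("N6"), G = c("N1", "N2"), C = c("N4"), U = c("N3")
)
DONOR_HYDROGENS <- list(
  N6 = c("H61", "H62"), N1 = "H1", N2 = c("H21", "H22"),
  N4 = c("H41", "H42"), N3 = "H3", `O2'` = "HO2'"
)
BASE_ACCEPTORS <- list(
  A = c("N1", "N3", "N7"), G = c("O6", "N3", "N7"),
  C = c("N3", "O2"), U = c("O2", "O4")
)
BACKBONE_ACCEPTORS <- c("OP1", "OP2", "O2'", "O3'", "O4'", "O5'")
BACKBONE_DONORS <- c("O2'")

# Formal-charge carriers: the anionic phosphate oxygens. RNA has no
# formally cationic group, so the default cation set is empty and salt
# bridges only appear if a user supplies one.
CHARGED_ANIONIC <- c("OP1", "OP2", "OP3")

#' Classify nucleic-acid atoms as base or backbone
#'
#' Phosphate and sugar atoms (including C1' and, by default, O2'/HO2')
#' are backbone; all base ring and exocyclic atoms are base. The
#' partition is total and exclusive: every recognized atom receives
#' exactly one role.
#'
#' @param atom_names Character vector of PDB atom names.
#' @param nucleotide Single nucleotide code ("A","C","G","U") used to
#'   validate base-atom membership, or `NA` to accept any base atom name.
#' @param o2prime_role Role for the 2'-hydroxyl ("backbone" default).
#' @return Character vector, one of "base"/"backbone" per atom.
#' @export
classify_atom_roles <- function(atom_names, nucleotide = NA,
                                o2prime_role = c("backbone", "base")) {
  o2prime_role <- match.arg(o2prime_role)
  base_names <- if (is.na(nucleotide)) unique(unlist(c(BASE_HEAVY, BASE_H)))
                else c(BASE_HEAVY[[nucleotide]], BASE_H[[nucleotide]])
  roles <- character(length(atom_names))
  for (i in seq_along(atom_names)) {
    nm <- atom_names[i]
    roles[i] <-
      if (nm %in% O2PRIME) o2prime_role
      else if (nm %in% c(BACKBONE_HEAVY, BACKBONE_H)) "backbone"
      else if (nm %in% base_names) "base"
      else stop("unrecognized atom name '", nm, "'",
                if (!is.na(nucleotide)) paste0(" for nucleotide ", nucleotide))
  }
  roles
}
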