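#' Build a structure topology from residue and atom tables
#'
#' The topology is the static description of an ASO--RNA-hairpin complex:
#' residues with their region labels, atoms with base/backbone roles,
#' hydrogen-bond donor/acceptor capability, apolar (carbon) membership,
#' formal-charge groups, and -- once attached -- nonbonded parameters.
#'
#' @param residues data.frame with columns `residue_index` (integer,
#'   contiguous 1-based), `nucleotide` ("A","C","G","U"), and optionally
#'   `chain_label`.
#' @param atoms data.frame with columns `atom_name`, `residue_index`.
#' @param region_map Named list mapping region names (`aso`,
#'   `hairpin_strand1`, `hairpin_strand2`, ...) to residue-index vectors.
#'   Region labels always come from this mapping, never from chain IDs.
#'   `NULL` leaves all regions `NA`.
#' @param o2prime_role Role given to O2'/HO2' (default backbone).
#' @return Object of class `"topology"`: list with `atoms` and
#'   `residues` data.frames.
#' @export
build_topology <- function(residues, atoms, region_map = NULL,
                           o2prime_role = "backbone") {
  stopifnot(all(c("residue_index", "nucleotide") %in% names(residues)),
            all(c("atom_name", "residue_index") %in% names(atoms)))
  bad <- setdiff(residues$nucleotide, c("A", "C", "G", "U"))
  if (length(bad))
    stop("unsupported residue type(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(residues$residue_index))
    stop("duplicated residue indices in residue table")
  orphan <- setdiff(atoms$residue_index, residues$residue_index)
  if (length(orphan))
    stop("atoms reference unknown residue indices: ",
         paste(orphan, collapse = ", "))
  if (is.null(residues$chain_label)) residues$chain_label <- "A"

  residues$region <- NA_character_
  if (!is.null(region_map)) {
    seen <- integer(0)
    for (rg in names(region_map)) {
      idx <- region_map[[rg]]
      overlap <- intersect(idx, seen)
      if (length(overlap))
        stop("region mapping overlaps at residue(s) ",
             paste(overlap, collapse = ", "))
      seen <- c(seen, idx)
      residues$region[residues$residue_index %in% idx] <- rg
    }
  }

  nuc_of <- residues$nucleotide[match(atoms$residue_index,
                                      residues$residue_index)]
  n <- nrow(atoms)
  atoms$element <- vapply(atoms$atom_name, element_of, character(1))
  atoms$is_heavy <- atoms$element != "H"
  atoms$role <- vapply(seq_len(n), function(i) {
    classify_atom_roles(atoms$atom_name[i], nuc_of[i],
                        o2prime_role = o2prime_role)
  }, character(1))
  atoms$nucleotide <- nuc_of

  atoms$is_donor <- vapply(seq_len(n), function(i) {
    nm <- atoms$atom_name[i]
    nm %in% BASE_DONORS[[nuc_of[i]]] || nm %in% BACKBONE_DONORS
  }, logical(1))
  atoms$is_acceptor <- vapply(seq_len(n), function(i) {
    nm <- atoms$atom_name[i]
    nm %in% BASE_ACCEPTORS[[nuc_of[i]]] || nm %in% BACKBONE_ACCEPTORS
  }, logical(1))
  atoms$is_apolar <- atoms$element == "C"
  atoms$is_charged <- atoms$atom_name %in% CHARGED_ANIONIC
  atoms$charge <- NA_real_
  atoms$lj_sigma <- NA_real_
  atoms$lj_epsilon <- NA_real_
  rownames(atoms) <- NULL

  structure(list(atoms = atoms, residues = residues), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat("<topology> ", nrow(x$residues), " residues, ", nrow(x$atoms),
      " atoms (", sum(x$atoms$is_heavy), " heavy)\n", sep = "")
  rg <- table(x$residues$region, useNA = "ifany")
  cat("  regions:", paste(names(rg), rg, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Default region mapping for the ASO--hairpin residue scheme
#'
#' The complexes studied here place the antisense oligonucleotide at
#' residues 1-10 and the RNA hairpin at 11-42, with the hairpin treated
#' as two strands (11-26 and 27-42) for helical-parameter purposes.
#'
#' @param n_aso,n_hairpin Residue counts (defaults 10 and 32).
#' @return Named list of residue-index vectors.
#' @export
aso_hairpin_regions <- function(n_aso = 10, n_hairpin = 32) {
  split_at <- n_aso + ceiling(n_hairpin / 2)
  list(aso = seq_len(n_aso),
       hairpin_strand1 = seq(n_aso + 1, split_at),
       hairpin_strand2 = seq(split_at + 1, n_aso + n_hairpin))
}

#' Attach per-atom nonbonded parameters from a table
#'
#' @param topology A `"topology"` object.
#' @param params data.frame with columns `residue` (nucleotide code),
#'   `atom` (atom name), `charge_e`, `sigma_A`, `epsilon_kcal`.
#' @return The topology with `charge`, `lj_sigma`, `lj_epsilon` filled.
#'   Any atom without a table entry aborts with the complete list of
#'   missing (residue, atom) pairs -- no silent zero-fill.
#' @export
attach_nonbonded_params <- function(topology, params) {
  stopifnot(inherits(topology, "topology"),
            all(c("residue", "atom", "charge_e", "sigma_A",
                  "epsilon_kcal") %in% names(params)))
  if (any(params$sigma_A < 0) || any(params$epsilon_kcal < 0))
    stop("Lennard-Jones sigma and epsilon must be non-negative")
  at <- topology$atoms
  key <- paste(at$nucleotide, at$atom_name)
  pkey <- paste(params$residue, params$atom)
  hit <- match(key, pkey)
  if (anyNA(hit)) {
    miss <- unique(key[is.na(hit)])
    stop("unparameterized atoms (residue atom): ",
         paste(miss, collapse = "; "))
  }
  at$charge <- params$charge_e[hit]
  at$lj_sigma <- params$sigma_A[hit]
  at$lj_epsilon <- params$epsilon_kcal[hit]
  topology$atoms <- at
  topology
}

#' Read a nonbonded parameter table from CSV
#'
#' Expected columns: residue, atom, charge_e, sigma_A, epsilon_kcal.
#'
#' @param path CSV file path.
#' @return data.frame suitable for [attach_nonbonded_params()].
#' @export
read_param_table <- function(path) {
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("residue", "atom", "charge_e", "sigma_A", "epsilon_kcal")
  miss <- setdiff(need, names(tb))
  if (length(miss))
    stop("parameter table lacks column(s): ", paste(miss, collapse = ", "))
  tb
}

#' Generic per-atom nonbonded parameters for synthetic work
#'
#' A deliberately simple, element-based parameter set (labelled
#' synthetic, not a force field): -0.8 e on each anionic phosphate
#' oxygen, dipolar charges on N/O/polar-H balanced by positive carbons
#' so bases and sugars are near-neutral and the formal charge sits on
#' the phosphate; Lennard-Jones sigma/epsilon are element-typical.
#'
#' @param topology A `"topology"` object.
#' @return data.frame parameter table covering every atom in `topology`.
#' @export
synthetic_param_table <- function(topology) {
  at <- unique(topology$atoms[, c("nucleotide", "atom_name", "element")])
  sig <- c(H = 1.07, C = 3.40, N = 3.25, O = 2.96, P = 3.74)
  eps <- c(H = 0.0157, C = 0.086, N = 0.17, O = 0.21, P = 0.20)
  chg <- function(name, el) {
    if (name %in% CHARGED_ANIONIC) -0.80
    else if (el == "O") -0.50
    else if (el == "N") -0.50
    else if (el == "P") 1.40
    else if (el == "H") 0.35
    else 0.40
  }
  data.frame(residue = at$nucleotide, atom = at$atom_name,
             charge_e = mapply(chg, at$atom_name, at$element),
             sigma_A = unname(sig[at$element]),
             epsilon_kcal = unname(eps[at$element]),
             row.names = NULL)
}
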