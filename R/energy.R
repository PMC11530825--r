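# Short-range nonbonded interaction energies: Coulomb + Lennard-Jones
# with plain cutoff truncation, Lorentz-Berthelot combination rules,
# and the four-group base/backbone decomposition that separates
# specific (base-base) from nonspecific (backbone-involving)
# interactions between an ASO and its target hairpin.

COULOMB_K <- 332.0636  # kcal A mol^-1 e^-2

#' Nonbonded pair energy
#'
#' `k q_i q_j / r + 4 eps_ij [ (sig_ij/r)^12 - (sig_ij/r)^6 ]` with
#' `k = 332.0636`, arithmetic-mean sigma and geometric-mean epsilon;
#' zero beyond the cutoff.
#'
#' @param q_i,q_j Partial charges (e).
#' @param sigma_i,sigma_j LJ sigma (Angstrom).
#' @param eps_i,eps_j LJ epsilon (kcal/mol).
#' @param r Distance (Angstrom), > 0.
#' @param cutoff Truncation distance (Angstrom).
#' @return Energy in kcal/mol.
#' @export
pair_energy <- function(q_i, q_j, sigma_i, sigma_j, eps_i, eps_j, r,
                        cutoff = 10) {
  if (any(r <= 0)) stop("pair distance must be positive")
  sig <- (sigma_i + sigma_j) / 2
  eps <- sqrt(eps_i * eps_j)
  sr6 <- (sig / r)^6
  e <- COULOMB_K * q_i * q_j / r + 4 * eps * (sr6^2 - sr6)
  e[r > cutoff] <- 0
  e
}

# Sum of pair energies between two atom index sets of one frame.
group_energy_frame <- function(frame, at, idx_a, idx_b, cutoff) {
  d <- cross_dist(frame[idx_a, , drop = FALSE],
                  frame[idx_b, , drop = FALSE])
  within <- which(d <= cutoff & d > 0, arr.ind = TRUE)
  if (nrow(within) == 0L) return(0)
  ia <- idx_a[within[, 1]]; ib <- idx_b[within[, 2]]
  if (any(d[within] <= 0)) stop("zero interatomic distance")
  sum(pair_energy(at$charge[ia], at$charge[ib],
                  at$lj_sigma[ia], at$lj_sigma[ib],
                  at$lj_epsilon[ia], at$lj_epsilon[ib],
                  d[within], cutoff = cutoff))
}

#' Interaction energy between two atom groups
#'
#' Sums [pair_energy()] over the cross product of two disjoint atom
#' sets within the cutoff. Intended for inter-molecular groups;
#' overlapping groups are refused (intramolecular energies would need
#' bonded exclusions this tool does not apply).
#'
#' @param frame n_atoms x 3 coordinates (or an `"ensemble"`; frame 1).
#' @param topology Parameterized `"topology"`.
#' @param group_a,group_b Atom index vectors (disjoint).
#' @param cutoff Cutoff distance (Angstrom), default 10.
#' @return Energy in kcal/mol (symmetric in the two groups).
#' @export
group_energy <- function(frame, topology, group_a, group_b, cutoff = 10) {
  if (inherits(frame, "ensemble")) {
    topology <- frame$topology
    frame <- frame_xyz(frame, 1L)
  }
  if (length(intersect(group_a, group_b)))
    stop("atom groups overlap; intramolecular energies are not supported")
  at <- topology$atoms
  if (anyNA(at$charge[c(group_a, group_b)]))
    stop("topology is not parameterized; run attach_nonbonded_params()")
  group_energy_frame(frame, at, group_a, group_b, cutoff)
}

#' Assemble a four-group energy decomposition from component means
#'
#' The decomposition's total rule: total = base-base + backbone-backbone
#' + base-backbone + backbone-base. Used both by
#' [four_group_decomposition()] and directly on reported component
#' means.
#'
#' @param base_base,bac_bac,base_bac,bac_base Component energies
#'   (kcal/mol): ASO-base/hairpin-base, ASO-backbone/hairpin-backbone,
#'   ASO-base/hairpin-backbone, ASO-backbone/hairpin-base.
#' @param sd Optional named numeric of component SDs.
#' @param cutoff Cutoff recorded with the result.
#' @return Object of class `"energy_decomposition"`.
#' @export
energy_decomposition <- function(base_base, bac_bac, base_bac, bac_base,
                                 sd = NULL, cutoff = 10) {
  comp <- c(base_base = base_base, bac_bac = bac_bac,
            base_bac = base_bac, bac_base = bac_base)
  structure(list(components = comp, sd = sd, total = sum(comp),
                 cutoff = cutoff), class = "energy_decomposition")
}

#' @export
print.energy_decomposition <- function(x, ...) {
  cat("<energy_decomposition> (kcal/mol, cutoff ", x$cutoff, " A)\n",
      sep = "")
  for (nm in names(x$components))
    cat(sprintf("  %-10s %9.2f%s\n", nm, x$components[[nm]],
                if (!is.null(x$sd)) sprintf(" +/- %.2f", x$sd[[nm]])
                else ""))
  cat(sprintf("  %-10s %9.2f\n", "total", x$total))
  invisible(x)
}

# Atom indices of one region/role cell of the partition.
role_group <- function(topology, region_residues, role) {
  at <- topology$atoms
  which(at$residue_index %in% region_residues & at$role == role)
}

#' Four-group base/backbone interaction-energy decomposition
#'
#' Splits the ASO-hairpin nonbonded energy into base-base ("specific"),
#' backbone-backbone, base-backbone, and backbone-base ("nonspecific")
#' group energies, averaged over the analysis window; their sum is the
#' undecomposed total.
#'
#' @param ensemble Parameterized `"ensemble"`.
#' @param aso_residues,hairpin_residues Residue index vectors.
#' @param window Time window in ns or `NULL`.
#' @param cutoff Cutoff (Angstrom), default 10.
#' @return `"energy_decomposition"` with component means, SDs, total,
#'   and the per-frame component matrix as attribute `"per_frame"`.
#' @export
four_group_decomposition <- function(ensemble, aso_residues,
                                     hairpin_residues, window = NULL,
                                     cutoff = 10) {
  idx <- window_frames(ensemble, window)
  topo <- ensemble$topology
  if (length(intersect(aso_residues, hairpin_residues)))
    stop("ASO and hairpin residue sets overlap")
  g <- list(
    base_base = list(role_group(topo, aso_residues, "base"),
                     role_group(topo, hairpin_residues, "base")),
    bac_bac = list(role_group(topo, aso_residues, "backbone"),
                   role_group(topo, hairpin_residues, "backbone")),
    base_bac = list(role_group(topo, aso_residues, "base"),
                    role_group(topo, hairpin_residues, "backbone")),
    bac_base = list(role_group(topo, aso_residues, "backbone"),
                    role_group(topo, hairpin_residues, "base")))
  per_frame <- vapply(idx, function(f) {
    fr <- frame_xyz(ensemble, f)
    vapply(g, function(gg)
      group_energy_frame(fr, topo$atoms, gg[[1]], gg[[2]], cutoff),
      numeric(1))
  }, numeric(4))
  per_frame <- t(per_frame)  # frames x 4
  means <- colMeans(per_frame)
  sds <- apply(per_frame, 2, stats::sd)
  out <- energy_decomposition(means[["base_base"]], means[["bac_bac"]],
                              means[["base_bac"]], means[["bac_base"]],
                              sd = sds, cutoff = cutoff)
  attr(out, "per_frame") <- per_frame
  out
}

#' Window-mean interaction-energy matrix over residue pairs
#'
#' Entry (i, j) is the window mean of the summed atom-pair nonbonded
#' energies between residues i and j (force-field Coulomb + LJ with
#' cutoff; not an implicit-solvent free energy). Summing the entries
#' over the ASO x hairpin block reproduces the four-group total.
#'
#' @param ensemble Parameterized `"ensemble"`.
#' @param window Time window in ns or `NULL`.
#' @param cutoff Cutoff (Angstrom).
#' @param inter_only If `TRUE` (default) only pairs in different chains
#'   are computed (intramolecular pairs need bonded exclusions).
#' @return Symmetric residue x residue matrix (kcal/mol).
#' @export
per_residue_pair_matrix <- function(ensemble, window = NULL, cutoff = 10,
                                    inter_only = TRUE) {
  idx <- window_frames(ensemble, window)
  topo <- ensemble$topology
  res <- topo$residues
  nr <- nrow(res)
  chain <- res$chain_label
  acc <- matrix(0, nr, nr)
  atom_of <- lapply(res$residue_index, function(ri)
    which(topo$atoms$residue_index == ri))
  for (f in idx) {
    fr <- frame_xyz(ensemble, f)
    for (a in seq_len(nr - 1L)) for (b in (a + 1L):nr) {
      if (inter_only && chain[a] == chain[b]) next
      e <- group_energy_frame(fr, topo$atoms, atom_of[[a]], atom_of[[b]],
                              cutoff)
      acc[a, b] <- acc[a, b] + e
    }
  }
  m <- acc / length(idx)
  m <- m + t(m)
  dimnames(m) <- list(res$residue_index, res$residue_index)
  m
}

#' Combine enthalpy and entropy into a Gibbs free energy record
#'
#' Bookkeeping identity `dG = dH - TdS`, with the entropy supplied as
#' the temperature-weighted term TdS (kcal/mol).
#'
#' @param enthalpy Binding enthalpy dH (kcal/mol).
#' @param entropy_term_TdS TdS (kcal/mol).
#' @return List of class `"free_energy_record"` with `enthalpy`,
#'   `entropy_term_TdS`, `gibbs`.
#' @export
combine_free_energy <- function(enthalpy, entropy_term_TdS) {
  structure(list(enthalpy = enthalpy,
                 entropy_term_TdS = entropy_term_TdS,
                 gibbs = enthalpy - entropy_term_TdS),
            class = "free_energy_record")
}

#' @export
print.free_energy_record <- function(x, ...) {
  cat(sprintf("dG = dH - TdS = %.1f - (%.1f) = %.1f kcal/mol\n",
              x$enthalpy, x$entropy_term_TdS, x$gibbs))
  invisible(x)
}

#' Per-frame energy component traces with moving average
#'
#' Recomputes the four-group components per frame and attaches a
#' centered moving-average smoothing of each, for contact-style
#' time-evolution plots.
#'
#' @param ensemble Parameterized `"ensemble"`.
#' @param aso_residues,hairpin_residues Residue index vectors.
#' @param smoothing_window Window in frames.
#' @param cutoff Cutoff (Angstrom).
#' @return data.frame: time, component, energy, smoothed.
#' @export
energy_timeseries <- function(ensemble, aso_residues, hairpin_residues,
                              smoothing_window = 1, cutoff = 10) {
  dec <- four_group_decomposition(ensemble, aso_residues,
                                  hairpin_residues, cutoff = cutoff)
  pf <- attr(dec, "per_frame")
  comps <- colnames(pf)
  pf <- cbind(pf, total = rowSums(pf))
  do.call(rbind, lapply(c(comps, "total"), function(cc) {
    data.frame(time = ensemble$times, component = cc,
               energy = pf[, cc],
               smoothed = moving_average(pf[, cc], smoothing_window))
  }))
}
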