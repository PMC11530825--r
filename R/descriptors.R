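# Global ensemble descriptors over heavy atoms: RMSD to a reference
# after optimal superposition, per-residue RMSF about the window mean,
# mass-weighted radius of gyration, and PCA of the superposed
# coordinate covariance.

selection_idx <- function(topology, selection) {
  at <- topology$atoms
  idx <- switch(selection,
                heavy = which(at$is_heavy),
                all = seq_len(nrow(at)),
                base = which(at$role == "base" & at$is_heavy),
                backbone = which(at$role == "backbone" & at$is_heavy),
                stop("unknown selection '", selection, "'"))
  if (length(idx) == 0L) stop("empty atom selection '", selection, "'")
  idx
}

#' RMSD trace relative to a reference structure
#'
#' Each frame is optimally superposed onto the reference over the
#' selection (Kabsch least squares) before the deviation is measured,
#' so global rigid motion does not contribute. Set `fit = FALSE` for a
#' no-fit RMSD.
#'
#' @param ensemble An `"ensemble"`.
#' @param reference Reference coordinates: a frame index into the
#'   ensemble (default 1, the starting structure) or an n_atoms x 3
#'   matrix.
#' @param selection `"heavy"` (default), `"all"`, `"base"`,
#'   `"backbone"`.
#' @param fit Superpose before measuring (default `TRUE`).
#' @return data.frame: time (ns), rmsd (Angstrom).
#' @export
rmsd_trace <- function(ensemble, reference = 1L, selection = "heavy",
                       fit = TRUE) {
  idx <- selection_idx(ensemble$topology, selection)
  ref <- if (is.matrix(reference)) reference
         else frame_xyz(ensemble, reference)
  if (nrow(ref) != dim(ensemble$xyz)[2])
    stop("reference atom count does not match ensemble")
  ref_sel <- ref[idx, , drop = FALSE]
  vals <- vapply(seq_len(n_frames(ensemble)), function(f) {
    m <- frame_xyz(ensemble, f)[idx, , drop = FALSE]
    if (fit) superpose_kabsch(m, ref_sel)$rmsd
    else sqrt(mean(rowSums((m - ref_sel)^2)))
  }, numeric(1))
  data.frame(time = ensemble$times, rmsd = vals)
}

# Superpose every selected-atom frame onto the iterated window mean
# (or take frames as already aligned when fit = FALSE).
superposed_stack <- function(ensemble, idx, frames, fit = TRUE) {
  stack <- lapply(frames, function(f)
    frame_xyz(ensemble, f)[idx, , drop = FALSE])
  if (!fit)
    return(list(stack = stack,
                mean = Reduce(`+`, stack) / length(stack)))
  mean_xyz <- stack[[1]]
  for (it in 1:2) {
    stack <- lapply(stack, function(m) superpose_kabsch(m, mean_xyz)$xyz)
    mean_xyz <- Reduce(`+`, stack) / length(stack)
  }
  list(stack = stack, mean = mean_xyz)
}

#' Per-residue RMSF over an analysis window
#'
#' Frames are superposed to the window-mean structure; the per-atom
#' RMSF is `sqrt(<|r - <r>|^2>)` and the residue value is the
#' unweighted mean over its heavy atoms. Choose the window to discard
#' equilibration (and, where late-trajectory artifacts dominate, to
#' stop early).
#'
#' @param ensemble An `"ensemble"`.
#' @param window Time window `c(start, end)` in ns, or `NULL`.
#' @param fit Superpose frames to the window mean first (default
#'   `TRUE`, the trajectory convention). Use `FALSE` for ensembles
#'   already expressed in a common frame (e.g. generator output),
#'   where fitting would leak mobile-residue noise into static ones.
#' @return data.frame: residue_index, nucleotide, region, rmsf (A).
#' @export
rmsf_per_residue <- function(ensemble, window = NULL, fit = TRUE) {
  frames <- window_frames(ensemble, window)
  topo <- ensemble$topology
  idx <- selection_idx(topo, "heavy")
  sp <- superposed_stack(ensemble, idx, frames, fit = fit)
  dev2 <- Reduce(`+`, lapply(sp$stack, function(m)
    rowSums((m - sp$mean)^2))) / length(sp$stack)
  atom_rmsf <- sqrt(dev2)
  res_of <- topo$atoms$residue_index[idx]
  agg <- tapply(atom_rmsf, res_of, mean)
  res <- topo$residues
  data.frame(residue_index = res$residue_index,
             nucleotide = res$nucleotide,
             region = res$region,
             rmsf = as.numeric(agg[as.character(res$residue_index)]))
}

#' Mass-weighted radius of gyration
#'
#' `sqrt( sum m_i |r_i - r_com|^2 / sum m_i )` over the selection,
#' with standard atomic masses (set `mass_weighted = FALSE` for the
#' unweighted variant).
#'
#' @param frame n_atoms x 3 matrix, or an `"ensemble"` (then a full
#'   trace is returned).
#' @param topology Matching `"topology"` (ignored for ensembles).
#' @param selection Atom selection (default heavy).
#' @param mass_weighted Logical.
#' @return Single value (Angstrom), or a data.frame time/rg trace.
#' @export
radius_of_gyration <- function(frame, topology = NULL,
                               selection = "heavy",
                               mass_weighted = TRUE) {
  if (inherits(frame, "ensemble")) {
    ens <- frame
    vals <- vapply(seq_len(n_frames(ens)), function(f)
      radius_of_gyration(frame_xyz(ens, f), ens$topology, selection,
                         mass_weighted), numeric(1))
    return(data.frame(time = ens$times, rg = vals))
  }
  idx <- selection_idx(topology, selection)
  m <- frame[idx, , drop = FALSE]
  w <- if (mass_weighted)
    ATOMIC_MASSES[topology$atoms$element[idx]] else rep(1, length(idx))
  com <- colSums(m * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(m, 2, com)^2)) / sum(w))
}

#' Principal component analysis of ensemble coordinates
#'
#' Frames are superposed to the iterated mean structure; PCA is the
#' eigendecomposition of the 3N-coordinate covariance. The variance
#' fraction of mode k is `lambda_k / sum(lambda)`.
#'
#' @param ensemble An `"ensemble"` with >= 2 frames.
#' @param selection Atom selection (default heavy).
#' @param fit Superpose frames to the iterated mean first (default
#'   `TRUE`); `FALSE` analyses the raw coordinates of an already
#'   aligned ensemble.
#' @return List of class `"ensemble_pca"`: `eigenvalues` (A^2,
#'   descending), `variance_fractions`, `modes` (3N x k), `mean`
#'   (n_sel x 3 matrix), `selection_idx`.
#' @export
pca_ensemble <- function(ensemble, selection = "heavy", fit = TRUE) {
  if (n_frames(ensemble) < 2L)
    stop("PCA needs at least 2 frames")
  idx <- selection_idx(ensemble$topology, selection)
  sp <- superposed_stack(ensemble, idx, seq_len(n_frames(ensemble)),
                         fit = fit)
  x <- t(vapply(sp$stack, function(m) as.numeric(t(m)),
                numeric(3L * length(idx))))
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  structure(list(eigenvalues = ev,
                 variance_fractions = ev / sum(ev),
                 modes = pr$rotation,
                 mean = sp$mean,
                 selection_idx = idx,
                 total_variance = sum(ev)),
            class = "ensemble_pca")
}

#' @export
print.ensemble_pca <- function(x, ...) {
  k <- min(3L, length(x$eigenvalues))
  cat("<ensemble_pca> top variance fractions:",
      paste(sprintf("PC%d %.1f%%", seq_len(k),
                    100 * x$variance_fractions[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Interpolated structures along a principal component
#'
#' Multi-model ensemble sweeping the mean structure by `+/- amplitude`
#' standard deviations along one PCA mode (for mode animation export).
#'
#' @param pca An `"ensemble_pca"`.
#' @param topology The topology the PCA selection refers to.
#' @param mode Mode number.
#' @param amplitude Sweep amplitude in mode standard deviations.
#' @param n_steps Number of interpolation frames.
#' @return An `"ensemble"` over the selected atoms' sub-topology.
#' @export
pca_mode_ensemble <- function(pca, topology, mode = 1L, amplitude = 2,
                              n_steps = 11L) {
  idx <- pca$selection_idx
  sub_atoms <- topology$atoms[idx, c("atom_name", "residue_index")]
  keep_res <- topology$residues$residue_index %in% sub_atoms$residue_index
  sub_topo <- build_topology(topology$residues[keep_res, , drop = FALSE],
                             sub_atoms)
  sdv <- sqrt(pca$eigenvalues[mode])
  v <- pca$modes[, mode]
  na <- length(idx)
  xyz <- array(0, dim = c(n_steps, na, 3L))
  scales <- seq(-amplitude, amplitude, length.out = n_steps)
  base_flat <- as.numeric(t(pca$mean))
  for (s in seq_len(n_steps)) {
    flat <- base_flat + scales[s] * sdv * v
    xyz[s, , ] <- matrix(flat, na, 3L, byrow = TRUE)
  }
  new_ensemble(sub_topo, xyz)
}
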