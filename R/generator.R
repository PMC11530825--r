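# Synthetic structural-ensemble generator. Scenes are built from
# idealized nucleotides posed into requested base-pair geometries, then
# animated with Gaussian positional noise and scheduled contacts, so
# fluctuation amplitudes, contact occupancies, pairing motifs, and
# puckers are all known ground truth for the analysis modules.

# Canonical donor/acceptor atom pairs per pairing geometry; the first
# named edge belongs to the first nucleotide.
HBOND_POSES <- list(
  "A:WC|U:WC" = list(c("N1", "N3"), c("N6", "O4")),
  "G:WC|C:WC" = list(c("O6", "N4"), c("N1", "N3"), c("N2", "O2")),
  "G:WC|U:WC" = list(c("O6", "N3"), c("N1", "O2")),
  "A:Hoogsteen|U:WC" = list(c("N7", "N3"), c("N6", "O4")),
  "G:Hoogsteen|C:WC" = list(c("N7", "N4"), c("O6", "N4"))
)

hbond_pose_pairs <- function(nuc_i, edge_i, nuc_j, edge_j) {
  k1 <- paste0(nuc_i, ":", edge_i, "|", nuc_j, ":", edge_j)
  k2 <- paste0(nuc_j, ":", edge_j, "|", nuc_i, ":", edge_i)
  if (!is.null(HBOND_POSES[[k1]])) return(list(pairs = HBOND_POSES[[k1]],
                                               swap = FALSE))
  if (!is.null(HBOND_POSES[[k2]])) return(list(pairs = HBOND_POSES[[k2]],
                                               swap = TRUE))
  stop("no pairing geometry defined for ", k1)
}

apply_rigid <- function(xyz, par, center) {
  r <- rotation_about_axis(
    if (sum(par[4:6]^2) < 1e-18) c(1, 0, 0) else par[4:6],
    sqrt(sum(par[4:6]^2)) * 180 / pi)
  sweep(sweep(xyz, 2, center) %*% t(r), 2, center + par[1:3], "+")
}

# Pose residue j against placed residue i so the listed donor-acceptor
# distances hit `d0` (2.9 A), bases stay coplanar, and heavy atoms do
# not clash. Rigid-body least squares from several starts.
pose_partner <- function(xyz_i, nuc_i, xyz_j, nuc_j, pairs, d0 = 2.9) {
  f_i <- base_frame(xyz_i, nuc_i)
  f_j <- base_frame(xyz_j, nuc_j)
  tgt <- flip_frame(f_i)
  r_init <- tgt$axes %*% t(f_j$axes)
  x0 <- sweep(xyz_j, 2, f_j$origin) %*% t(r_init)
  x0 <- sweep(x0, 2, tgt$origin, "+")

  heavy_i <- xyz_i[!grepl("^H", rownames(xyz_i)), , drop = FALSE]
  heavy_sel <- !grepl("^H", rownames(x0))
  n_i <- f_i$axes[, 3]
  ai <- vapply(pairs, `[`, character(1), 1)
  aj <- vapply(pairs, `[`, character(1), 2)
  cj <- colMeans(x0)
  # donor hydrogens per H-bond, to keep D-H...A near-linear and so
  # exclude mirror poses that meet the distances with H pointing away
  h_i <- lapply(ai, function(a)
    intersect(DONOR_HYDROGENS[[a]], rownames(xyz_i)))
  h_j <- lapply(aj, function(a)
    intersect(DONOR_HYDROGENS[[a]], rownames(x0)))

  objective <- function(par) {
    xj <- apply_rigid(x0, par, cj)
    s <- 0
    cos150 <- cos(150 * pi / 180)
    for (k in seq_along(ai)) {
      d <- sqrt(sum((xyz_i[ai[k], ] - xj[aj[k], ])^2))
      s <- s + 10 * (d - d0)^2
      lin <- function(hpos, dpos, apos) {
        v1 <- dpos - hpos; v2 <- apos - hpos
        ct <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        max(0, ct - cos150)^2
      }
      if (length(h_i[[k]]))
        s <- s + 3 * min(vapply(h_i[[k]], function(h)
          lin(xyz_i[h, ], xyz_i[ai[k], ], xj[aj[k], ]), numeric(1)))
      if (length(h_j[[k]]))
        s <- s + 3 * min(vapply(h_j[[k]], function(h)
          lin(xj[h, ], xj[aj[k], ], xyz_i[ai[k], ]), numeric(1)))
    }
    hj <- xj[heavy_sel, , drop = FALSE]
    dd <- sqrt(outer(rowSums(heavy_i^2), rowSums(hj^2), "+") -
                 2 * heavy_i %*% t(hj))
    viol <- pmax(0, 2.6 - dd)
    s <- s + 2 * sum(viol^2)
    fj <- tryCatch(base_frame(xj, nuc_j), error = function(e) NULL)
    if (!is.null(fj)) s <- s + 5 * (1 - sum(n_i * fj$axes[, 3])^2)
    s
  }
  best <- NULL
  for (ang in seq(0, 315, by = 45)) {
    start <- c(0, 0, 0, (ang * pi / 180) * n_i)
    fit <- stats::optim(start, objective, method = "BFGS",
                        control = list(maxit = 300, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
    if (best$value < 1e-6) break
  }
  apply_rigid(x0, best$par, cj)
}

#' Build a one-frame ensemble realizing a base-pairing plan
#'
#' Residues are built from idealized templates and rigidly posed so that
#' each requested pair presents its canonical donor-acceptor contacts at
#' hydrogen-bond geometry on the requested edges. A residue appearing as
#' partner in two rows of the plan on distinct edges yields a triple
#' base pair.
#'
#' @param residues data.frame: `residue_index`, `nucleotide`, optional
#'   `chain_label`, `pucker` (conformer), `chi` (degrees).
#' @param plan data.frame: `res_i`, `res_j`, `edge_i`, `edge_j` (edges
#'   "WC" or "Hoogsteen"; `res_i` must already be placed or be the
#'   anchor).
#' @param region_map Passed to [build_topology()].
#' @return A one-frame `"ensemble"`.
#' @export
build_paired_arrangement <- function(residues, plan = NULL,
                                     region_map = NULL) {
  if (is.null(residues$chain_label)) residues$chain_label <- "A"
  if (is.null(residues$pucker)) residues$pucker <- "C3'-endo"
  if (is.null(residues$chi)) residues$chi <- -160
  built <- lapply(seq_len(nrow(residues)), function(i) {
    nt <- build_nucleotide(residues$nucleotide[i], residues$pucker[i],
                           residues$chi[i])
    as_named_xyz(nt)
  })
  names(built) <- as.character(residues$residue_index)
  placed <- list()
  n_anchor <- 0L
  if (!is.null(plan) && nrow(plan) > 0L) {
    for (r in seq_len(nrow(plan))) {
      i <- as.character(plan$res_i[r])
      j <- as.character(plan$res_j[r])
      nuc_i <- residues$nucleotide[residues$residue_index == plan$res_i[r]]
      nuc_j <- residues$nucleotide[residues$residue_index == plan$res_j[r]]
      if (length(nuc_i) == 0L || length(nuc_j) == 0L)
        stop("plan references unknown residue in row ", r)
      if (is.null(placed[[i]])) {
        off <- c(0, 0, 30 * n_anchor)
        n_anchor <- n_anchor + 1L
        placed[[i]] <- sweep(built[[i]], 2, off, "+")
      }
      pose <- hbond_pose_pairs(nuc_i, plan$edge_i[r], nuc_j, plan$edge_j[r])
      pairs <- pose$pairs
      if (pose$swap) pairs <- lapply(pairs, rev)
      if (is.null(placed[[j]])) {
        placed[[j]] <- pose_partner(placed[[i]], nuc_i, built[[j]], nuc_j,
                                    pairs)
      }
    }
  }
  k <- 0L
  for (i in as.character(residues$residue_index)) {
    if (is.null(placed[[i]])) {
      k <- k + 1L
      placed[[i]] <- sweep(built[[i]], 2, c(40 * k, 40 * k, 0), "+")
    }
  }
  # steric feasibility across distinct residues
  for (a in seq_len(nrow(residues) - 1L)) for (b in (a + 1L):nrow(residues)) {
    xa <- placed[[as.character(residues$residue_index[a])]]
    xb <- placed[[as.character(residues$residue_index[b])]]
    dmin <- sqrt(max(0, min(outer(rowSums(xa^2), rowSums(xb^2), "+") -
                              2 * xa %*% t(xb))))
    if (dmin < 1.5)
      stop("sterically impossible plan: residues ",
           residues$residue_index[a], " and ", residues$residue_index[b],
           " overlap (min distance ", round(dmin, 2), " A)")
  }
  atom_rows <- do.call(rbind, lapply(seq_len(nrow(residues)), function(i) {
    m <- placed[[as.character(residues$residue_index[i])]]
    data.frame(atom_name = rownames(m),
               residue_index = residues$residue_index[i],
               x = m[, 1], y = m[, 2], z = m[, 3], row.names = NULL)
  }))
  topo <- build_topology(residues[, c("residue_index", "nucleotide",
                                      "chain_label")],
                         atom_rows[, c("atom_name", "residue_index")],
                         region_map = region_map)
  new_ensemble(topo, as.matrix(atom_rows[, c("x", "y", "z")]))
}

#' Gaussian positional fluctuation around a reference frame
#'
#' Frame i = reference + independent isotropic Gaussian displacement per
#' atom, with the standard deviation of the atom's residue. Per-atom
#' RMSF about the ensemble mean converges to sigma * sqrt(3).
#'
#' @param reference A one-frame `"ensemble"` (or any ensemble; frame 1
#'   is the reference).
#' @param per_residue_sigma Sigma (Angstrom) per residue, recycled.
#' @param n_frames Number of frames to generate.
#' @param seed Integer seed; equal seeds give bit-identical ensembles.
#' @param dt Time step between frames (ns).
#' @return An `"ensemble"` with `n_frames` frames.
#' @export
perturb <- function(reference, per_residue_sigma, n_frames, seed = 1,
                    dt = 1) {
  stopifnot(inherits(reference, "ensemble"), n_frames >= 1)
  topo <- reference$topology
  nres <- nrow(topo$residues)
  sig <- rep_len(per_residue_sigma, nres)
  if (any(sig < 0)) stop("fluctuation sigma must be >= 0")
  atom_sig <- sig[match(topo$atoms$residue_index,
                        topo$residues$residue_index)]
  ref <- frame_xyz(reference, 1L)
  na <- nrow(ref)
  xyz <- array(0, dim = c(n_frames, na, 3L))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "perturb"))
  for (f in seq_len(n_frames)) {
    noise <- matrix(stats::rnorm(na * 3L, sd = rep(atom_sig, 3L)), na, 3L)
    xyz[f, , ] <- ref + noise
  }
  ens <- new_ensemble(topo, xyz, times = dt * (seq_len(n_frames) - 1L))
  attr(ens, "ground_truth") <- list(per_residue_sigma = sig, seed = seed)
  ens
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Impose scheduled on/off contacts with known occupancy
#'
#' For each schedule the mobile residue (`res_j`) keeps its in-contact
#' coordinates in a deterministic, seed-chosen fraction of frames equal
#' to the target occupancy (realized as ceiling(occupancy * n_frames)
#' frames, i.e. the smallest count not below the target), and is
#' displaced far beyond every contact cutoff otherwise.
#'
#' @param ensemble An `"ensemble"` whose reference geometry has each
#'   scheduled pair in contact.
#' @param schedules data.frame: `res_i`, `res_j`, `occupancy` in [0,1].
#' @param seed Integer seed for the frame selection.
#' @return The modified ensemble; `attr(, "ground_truth")$schedules`
#'   records the realized on-frame counts.
#' @export
schedule_contacts <- function(ensemble, schedules, seed = 1) {
  stopifnot(inherits(ensemble, "ensemble"))
  key <- paste(pmin(schedules$res_i, schedules$res_j),
               pmax(schedules$res_i, schedules$res_j))
  if (anyDuplicated(key))
    stop("conflicting schedules on pair ", key[duplicated(key)][1])
  if (anyDuplicated(schedules$res_j))
    stop("residue ", schedules$res_j[duplicated(schedules$res_j)][1],
         " is the mobile member of more than one schedule")
  if (any(schedules$occupancy < 0 | schedules$occupancy > 1))
    stop("occupancy must lie in [0, 1]")
  topo <- ensemble$topology
  nf <- n_frames(ensemble)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  realized <- integer(nrow(schedules))
  for (s in seq_len(nrow(schedules))) {
    ri <- schedules$res_i[s]; rj <- schedules$res_j[s]
    idx_i <- which(topo$atoms$residue_index == ri & topo$atoms$is_heavy)
    idx_j <- which(topo$atoms$residue_index == rj)
    if (length(idx_i) == 0L || length(idx_j) == 0L)
      stop("schedule pair (", ri, ", ", rj, ") references missing residue")
    xi <- frame_xyz(ensemble, 1L)[idx_i, , drop = FALSE]
    xj <- frame_xyz(ensemble, 1L)[intersect(idx_j,
            which(topo$atoms$is_heavy)), , drop = FALSE]
    dmin <- sqrt(min(outer(rowSums(xi^2), rowSums(xj^2), "+") -
                       2 * xi %*% t(xj)))
    if (dmin > 4.0)
      stop("schedule pair (", ri, ", ", rj,
           ") is not in contact geometry in the reference frame")
    n_on <- min(nf, as.integer(ceiling(schedules$occupancy[s] * nf - 1e-9)))
    realized[s] <- n_on
    set.seed(derive_seed(seed, paste0("schedule_", ri, "_", rj)))
    on_frames <- sort(sample.int(nf, n_on))
    off <- setdiff(seq_len(nf), on_frames)
    # displace radially outward from the complex center, past every
    # contact and energy cutoff but without teleporting across the box
    all_xyz <- frame_xyz(ensemble, 1L)
    dir <- colMeans(all_xyz[idx_j, , drop = FALSE]) - colMeans(all_xyz)
    nrm <- sqrt(sum(dir^2))
    dir <- if (nrm < 1e-6) c(0, 0, 1) else dir / nrm
    shift <- dir * (25 + 5 * s)
    for (f in off)
      ensemble$xyz[f, idx_j, ] <- sweep(ensemble$xyz[f, idx_j, ,
                                                     drop = TRUE], 2,
                                        shift, "+")
  }
  gt <- attr(ensemble, "ground_truth")
  if (is.null(gt)) gt <- list()
  gt$schedules <- cbind(schedules, n_on = realized, n_frames = nf)
  gt$schedule_seed <- seed
  attr(ensemble, "ground_truth") <- gt
  ensemble
}

#' Small built-in demonstration scene
#'
#' A nine-residue ASO--hairpin miniature: a three-residue ASO (chain B)
#' bound to a six-residue hairpin (chain A) with two Watson-Crick stem
#' pairs, one ASO Watson-Crick pair, and one ASO Hoogsteen interaction
#' that completes a U.A-U triple at the stem. Gaussian fluctuations and
#' one scheduled intermittent contact provide dynamics with known
#' ground truth.
#'
#' @param seed Integer seed.
#' @param n_frames Number of frames (default 100).
#' @param sigma Baseline fluctuation (Angstrom).
#' @return List: `ensemble`, `regions`, `pairing` (stem pairs for
#'   helical parameters), `plan`, `ground_truth`.
#' @export
demo_scene <- function(seed = 1, n_frames = 100, sigma = 0.05) {
  residues <- data.frame(
    residue_index = 1:9,
    nucleotide = c("U", "G", "U", "A", "G", "C", "G", "C", "U"),
    chain_label = c("B", "B", "B", rep("A", 6)))
  regions <- list(aso = 1:3, hairpin_strand1 = 4:6, hairpin_strand2 = 7:9)
  plan <- data.frame(
    res_i = c(4, 5, 4, 2),
    res_j = c(9, 8, 1, 6),
    edge_i = c("WC", "WC", "Hoogsteen", "WC"),
    edge_j = c("WC", "WC", "WC", "WC"))
  # the posed scene is deterministic; cache it for repeated runs
  if (is.null(.ring_cache[["demo_scene"]]))
    .ring_cache[["demo_scene"]] <-
      build_paired_arrangement(residues, plan, region_map = regions)
  scene <- .ring_cache[["demo_scene"]]
  sig <- rep(sigma, 9)
  sig[3] <- 0.4  # one mobile ASO tail residue
  ens <- perturb(scene, sig, n_frames, seed = seed)
  ens <- schedule_contacts(ens, data.frame(res_i = 2, res_j = 6,
                                           occupancy = 0.6), seed = seed)
  gt <- attr(ens, "ground_truth")
  gt$plan <- plan
  attr(ens, "ground_truth") <- gt
  list(ensemble = ens, regions = regions,
       pairing = data.frame(res_i = c(4, 5), res_j = c(9, 8)),
       plan = plan, ground_truth = gt)
}
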