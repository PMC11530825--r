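#' Contact-detection criteria
#'
#' Numeric criteria for typed atom contacts. Defaults follow common MD
#' analysis practice: hydrogen bonds at heavy-atom donor-acceptor
#' distance <= 3.0 A with donor-H...acceptor angle >= 135 degrees (the
#' angle test applies only when hydrogens are present), salt bridges at
#' <= 4.0 A between oppositely charged formal-charge groups, apolar
#' (hydrophobic/stacking proxy) contacts at carbon-carbon <= 4.0 A.
#'
#' @param hbond_dist,salt_dist,apolar_dist Distance cutoffs (Angstrom).
#' @param hbond_angle Minimum donor-H...acceptor angle (degrees).
#' @param use_hydrogen_angle Apply the angle criterion when the donor's
#'   hydrogens are present (`TRUE`, the strict MD convention);
#'   `FALSE` gives a distance-only criterion (the base-pair-annotation
#'   convention of [pairing_criteria()]).
#' @return List of class `"contact_criteria"`.
#' @export
contact_criteria <- function(hbond_dist = 3.0, hbond_angle = 135,
                             salt_dist = 4.0, apolar_dist = 4.0,
                             use_hydrogen_angle = TRUE) {
  if (any(c(hbond_dist, salt_dist, apolar_dist) <= 0))
    stop("distance cutoffs must be positive")
  if (hbond_angle <= 0 || hbond_angle > 180)
    stop("hbond angle must lie in (0, 180]")
  structure(list(hbond_dist = hbond_dist, hbond_angle = hbond_angle,
                 salt_dist = salt_dist, apolar_dist = apolar_dist,
                 use_hydrogen_angle = isTRUE(use_hydrogen_angle)),
            class = "contact_criteria")
}

# Pairwise distance matrix between two coordinate sets.
cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

#' Detect typed atom contacts in one frame
#'
#' Hydrogen bonds (donor-acceptor heavy atoms within cutoff, and, when
#' the donor's hydrogens are in the topology, donor-H...acceptor angle
#' above threshold), salt bridges (opposite formal charges within
#' cutoff) and apolar carbon-carbon contacts. Each qualifying atom pair
#' is reported once with a single type (precedence hydrogen bond >
#' salt bridge > apolar). Same-residue pairs and covalent-neighbor
#' residues (|i-j| <= 1 within one chain) are excluded.
#'
#' A contact is *specific* when both atoms are base-role; any contact
#' involving a backbone atom is *nonspecific*.
#'
#' @param frame n_atoms x 3 coordinate matrix (or an `"ensemble"`, in
#'   which case `frame_index` selects the frame).
#' @param topology Matching `"topology"`.
#' @param criteria A [contact_criteria()] object.
#' @param frame_index Frame label stored in the output.
#' @return data.frame: frame, res_i, res_j (i < j), atom_i, atom_j,
#'   type, specificity.
#' @export
detect_contacts <- function(frame, topology,
                            criteria = contact_criteria(),
                            frame_index = 1L) {
  if (inherits(frame, "ensemble")) {
    topology <- frame$topology
    frame <- frame_xyz(frame, frame_index)
  }
  at <- topology$atoms
  if (nrow(frame) != nrow(at))
    stop("frame has ", nrow(frame), " atoms; topology has ", nrow(at))
  res <- topology$residues
  chain <- res$chain_label[match(at$residue_index, res$residue_index)]
  sign_of <- if (is.null(at$formal_sign))
    ifelse(at$is_charged, -1L, 0L) else at$formal_sign

  allowed_pair <- function(ii, jj) {
    ri <- at$residue_index[ii]; rj <- at$residue_index[jj]
    ok <- ri != rj
    same_chain <- chain[ii] == chain[jj]
    ok & !(same_chain & abs(ri - rj) <= 1L)
  }
  collect <- function(ii, jj, d, type) {
    if (length(ii) == 0L) return(NULL)
    data.frame(atom_a = ii, atom_b = jj, type = type)
  }
  found <- list()

  don <- which(at$is_donor & at$is_heavy)
  acc <- which(at$is_acceptor & at$is_heavy)
  if (length(don) && length(acc)) {
    dd <- cross_dist(frame[don, , drop = FALSE], frame[acc, , drop = FALSE])
    hit <- which(dd <= criteria$hbond_dist, arr.ind = TRUE)
    if (nrow(hit)) {
      ii <- don[hit[, 1]]; jj <- acc[hit[, 2]]
      keep <- ii != jj & allowed_pair(ii, jj)
      ii <- ii[keep]; jj <- jj[keep]
      ok <- vapply(seq_along(ii), function(k) {
        if (!criteria$use_hydrogen_angle) return(TRUE)
        hyd <- donor_hydrogen_idx(at, ii[k])
        if (length(hyd) == 0L) return(TRUE)  # distance-only criterion
        any(vapply(hyd, function(h) {
          v1 <- frame[ii[k], ] - frame[h, ]
          v2 <- frame[jj[k], ] - frame[h, ]
          ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                    sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
          ang >= criteria$hbond_angle
        }, logical(1)))
      }, logical(1))
      found$hbond <- collect(ii[ok], jj[ok], NULL, "hbond")
    }
  }

  chg <- which(sign_of != 0L & at$is_heavy)
  if (length(chg) > 1L) {
    dd <- cross_dist(frame[chg, , drop = FALSE], frame[chg, , drop = FALSE])
    hit <- which(dd <= criteria$salt_dist, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    if (nrow(hit)) {
      ii <- chg[hit[, 1]]; jj <- chg[hit[, 2]]
      keep <- allowed_pair(ii, jj) & sign_of[ii] * sign_of[jj] < 0
      found$salt <- collect(ii[keep], jj[keep], NULL, "salt_bridge")
    }
  }

  apo <- which(at$is_apolar & at$is_heavy)
  if (length(apo) > 1L) {
    dd <- cross_dist(frame[apo, , drop = FALSE], frame[apo, , drop = FALSE])
    hit <- which(dd <= criteria$apolar_dist, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    if (nrow(hit)) {
      ii <- apo[hit[, 1]]; jj <- apo[hit[, 2]]
      keep <- allowed_pair(ii, jj)
      found$apolar <- collect(ii[keep], jj[keep], NULL, "apolar")
    }
  }

  recs <- do.call(rbind, found)
  if (is.null(recs) || nrow(recs) == 0L)
    return(data.frame(frame = integer(0), res_i = integer(0),
                      res_j = integer(0), atom_i = character(0),
                      atom_j = character(0), type = character(0),
                      specificity = character(0)))
  # canonical atom order, then de-duplicate by type precedence
  a <- pmin(recs$atom_a, recs$atom_b)
  b <- pmax(recs$atom_a, recs$atom_b)
  prec <- c(hbond = 1L, salt_bridge = 2L, apolar = 3L)
  o <- order(a, b, prec[recs$type])
  a <- a[o]; b <- b[o]; ty <- recs$type[o]
  keep <- !duplicated(paste(a, b))
  a <- a[keep]; b <- b[keep]; ty <- ty[keep]
  swap <- at$residue_index[a] > at$residue_index[b]
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  data.frame(
    frame = frame_index,
    res_i = at$residue_index[a], res_j = at$residue_index[b],
    atom_i = at$atom_name[a], atom_j = at$atom_name[b], type = ty,
    specificity = ifelse(at$role[a] == "base" & at$role[b] == "base",
                         "specific", "nonspecific"))
}

donor_hydrogen_idx <- function(at, donor_idx) {
  hn <- DONOR_HYDROGENS[[at$atom_name[donor_idx]]]
  if (is.null(hn)) return(integer(0))
  which(at$residue_index == at$residue_index[donor_idx] &
          at$atom_name %in% hn)
}

#' Unit-weight contact strength of a residue pair in one frame
#'
#' Every contact record counts 1 regardless of type, so the strength of
#' a residue pair is simply its number of simultaneous atom contacts.
#'
#' @param records Contact records of one frame ([detect_contacts()]).
#' @param residue_pair Length-2 residue-index vector.
#' @return Integer count.
#' @export
contact_strength <- function(records, residue_pair) {
  i <- min(residue_pair); j <- max(residue_pair)
  sum(records$res_i == i & records$res_j == j)
}

#' Per-residue-pair contact time series over an ensemble
#'
#' Runs contact detection on every frame of the analysis window and
#' aggregates to residue pairs: per-frame presence and unit-weight
#' strength (split by specificity), occupancy (fraction of window
#' frames with any contact), and mean strength over the window.
#'
#' @param ensemble An `"ensemble"`.
#' @param criteria A [contact_criteria()] object.
#' @param window Time window `c(start, end)` in ns, or `NULL` for all
#'   frames (set it to discard equilibration).
#' @return Object of class `"contact_series"`: `pairs` data.frame
#'   (res_i, res_j, occupancy, mean_strength, mean_specific,
#'   mean_nonspecific), plus presence/strength matrices (pair x frame).
#' @export
build_series <- function(ensemble, criteria = contact_criteria(),
                         window = NULL) {
  idx <- window_frames(ensemble, window)
  recs <- do.call(rbind, lapply(idx, function(f)
    detect_contacts(frame_xyz(ensemble, f), ensemble$topology, criteria,
                    frame_index = f)))
  if (is.null(recs) || nrow(recs) == 0L) {
    return(structure(list(
      pairs = data.frame(res_i = integer(0), res_j = integer(0),
                         occupancy = numeric(0), mean_strength = numeric(0),
                         mean_specific = numeric(0),
                         mean_nonspecific = numeric(0)),
      presence = matrix(FALSE, 0, length(idx)),
      strength = matrix(0L, 0, length(idx)),
      specific = matrix(0L, 0, length(idx)),
      frame_idx = idx, times = ensemble$times[idx],
      criteria = criteria), class = "contact_series"))
  }
  pair_key <- paste(recs$res_i, recs$res_j)
  pairs <- unique(recs[, c("res_i", "res_j")])
  pairs <- pairs[order(pairs$res_i, pairs$res_j), , drop = FALSE]
  ukey <- paste(pairs$res_i, pairs$res_j)
  np <- nrow(pairs); nw <- length(idx)
  strength <- matrix(0L, np, nw)
  specific <- matrix(0L, np, nw)
  fcol <- match(recs$frame, idx)
  prow <- match(pair_key, ukey)
  is_spec <- recs$specificity == "specific"
  for (k in seq_len(nrow(recs))) {
    strength[prow[k], fcol[k]] <- strength[prow[k], fcol[k]] + 1L
    if (is_spec[k])
      specific[prow[k], fcol[k]] <- specific[prow[k], fcol[k]] + 1L
  }
  presence <- strength > 0L
  pairs$occupancy <- rowMeans(presence)
  pairs$mean_strength <- rowMeans(strength)
  pairs$mean_specific <- rowMeans(specific)
  pairs$mean_nonspecific <- rowMeans(strength - specific)
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, presence = presence, strength = strength,
                 specific = specific, frame_idx = idx,
                 times = ensemble$times[idx], criteria = criteria),
            class = "contact_series")
}

#' @export
print.contact_series <- function(x, ...) {
  cat("<contact_series> ", nrow(x$pairs), " residue pairs over ",
      length(x$frame_idx), " frames\n", sep = "")
  invisible(x)
}

#' Keep residue pairs present in more than a fraction of the trajectory
#'
#' The occupancy filter is strict: a pair at exactly the threshold is
#' removed. The default threshold 0.10 keeps contacts present for
#' longer than 10% of the analysis window.
#'
#' @param series A `"contact_series"`.
#' @param threshold Occupancy threshold in (0, 1).
#' @return Filtered `"contact_series"` (ordering preserved).
#' @export
occupancy_filter <- function(series, threshold = 0.10) {
  stopifnot(inherits(series, "contact_series"))
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)")
  keep <- series$pairs$occupancy > threshold
  series$pairs <- series$pairs[keep, , drop = FALSE]
  rownames(series$pairs) <- NULL
  series$presence <- series$presence[keep, , drop = FALSE]
  series$strength <- series$strength[keep, , drop = FALSE]
  series$specific <- series$specific[keep, , drop = FALSE]
  series
}

#' Mean contact-strength map over residue pairs
#'
#' Symmetric residue x residue matrix of window-mean strengths,
#' reported separately for specific and nonspecific contacts or
#' combined; specific + nonspecific = all, entry by entry.
#'
#' @param series A `"contact_series"`.
#' @param mode `"specific"`, `"nonspecific"` or `"all"`.
#' @param n_residues Matrix dimension (default: largest residue index).
#' @return Symmetric numeric matrix.
#' @export
contact_map <- function(series, mode = c("all", "specific", "nonspecific"),
                        n_residues = NULL) {
  mode <- match.arg(mode)
  p <- series$pairs
  if (is.null(n_residues))
    n_residues <- if (nrow(p)) max(p$res_j) else 0L
  m <- matrix(0, n_residues, n_residues)
  if (nrow(p) == 0L) return(m)
  val <- switch(mode, all = p$mean_strength, specific = p$mean_specific,
                nonspecific = p$mean_nonspecific)
  for (k in seq_len(nrow(p))) {
    m[p$res_i[k], p$res_j[k]] <- val[k]
    m[p$res_j[k], p$res_i[k]] <- val[k]
  }
  m
}

#' Block-wise evolution of contact occupancy and strength
#'
#' Splits the analysis window into `n_blocks` equal frame blocks and
#' reports per-pair occupancy and mean strength per block, resolving
#' contact-network rearrangements in time.
#'
#' @param series A `"contact_series"`.
#' @param n_blocks Number of equal frame blocks (>= 1).
#' @return data.frame: res_i, res_j, block, occupancy, mean_strength.
#' @export
contact_evolution <- function(series, n_blocks) {
  stopifnot(inherits(series, "contact_series"))
  nw <- length(series$frame_idx)
  if (n_blocks < 1) stop("n_blocks must be >= 1")
  if (n_blocks > nw)
    stop("n_blocks (", n_blocks, ") exceeds window frame count (", nw, ")")
  block_of <- ceiling(seq_len(nw) / (nw / n_blocks))
  out <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
    cols <- which(block_of == b)
    data.frame(res_i = series$pairs$res_i, res_j = series$pairs$res_j,
               block = b,
               occupancy = rowMeans(series$presence[, cols, drop = FALSE]),
               mean_strength = rowMeans(series$strength[, cols,
                                                        drop = FALSE]))
  }))
  rownames(out) <- NULL
  out
}
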