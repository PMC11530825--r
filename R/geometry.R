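#' Signed dihedral angle of four points
#'
#' Standard atan2 construction; result in (-180, 180] degrees.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom).
#' @return Angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (sum(b1^2) < 1e-12 || sum(b2^2) < 1e-12 || sum(b3^2) < 1e-12)
    stop("degenerate geometry: consecutive points coincide")
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12)
    stop("degenerate geometry: collinear points")
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  wrap_angle(ang)
}

# Endocyclic torsion definitions nu0..nu4 of the furanose ring.
RING_TORSIONS <- list(
  nu0 = c("C4'", "O4'", "C1'", "C2'"),
  nu1 = c("O4'", "C1'", "C2'", "C3'"),
  nu2 = c("C1'", "C2'", "C3'", "C4'"),
  nu3 = c("C2'", "C3'", "C4'", "O4'"),
  nu4 = c("C3'", "C4'", "O4'", "C1'")
)

# Pseudorotation wheel: 20 classes of 18 degrees, envelopes centered at
# 18 + 36k, twists between them. C3'-endo is centered at P = 18,
# C2'-endo at 162, C2'-exo at 342.
PUCKER_CLASSES <- c(
  "C3'-exo/C2'-endo-twist",  # this placeholder is overwritten below
  rep(NA, 19))
PUCKER_CLASSES <- {
  env <- c("C3'-endo", "C4'-exo", "O4'-endo", "C1'-exo", "C2'-endo",
           "C3'-exo", "C4'-endo", "O4'-exo", "C1'-endo", "C2'-exo")
  tw <- paste0(c("C2'-exo", env[-10]), "/", env, "-twist")
  out <- character(20)
  out[seq(2, 20, 2)] <- env       # centers 18, 54, ..., 342
  out[seq(1, 19, 2)] <- tw        # centers 0, 36, ..., 324
  out
}

#' Sugar pucker pseudorotation phase, amplitude, and conformer
#'
#' Computes the five endocyclic torsions nu0..nu4 and derives the
#' pseudorotation phase P and amplitude via
#' `tan P = ((nu4 + nu1) - (nu3 + nu0)) / (2 nu2 (sin 36 + sin 72))`,
#' then classifies P into one of twenty 18-degree conformer sectors
#' (C3'-endo centered at 18 degrees, C2'-endo at 162, ...).
#'
#' @param coords Named matrix (rownames = atom names) or data.frame of
#'   residue coordinates containing the five ring atoms
#'   C1', C2', C3', C4', O4'.
#' @return List of class `"pucker_state"`: `phase` (degrees, [0, 360)),
#'   `amplitude` (degrees), `conformer` (name or "planar"), `nu`
#'   (the five torsions).
#' @export
pucker <- function(coords) {
  xyz <- as_named_xyz(coords)
  ring <- c("C1'", "C2'", "C3'", "C4'", "O4'")
  miss <- setdiff(ring, rownames(xyz))
  if (length(miss))
    stop("missing sugar ring atom(s): ", paste(miss, collapse = ", "))
  nu <- vapply(RING_TORSIONS, function(a)
    dihedral(xyz[a[1], ], xyz[a[2], ], xyz[a[3], ], xyz[a[4], ]),
    numeric(1))
  if (all(abs(nu) < 1e-6))
    return(structure(list(phase = NA_real_, amplitude = 0,
                          conformer = "planar", nu = nu),
                     class = "pucker_state"))
  denom <- 2 * nu[["nu2"]] * (sin(36 * pi / 180) + sin(72 * pi / 180))
  p <- atan2((nu[["nu4"]] + nu[["nu1"]]) - (nu[["nu3"]] + nu[["nu0"]]),
             denom) * 180 / pi
  # atan2 already resolves the nu2 < 0 branch; fold into [0, 360)
  p <- p %% 360
  amp <- nu[["nu2"]] / cos(p * pi / 180)
  sector <- floor(((p + 9) %% 360) / 18) + 1L
  structure(list(phase = p, amplitude = abs(amp),
                 conformer = PUCKER_CLASSES[sector], nu = nu),
            class = "pucker_state")
}

#' @export
print.pucker_state <- function(x, ...) {
  cat(sprintf("<pucker> P = %.1f deg, amplitude = %.1f deg, %s\n",
              x$phase, x$amplitude, x$conformer))
  invisible(x)
}

# Coerce residue coordinates (matrix with rownames, or data.frame with
# atom_name/x/y/z) to a named n x 3 matrix.
as_named_xyz <- function(coords) {
  if (is.data.frame(coords)) {
    m <- as.matrix(coords[, c("x", "y", "z")])
    rownames(m) <- coords$atom_name
    return(m)
  }
  stopifnot(is.matrix(coords), ncol(coords) == 3L,
            !is.null(rownames(coords)))
  coords
}

#' Fit the standard reference frame to a base
#'
#' Least-squares superposition of the idealized planar base template
#' (in its standard reference frame) onto the observed base ring atoms.
#' The recovered rotation and origin constitute the base frame used for
#' base-pair and step parameters.
#'
#' @param coords Residue coordinates (named matrix or data.frame).
#' @param nucleotide "A", "C", "G" or "U".
#' @return List: `origin` (3-vector), `axes` (3 x 3 matrix, columns =
#'   x/y/z axes), `rmsd` of the template fit.
#' @export
base_frame <- function(coords, nucleotide) {
  xyz <- as_named_xyz(coords)
  tpl <- BASE_TEMPLATES[[nucleotide]]
  ring <- if (nucleotide %in% c("A", "G"))
    c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
  else c("N1", "C2", "N3", "C4", "C5", "C6")
  miss <- setdiff(ring, rownames(xyz))
  if (length(miss))
    stop("missing base ring atom(s): ", paste(miss, collapse = ", "))
  obs <- xyz[ring, , drop = FALSE]
  ref <- tpl[ring, , drop = FALSE]
  fit <- superpose_kabsch(ref, obs)
  # template point p maps to R p + t; frame axes are R's columns
  rot <- fit$rotation
  origin <- as.numeric(fit$xyz[1, ] - ref[1, , drop = FALSE] %*% t(rot))
  list(origin = origin, axes = rot, rmsd = fit$rmsd)
}

# Flip a base frame for the complementary strand (rotate 180 about x:
# y and z axes reverse) so both frames of a pair share a sense.
flip_frame <- function(frame) {
  frame$axes[, 2] <- -frame$axes[, 2]
  frame$axes[, 3] <- -frame$axes[, 3]
  frame
}

# Signed angle (degrees) from vector a to b about axis n.
signed_angle_about <- function(a, b, n) {
  n <- n / sqrt(sum(n^2))
  a <- a - sum(a * n) * n
  b <- b - sum(b * n) * n
  atan2(sum(n * cross3(a, b)), sum(a * b)) * 180 / pi
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Mid-frame parameter algebra shared by intra-base-pair and step
# parameters (CEHS / standard-reference-frame construction): the
# relative rotation is split into a twist about the mean z axis and a
# roll-tilt rotation about a hinge perpendicular to both z axes;
# translations are expressed in the mid frame.
frame_params <- function(f1, f2) {
  z1 <- f1$axes[, 3]; z2 <- f2$axes[, 3]
  cosg <- max(-1, min(1, sum(z1 * z2)))
  gamma <- acos(cosg) * 180 / pi
  if (gamma > 1e-9) {
    hinge <- cross3(z1, z2)
    r_half <- rotation_about_axis(hinge, gamma / 2)
    a1 <- r_half %*% f1$axes
    a2 <- t(rotation_about_axis(hinge, gamma / 2)) %*% f2$axes
  } else {
    hinge <- f1$axes[, 1]
    a1 <- f1$axes
    a2 <- f2$axes
  }
  zm <- (a1[, 3] + a2[, 3])
  zm <- zm / sqrt(sum(zm^2))
  twist <- signed_angle_about(a1[, 2], a2[, 2], zm)
  ym <- a1[, 2] + a2[, 2]
  ym <- ym / sqrt(sum(ym^2))
  xm <- cross3(ym, zm)
  rm <- cbind(xm, ym, zm)
  phi <- if (gamma > 1e-9) signed_angle_about(hinge, ym, zm) else 0
  roll <- gamma * cos(phi * pi / 180)
  tilt <- gamma * sin(phi * pi / 180)
  tr <- as.numeric(t(rm) %*% (f2$origin - f1$origin))
  list(translation = tr, rot = c(tilt = tilt, roll = roll, twist = twist),
       mid_frame = list(origin = (f1$origin + f2$origin) / 2, axes = rm))
}

#' Intra-base-pair and base-pair-step helical parameters
#'
#' Given the base frames of a pair (strand-2 frame supplied unflipped;
#' it is flipped internally) this returns shear/stretch/stagger and
#' buckle/propeller/opening; given two consecutive pair mid-frames it
#' returns shift/slide/rise and tilt/roll/twist.
#'
#' @param frame1,frame2 Base (or pair mid-) frames from [base_frame()].
#' @param type `"pair"` (intra-bp, frame2 flipped) or `"step"`.
#' @return Named numeric vector of six parameters (Angstrom / degrees),
#'   plus attribute `"mid_frame"` carrying the pair mid-frame.
#' @export
bp_step_params <- function(frame1, frame2, type = c("pair", "step")) {
  type <- match.arg(type)
  if (type == "pair") frame2 <- flip_frame(frame2)
  fp <- frame_params(frame1, frame2)
  out <- if (type == "pair")
    c(shear = fp$translation[1], stretch = fp$translation[2],
      stagger = fp$translation[3], buckle = fp$rot[["tilt"]],
      propeller = fp$rot[["roll"]], opening = fp$rot[["twist"]])
  else
    c(shift = fp$translation[1], slide = fp$translation[2],
      rise = fp$translation[3], tilt = fp$rot[["tilt"]],
      roll = fp$rot[["roll"]], twist = fp$rot[["twist"]])
  attr(out, "mid_frame") <- fp$mid_frame
  out
}

# Backbone/glycosidic torsion atom definitions. alpha, epsilon and zeta
# span the phosphodiester linkage and need the neighboring residue.
TORSION_DEFS <- list(
  alpha = list(c("O3'", -1L), c("P", 0L), c("O5'", 0L), c("C5'", 0L)),
  beta  = list(c("P", 0L), c("O5'", 0L), c("C5'", 0L), c("C4'", 0L)),
  gamma = list(c("O5'", 0L), c("C5'", 0L), c("C4'", 0L), c("C3'", 0L)),
  delta = list(c("C5'", 0L), c("C4'", 0L), c("C3'", 0L), c("O3'", 0L)),
  epsilon = list(c("C4'", 0L), c("C3'", 0L), c("O3'", 0L), c("P", 1L)),
  zeta  = list(c("C3'", 0L), c("O3'", 0L), c("P", 1L), c("O5'", 1L))
)

#' Backbone and glycosidic torsions for one frame
#'
#' Computes alpha, beta, gamma, delta, epsilon, zeta and chi per
#' residue; a torsion is `NA` where any defining atom is absent (chain
#' termini, unlinked synthetic residues).
#'
#' @param frame n_atoms x 3 coordinate matrix.
#' @param topology Matching `"topology"`.
#' @return data.frame: residue_index, nucleotide, one column per torsion
#'   (degrees).
#' @export
backbone_torsions <- function(frame, topology) {
  at <- topology$atoms
  res <- topology$residues
  chain <- res$chain_label[match(res$residue_index, res$residue_index)]
  get_atom <- function(ri, name) {
    k <- which(at$residue_index == ri & at$atom_name == name)
    if (length(k) == 0L) return(NULL)
    frame[k[1], ]
  }
  same_chain_neighbor <- function(ri, off) {
    j <- ri + off
    k <- match(j, res$residue_index)
    i <- match(ri, res$residue_index)
    if (is.na(k) || res$chain_label[k] != res$chain_label[i]) NA else j
  }
  rows <- lapply(res$residue_index, function(ri) {
    vals <- vapply(names(TORSION_DEFS), function(tn) {
      def <- TORSION_DEFS[[tn]]
      pts <- vector("list", 4L)
      for (q in 1:4) {
        off <- as.integer(def[[q]][2])
        rj <- if (off == 0L) ri else same_chain_neighbor(ri, off)
        if (is.na(rj)) return(NA_real_)
        p <- get_atom(rj, def[[q]][1])
        if (is.null(p)) return(NA_real_)
        pts[[q]] <- p
      }
      dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
    }, numeric(1))
    nuc <- res$nucleotide[match(ri, res$residue_index)]
    chi_atoms <- if (nuc %in% c("A", "G")) c("O4'", "C1'", "N9", "C4")
                 else c("O4'", "C1'", "N1", "C2")
    pts <- lapply(chi_atoms, get_atom, ri = ri)
    chi <- if (any(vapply(pts, is.null, logical(1)))) NA_real_
           else dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
    c(vals, chi = chi)
  })
  out <- as.data.frame(do.call(rbind, rows))
  cbind(data.frame(residue_index = res$residue_index,
                   nucleotide = res$nucleotide), out)
}

residue_coords <- function(frame, topology, residue_index) {
  k <- which(topology$atoms$residue_index == residue_index)
  m <- frame[k, , drop = FALSE]
  rownames(m) <- topology$atoms$atom_name[k]
  m
}

#' Geometry profiles over an ensemble
#'
#' Per-frame backbone/glycosidic torsions and sugar puckers for every
#' residue, and intra-base-pair plus step parameters for a supplied
#' pairing assignment. Angle summaries use circular means.
#'
#' @param ensemble An `"ensemble"`.
#' @param pairing Optional data.frame with columns `res_i`, `res_j`
#'   (strand-1/ASO residue first); consecutive rows define steps.
#' @param window Time window in ns (`c(start, end)`) or `NULL`.
#' @return List of class `"geometry_profile"`: `torsions`, `puckers`,
#'   `bp_params`, `step_params` (long-format data.frames).
#' @export
geometry_profiles <- function(ensemble, pairing = NULL, window = NULL) {
  idx <- window_frames(ensemble, window)
  topo <- ensemble$topology
  if (!is.null(pairing)) {
    known <- topo$residues$residue_index
    bad <- setdiff(c(pairing$res_i, pairing$res_j), known)
    if (length(bad))
      stop("pairing references missing residue(s): ",
           paste(bad, collapse = ", "))
  }
  tors <- list(); pucks <- list(); bps <- list(); steps <- list()
  for (f in idx) {
    fr <- frame_xyz(ensemble, f)
    tt <- backbone_torsions(fr, topo)
    tt$frame <- f
    tors[[length(tors) + 1L]] <- tt
    pk <- lapply(topo$residues$residue_index, function(ri) {
      ps <- pucker(residue_coords(fr, topo, ri))
      data.frame(frame = f, residue_index = ri, phase = ps$phase,
                 amplitude = ps$amplitude, conformer = ps$conformer)
    })
    pucks[[length(pucks) + 1L]] <- do.call(rbind, pk)
    if (!is.null(pairing) && nrow(pairing) > 0L) {
      frames_of_pair <- lapply(seq_len(nrow(pairing)), function(p) {
        nuc_i <- topo$residues$nucleotide[
          match(pairing$res_i[p], topo$residues$residue_index)]
        nuc_j <- topo$residues$nucleotide[
          match(pairing$res_j[p], topo$residues$residue_index)]
        f1 <- base_frame(residue_coords(fr, topo, pairing$res_i[p]), nuc_i)
        f2 <- base_frame(residue_coords(fr, topo, pairing$res_j[p]), nuc_j)
        pars <- bp_step_params(f1, f2, type = "pair")
        list(pars = pars, mid = attr(pars, "mid_frame"))
      })
      bp_tab <- do.call(rbind, lapply(seq_along(frames_of_pair), function(p)
        data.frame(frame = f, res_i = pairing$res_i[p],
                   res_j = pairing$res_j[p],
                   t(frames_of_pair[[p]]$pars))))
      bps[[length(bps) + 1L]] <- bp_tab
      if (nrow(pairing) > 1L) {
        st <- do.call(rbind, lapply(seq_len(nrow(pairing) - 1L), function(s) {
          pars <- bp_step_params(frames_of_pair[[s]]$mid,
                                 frames_of_pair[[s + 1L]]$mid, type = "step")
          data.frame(frame = f, step = s, t(pars))
        }))
        steps[[length(steps) + 1L]] <- st
      }
    }
  }
  structure(list(
    torsions = do.call(rbind, tors),
    puckers = do.call(rbind, pucks),
    bp_params = if (length(bps)) do.call(rbind, bps) else NULL,
    step_params = if (length(steps)) do.call(rbind, steps) else NULL),
    class = "geometry_profile")
}
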