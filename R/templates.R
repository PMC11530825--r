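# Idealized planar base geometries in the standard reference frame
# (x toward the major groove, y along the C1'-C1' direction toward the
# paired strand, z normal to the base plane; origin at the pair center).
# Used both to build synthetic nucleotides and to fit base frames.

.base_xy <- function(...) {
  v <- list(...)
  m <- do.call(rbind, lapply(v, function(r) c(r[[2]], r[[3]], 0)))
  rownames(m) <- vapply(v, `[[`, character(1), 1)
  colnames(m) <- c("x", "y", "z")
  m
}

BASE_TEMPLATES <- list(
  A = .base_xy(
    list("C1'", -2.479, 5.346), list("N9", -1.291, 4.498),
    list("C8", 0.024, 4.897), list("N7", 0.877, 3.902),
    list("C5", 0.071, 2.771), list("C6", 0.369, 1.398),
    list("N6", 1.611, 0.909), list("N1", -0.668, 0.532),
    list("C2", -1.912, 1.023), list("N3", -2.320, 2.290),
    list("C4", -1.267, 3.124)),
  G = .base_xy(
    list("C1'", -2.477, 5.399), list("N9", -1.289, 4.551),
    list("C8", 0.023, 4.962), list("N7", 0.870, 3.969),
    list("C5", 0.071, 2.833), list("C6", 0.424, 1.460),
    list("O6", 1.554, 0.955), list("N1", -0.700, 0.641),
    list("C2", -1.999, 1.087), list("N2", -2.949, 0.139),
    list("N3", -2.342, 2.364), list("C4", -1.265, 3.177)),
  C = .base_xy(
    list("C1'", -2.477, 5.402), list("N1", -1.285, 4.542),
    list("C2", -1.472, 3.158), list("O2", -2.628, 2.709),
    list("N3", -0.391, 2.344), list("C4", 0.837, 2.868),
    list("N4", 1.875, 2.027), list("C5", 1.056, 4.275),
    list("C6", -0.023, 5.068)),
  U = .base_xy(
    list("C1'", -2.481, 5.354), list("N1", -1.284, 4.500),
    list("C2", -1.462, 3.131), list("O2", -2.563, 2.608),
    list("N3", -0.302, 2.397), list("C4", 0.989, 2.884),
    list("O4", 1.935, 2.094), list("C5", 1.089, 4.311),
    list("C6", -0.024, 5.053))
)

GLYCOSIDIC_N <- c(A = "N9", G = "N9", C = "N1", U = "N1")

# Pseudorotation phase targets (degrees) at the sector centers.
PUCKER_TARGETS <- c("C3'-endo" = 18, "C4'-exo" = 54,
                    "C2'-endo" = 162, "C2'-exo" = 342)

# --- furanose ring construction -------------------------------------------

RING_ORDER <- c("C1'", "C2'", "C3'", "C4'", "O4'")
RING_BONDS <- c(1.528, 1.525, 1.526, 1.454, 1.414)   # i -> i+1 (cyclic)
RING_ANGLES <- c(106.4, 101.5, 102.6, 105.5, 109.9)  # at atom i

ring_torsions_of <- function(m) {
  # nu0..nu4 for a 5 x 3 matrix in RING_ORDER
  rownames(m) <- RING_ORDER
  vapply(RING_TORSIONS, function(a)
    dihedral(m[a[1], ], m[a[2], ], m[a[3], ], m[a[4], ]), numeric(1))
}

.ring_cache <- new.env(parent = emptyenv())

# Build the five ring atoms realizing pseudorotation phase `P` (deg) at
# amplitude `numax` (deg): target torsions nu_j = numax cos(P + 144(j-2))
# are imposed by penalized least squares over the 15 coordinates,
# starting from a planar pentagon with out-of-plane displacements.
build_sugar_ring <- function(phase, numax = 38) {
  key <- sprintf("%.3f_%.3f", phase, numax)
  if (!is.null(.ring_cache[[key]])) return(.ring_cache[[key]])
  target_nu <- numax * cos((phase + 144 * ((0:4) - 2)) * pi / 180)
  pent <- sapply(0:4, function(j) {
    th <- 2 * pi * j / 5
    c(1.24 * cos(th), 1.24 * sin(th), 0)
  })
  start <- t(pent)
  start[, 3] <- 0.4 * cos((phase + 90 + 144 * ((0:4) - 2)) * pi / 180)

  obj <- function(par) {
    m <- matrix(par, 5, 3)
    nu <- ring_torsions_of(m)
    s <- sum(wrap_angle(nu - target_nu)^2)
    for (i in 1:5) {
      j <- i %% 5 + 1
      s <- s + 500 * (sqrt(sum((m[j, ] - m[i, ])^2)) - RING_BONDS[i])^2
    }
    for (i in 1:5) {
      a <- (i - 2) %% 5 + 1; b <- i; cc <- i %% 5 + 1
      u <- m[a, ] - m[b, ]; v <- m[cc, ] - m[b, ]
      ang <- acos(max(-1, min(1, sum(u * v) /
                                sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
      s <- s + 0.3 * (ang - RING_ANGLES[i])^2
    }
    s
  }
  fit <- stats::optim(as.numeric(start), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  m <- matrix(fit$par, 5, 3)
  # the mirror ring realizes P + 180; flip if we landed on it
  got <- pucker_phase_of_ring(m)
  if (abs(wrap_angle(got - phase)) > 90) {
    m[, 3] <- -m[, 3]
    fit <- stats::optim(as.numeric(m), obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    m <- matrix(fit$par, 5, 3)
  }
  rownames(m) <- RING_ORDER
  colnames(m) <- c("x", "y", "z")
  .ring_cache[[key]] <- m
  m
}

pucker_phase_of_ring <- function(m) {
  rownames(m) <- RING_ORDER
  nu <- ring_torsions_of(m)
  denom <- 2 * nu[["nu2"]] * (sin(36 * pi / 180) + sin(72 * pi / 180))
  (atan2((nu[["nu4"]] + nu[["nu1"]]) - (nu[["nu3"]] + nu[["nu0"]]),
         denom) * 180 / pi) %% 360
}

# Place a tetrahedral substituent on ring atom `a` given its two ring
# neighbors; `face` (+1/-1) selects the ring face relative to `normal`.
place_on_ring <- function(m, a, b1, b2, face, bond, normal) {
  u1 <- m[b1, ] - m[a, ]; u1 <- u1 / sqrt(sum(u1^2))
  u2 <- m[b2, ] - m[a, ]; u2 <- u2 / sqrt(sum(u2^2))
  b <- -(u1 + u2); b <- b / sqrt(sum(b^2))
  n <- cross3(u1, u2); n <- n / sqrt(sum(n^2))
  x <- cos(109.5 * pi / 180) / sum(b * u1)
  x <- max(-1, min(1, x))
  y <- sqrt(max(0, 1 - x^2))
  d1 <- x * b + y * n
  d2 <- x * b - y * n
  d <- if (sign(sum(d1 * normal)) == face) d1 else d2
  m[a, ] + bond * d
}

# NeRF placement: new atom at `bond`/`angle_deg` from A-B with torsion
# X-A-B-C = `torsion_deg`.
place_atom <- function(a, b, c_, bond, angle_deg, torsion_deg) {
  th <- angle_deg * pi / 180
  ph <- torsion_deg * pi / 180
  ab <- a - b
  bc <- b - c_
  n_hat <- cross3(bc, ab); n_hat <- n_hat / sqrt(sum(n_hat^2))
  ab_hat <- ab / sqrt(sum(ab^2))
  m_hat <- cross3(n_hat, ab_hat)
  d <- bond * (-cos(th) * ab_hat + sin(th) * (cos(ph) * m_hat -
                                                sin(ph) * n_hat))
  a + d
}

# --- nucleotide assembly ---------------------------------------------------

#' Build an idealized ribonucleotide with requested pucker and chi
#'
#' Constructs a single residue (phosphate, sugar, full base, polar base
#' hydrogens) whose furanose ring realizes the requested pseudorotation
#' conformer (phase within 2 degrees of the sector center) and whose
#' glycosidic torsion equals `chi_angle_deg`.
#'
#' @param nucleotide "A", "C", "G" or "U".
#' @param pucker_conformer One of `"C3'-endo"`, `"C2'-endo"`,
#'   `"C2'-exo"`, `"C4'-exo"`.
#' @param chi_angle_deg Glycosidic torsion chi (degrees; A-form ~ -160).
#' @param backbone Named list overriding backbone torsions `gamma`
#'   (O5'-C5'-C4'-C3') and `beta` (P-O5'-C5'-C4').
#' @return data.frame with columns atom_name, x, y, z.
#' @export
build_nucleotide <- function(nucleotide, pucker_conformer = "C3'-endo",
                             chi_angle_deg = -160,
                             backbone = list()) {
  if (!nucleotide %in% names(BASE_TEMPLATES))
    stop("unknown nucleotide '", nucleotide, "'")
  if (!pucker_conformer %in% names(PUCKER_TARGETS))
    stop("unknown pucker conformer '", pucker_conformer, "'")
  bb <- utils::modifyList(list(gamma = 54, beta = 178), backbone)
  ring <- build_sugar_ring(PUCKER_TARGETS[[pucker_conformer]])
  nrm <- cross3(ring["C2'", ] - ring["C1'", ], ring["O4'", ] - ring["C1'", ])
  nrm <- nrm / sqrt(sum(nrm^2))

  n_pos <- place_on_ring(ring, "C1'", "O4'", "C2'", +1, 1.48, nrm)
  o2p <- place_on_ring(ring, "C2'", "C1'", "C3'", -1, 1.42, nrm)
  o3p <- place_on_ring(ring, "C3'", "C2'", "C4'", -1, 1.42, nrm)
  c5p <- place_on_ring(ring, "C4'", "C3'", "O4'", +1, 1.51, nrm)
  o5p <- place_atom(c5p, ring["C4'", ], ring["C3'", ], 1.42, 111,
                    bb$gamma)
  p <- place_atom(o5p, c5p, ring["C4'", ], 1.59, 120, bb$beta)
  op1 <- place_atom(p, o5p, c5p, 1.48, 108, 47)
  op2 <- place_atom(p, o5p, c5p, 1.48, 108, 178)

  # rigidly attach the planar base: map the template glycosidic N onto
  # n_pos with the N->C1' bond direction matched, then rotate about the
  # bond to realize chi
  tpl <- BASE_TEMPLATES[[nucleotide]]
  gn <- GLYCOSIDIC_N[[nucleotide]]
  v_t <- tpl["C1'", ] - tpl[gn, ]
  v_t <- v_t / sqrt(sum(v_t^2))
  u <- ring["C1'", ] - n_pos
  u <- u / sqrt(sum(u^2))
  axis <- cross3(v_t, u)
  r0 <- if (sqrt(sum(axis^2)) < 1e-9) diag(3) else
    rotation_about_axis(axis, acos(max(-1, min(1, sum(v_t * u)))) * 180 / pi)
  base <- sweep(tpl, 2, tpl[gn, ]) %*% t(r0)
  base <- sweep(base, 2, n_pos, "+")
  chi_ref <- if (nucleotide %in% c("A", "G")) "C4" else "C2"
  chi_now <- dihedral(ring["O4'", ], ring["C1'", ], base[gn, ],
                      base[chi_ref, ])
  r1 <- rotation_about_axis(u, -(chi_angle_deg - chi_now))
  base <- sweep(sweep(base, 2, n_pos) %*% t(r1), 2, n_pos, "+")
  chi_chk <- dihedral(ring["O4'", ], ring["C1'", ], base[gn, ],
                      base[chi_ref, ])
  if (abs(wrap_angle(chi_chk - chi_angle_deg)) > 1e-6) {
    r1 <- rotation_about_axis(u, +(chi_angle_deg - chi_now))
    base <- sweep(tpl, 2, tpl[gn, ]) %*% t(r0)
    base <- sweep(base, 2, n_pos, "+")
    base <- sweep(sweep(base, 2, n_pos) %*% t(r1), 2, n_pos, "+")
  }
  base <- base[setdiff(rownames(base), "C1'"), , drop = FALSE]

  h <- base_polar_hydrogens(base, nucleotide)
  coords <- rbind(
    P = p, OP1 = op1, OP2 = op2, `O5'` = o5p, `C5'` = c5p,
    ring[c("C4'", "O4'", "C3'"), ], `O3'` = o3p,
    ring["C2'", , drop = FALSE], `O2'` = o2p,
    ring["C1'", , drop = FALSE], base, h)
  data.frame(atom_name = rownames(coords), x = coords[, 1],
             y = coords[, 2], z = coords[, 3], row.names = NULL)
}

# Donor hydrogens placed in the base plane with ideal sp2 geometry.
base_polar_hydrogens <- function(base, nucleotide) {
  nb <- list(
    A = list(N6 = list(nbrs = "C6", h = c("H61", "H62"))),
    G = list(N1 = list(nbrs = c("C2", "C6"), h = "H1"),
             N2 = list(nbrs = "C2", h = c("H21", "H22"))),
    C = list(N4 = list(nbrs = "C4", h = c("H41", "H42"))),
    U = list(N3 = list(nbrs = c("C2", "C4"), h = "H3"))
  )[[nucleotide]]
  n_pl <- cross3(base[2, ] - base[1, ], base[3, ] - base[1, ])
  n_pl <- n_pl / sqrt(sum(n_pl^2))
  out <- NULL
  for (dn in names(nb)) {
    spec <- nb[[dn]]
    npos <- base[dn, ]
    if (length(spec$nbrs) == 2L) {
      u1 <- base[spec$nbrs[1], ] - npos
      u2 <- base[spec$nbrs[2], ] - npos
      d <- -(u1 / sqrt(sum(u1^2)) + u2 / sqrt(sum(u2^2)))
      d <- d / sqrt(sum(d^2))
      hpos <- rbind(npos + 1.01 * d)
      rownames(hpos) <- spec$h
    } else {
      d0 <- npos - base[spec$nbrs, ]
      d0 <- d0 / sqrt(sum(d0^2))
      r <- rotation_about_axis(n_pl, 60)
      hpos <- rbind(npos + 1.01 * as.numeric(r %*% d0),
                    npos + 1.01 * as.numeric(t(r) %*% d0))
      rownames(hpos) <- spec$h
    }
    out <- rbind(out, hpos)
  }
  out
}
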