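#' Centered moving average of a numeric trace
#'
#' Smooths a per-frame trace with a centered window; endpoints use
#' truncated windows so the output has the same length as the input.
#' Used for descriptor traces (RMSD, radius of gyration) and interaction
#' energy time series alike.
#'
#' @param x Numeric vector (one value per frame).
#' @param window Window width in frames (positive integer).
#' @return Numeric vector of the same length as `x`.
#' @export
moving_average <- function(x, window) {
  if (!is.numeric(window) || length(window) != 1L || window < 1)
    stop("`window` must be a positive integer number of frames")
  window <- as.integer(window)
  n <- length(x)
  if (window > n)
    stop("smoothing window (", window, ") exceeds trace length (", n, ")")
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window %/% 2L
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half_lo, 1L)
  hi <- pmin(seq_len(n) + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Circular mean of angles in degrees
#'
#' Angles near the +/-180 degree wrap (e.g. trans backbone torsions)
#' average correctly through the resultant-vector construction.
#'
#' @param theta Angles in degrees; `NA`s are dropped.
#' @return Mean angle in degrees in (-180, 180], or `NA` if no finite input.
#' @export
circular_mean <- function(theta) {
  theta <- theta[is.finite(theta)]
  if (length(theta) == 0L) return(NA_real_)
  rad <- theta * pi / 180
  ang <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
  wrap_angle(ang)
}

# Wrap any angle (degrees) into (-180, 180].
wrap_angle <- function(a) {
  a <- ((a + 180) %% 360) - 180
  a[a == -180] <- 180
  a
}

#' Optimal least-squares superposition (Kabsch algorithm)
#'
#' Finds the rotation and translation minimizing the RMSD of `mobile`
#' onto `target` over the selected rows.
#'
#' @param mobile,target n x 3 coordinate matrices with matching rows.
#' @param fit_idx Row indices used to determine the fit (default: all).
#' @return List with `xyz` (all mobile rows transformed), `rotation`
#'   (3 x 3), and `rmsd` over the fit selection.
#' @export
superpose_kabsch <- function(mobile, target, fit_idx = seq_len(nrow(mobile))) {
  stopifnot(ncol(mobile) == 3L, ncol(target) == 3L,
            nrow(mobile) == nrow(target))
  mb <- mobile[fit_idx, , drop = FALSE]
  tg <- target[fit_idx, , drop = FALSE]
  cm <- colMeans(mb)
  ct <- colMeans(tg)
  a <- sweep(mb, 2, cm)
  b <- sweep(tg, 2, ct)
  s <- svd(crossprod(a, b))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  out <- sweep(mobile, 2, cm) %*% t(rot)
  out <- sweep(out, 2, ct, "+")
  dev <- out[fit_idx, , drop = FALSE] - tg
  list(xyz = out, rotation = rot, rmsd = sqrt(mean(rowSums(dev^2))))
}

# Rotation matrix about an arbitrary unit axis by `deg` degrees
# (Rodrigues form).
rotation_about_axis <- function(axis, deg) {
  axis <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  k <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
}

# Independent sub-seed for a named operation under one root seed; keeps
# generator stages reproducible and decoupled. Result stays below 2^31.
derive_seed <- function(root_seed, label) {
  bytes <- utf8ToInt(label)
  h <- as.numeric(root_seed %% 2147483647)
  for (b in bytes) h <- (h * 31 + b) %% 2147483563
  as.integer(h)
}

# Standard atomic masses (u) for heavy-atom and hydrogen bookkeeping.
ATOMIC_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974)

# Element inferred from a PDB nucleic-acid atom name.
element_of <- function(atom_name) {
  first <- substr(gsub("^[0-9']+", "", atom_name), 1L, 1L)
  if (!first %in% names(ATOMIC_MASSES))
    stop("cannot infer element for atom name '", atom_name, "'")
  first
}
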