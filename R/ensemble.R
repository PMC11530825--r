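#' Construct a structural ensemble
#'
#' An ensemble is an ordered set of coordinate frames over one topology,
#' with a strictly increasing time stamp (ns) per frame. All analyses in
#' the package operate on this container.
#'
#' @param topology A `"topology"` object.
#' @param xyz Numeric array `[frame, atom, 3]` in Angstrom, or a single
#'   `n_atoms x 3` matrix for a one-frame ensemble.
#' @param times Numeric vector of frame times in ns (default 0, 1, ...).
#' @return Object of class `"ensemble"`.
#' @export
new_ensemble <- function(topology, xyz, times = NULL) {
  stopifnot(inherits(topology, "topology"))
  if (is.matrix(xyz)) xyz <- array(xyz, dim = c(1L, nrow(xyz), 3L))
  stopifnot(length(dim(xyz)) == 3L, dim(xyz)[3] == 3L)
  if (dim(xyz)[2] != nrow(topology$atoms))
    stop("frame atom count (", dim(xyz)[2], ") does not match topology (",
         nrow(topology$atoms), ")")
  if (!all(is.finite(xyz))) stop("non-finite coordinates in ensemble")
  n <- dim(xyz)[1]
  if (is.null(times)) times <- as.numeric(seq_len(n) - 1L)
  if (length(times) != n) stop("times length must equal frame count")
  if (n > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(topology = topology, xyz = xyz, times = times),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat("<ensemble> ", dim(x$xyz)[1], " frames x ", dim(x$xyz)[2],
      " atoms, t = [", min(x$times), ", ", max(x$times), "] ns\n", sep = "")
  invisible(x)
}

n_frames <- function(ens) dim(ens$xyz)[1]

frame_xyz <- function(ens, i) {
  m <- ens$xyz[i, , , drop = FALSE]
  dim(m) <- dim(ens$xyz)[2:3]
  m
}

# Resolve a time window (ns, inclusive) to frame indices.
window_frames <- function(ens, window = NULL) {
  if (is.null(window)) return(seq_len(n_frames(ens)))
  stopifnot(length(window) == 2L)
  if (window[1] > window[2])
    stop("window start (", window[1], ") exceeds end (", window[2], ")")
  idx <- which(ens$times >= window[1] & ens$times <= window[2])
  if (length(idx) == 0L)
    stop("window [", window[1], ", ", window[2], "] ns contains no frames")
  idx
}
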