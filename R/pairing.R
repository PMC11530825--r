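# Base-pair detection and edge classification. Pairs are read off the
# base-base hydrogen-bond set; the interacting face of each base is
# classified Watson-Crick / Hoogsteen / sugar from which of its
# H-bond-capable atoms participate. A base simultaneously pairing two
# partners -- the triple-base-pair motif central to ASO-hairpin
# recognition -- is flagged with the edge used toward each partner.

# Every H-bond-capable base atom belongs to exactly one edge class.
# O6 of G sits on the WC face (it also serves Hoogsteen pairs, which
# the N7 signature still identifies); ties resolve by precedence
# Hoogsteen > WC > sugar.
EDGE_ASSIGNMENT <- list(
  A = c(N1 = "WC", N6 = "WC", N7 = "Hoogsteen", N3 = "sugar"),
  G = c(N1 = "WC", N2 = "WC", O6 = "WC", N7 = "Hoogsteen", N3 = "sugar"),
  C = c(N3 = "WC", N4 = "WC", O2 = "sugar"),
  U = c(N3 = "WC", O4 = "WC", O2 = "sugar")
)

# Structure-annotation-style criteria for base pairing: donor-acceptor
# heavy-atom distance up to 3.5 A, no hydrogen-angle requirement
# (pair detection conventions differ from strict MD H-bond counting).
#' @rdname detect_base_pairs
#' @export
pairing_criteria <- function() contact_criteria(hbond_dist = 3.5,
                                                use_hydrogen_angle = FALSE)

edge_of_atoms <- function(nucleotide, atom_names) {
  tab <- EDGE_ASSIGNMENT[[nucleotide]]
  if (is.null(tab))
    stop("no edge assignment for nucleotide '", nucleotide, "'")
  classes <- tab[atom_names]
  classes <- classes[!is.na(classes)]
  if (length(classes) == 0L) return(NA_character_)
  cnt <- table(classes)
  top <- names(cnt)[cnt == max(cnt)]
  for (e in c("Hoogsteen", "WC", "sugar")) if (e %in% top) return(e)
  top[1]
}

#' Detect base pairs and classify their edges in one frame
#'
#' Base-base hydrogen bonds are detected (delegating to
#' [detect_contacts()] restricted to base-role atoms, by default with
#' distance-only pairing criteria), aggregated per residue pair, and
#' categorized: `watson_crick` when both bases interact through their
#' WC edges with at least `min_hbonds["watson_crick"]` bonds (default
#' 2), `hoogsteen` when either base engages through its N7 face
#' (default minimum 1 bond), otherwise `other`.
#'
#' @param frame Coordinate matrix or `"ensemble"` (frame 1).
#' @param topology Matching `"topology"` (ignored for ensembles).
#' @param criteria [contact_criteria()]; default [pairing_criteria()].
#' @param min_hbonds Named minimum H-bond counts per category.
#' @param frame_index Frame label for the output.
#' @return data.frame: res_i, res_j, n_hbonds, edge_i, edge_j,
#'   category.
#' @export
detect_base_pairs <- function(frame, topology = NULL,
                              criteria = pairing_criteria(),
                              min_hbonds = c(watson_crick = 2,
                                             hoogsteen = 1),
                              frame_index = 1L) {
  if (inherits(frame, "ensemble")) {
    topology <- frame$topology
    frame <- frame_xyz(frame, frame_index)
  }
  miss <- setdiff(unique(topology$residues$nucleotide),
                  names(EDGE_ASSIGNMENT))
  if (length(miss))
    stop("no edge assignment for nucleotide(s): ",
         paste(miss, collapse = ", "))
  recs <- detect_contacts(frame, topology, criteria,
                          frame_index = frame_index)
  recs <- recs[recs$type == "hbond" & recs$specificity == "specific", ,
               drop = FALSE]
  if (nrow(recs) == 0L)
    return(data.frame(res_i = integer(0), res_j = integer(0),
                      n_hbonds = integer(0), edge_i = character(0),
                      edge_j = character(0), category = character(0)))
  res <- topology$residues
  key <- paste(recs$res_i, recs$res_j)
  out <- do.call(rbind, lapply(unique(key), function(k) {
    rr <- recs[key == k, , drop = FALSE]
    i <- rr$res_i[1]; j <- rr$res_j[1]
    nuc_i <- res$nucleotide[match(i, res$residue_index)]
    nuc_j <- res$nucleotide[match(j, res$residue_index)]
    e_i <- edge_of_atoms(nuc_i, rr$atom_i)
    e_j <- edge_of_atoms(nuc_j, rr$atom_j)
    n <- nrow(rr)
    category <-
      if ((identical(e_i, "Hoogsteen") || identical(e_j, "Hoogsteen")) &&
          n >= min_hbonds[["hoogsteen"]]) "hoogsteen"
      else if (identical(e_i, "WC") && identical(e_j, "WC") &&
               n >= min_hbonds[["watson_crick"]]) "watson_crick"
      else "other"
    data.frame(res_i = i, res_j = j, n_hbonds = n,
               edge_i = e_i, edge_j = e_j, category = category)
  }))
  rownames(out) <- NULL
  out[order(out$res_i, out$res_j), , drop = FALSE]
}

#' Identify triple base pairs from one frame's base pairs
#'
#' Any residue participating in two or more base pairs is the center of
#' a triple; the edge it uses toward each partner is recorded, together
#' with whether the two edge sets differ and whether the two partners
#' also pair with each other (closed triangle).
#'
#' @param base_pairs Output of [detect_base_pairs()] for one frame.
#' @return data.frame: central, partner_1, partner_2, edge_1, edge_2,
#'   distinct_edges, closed.
#' @export
detect_triples <- function(base_pairs) {
  empty <- data.frame(central = integer(0), partner_1 = integer(0),
                      partner_2 = integer(0), edge_1 = character(0),
                      edge_2 = character(0), distinct_edges = logical(0),
                      closed = logical(0))
  if (nrow(base_pairs) < 2L) return(empty)
  bp <- base_pairs[order(base_pairs$res_i, base_pairs$res_j), ,
                   drop = FALSE]
  members <- c(bp$res_i, bp$res_j)
  centrals <- sort(unique(members[duplicated(members)]))
  pair_key <- paste(bp$res_i, bp$res_j)
  out <- list()
  for (ct in centrals) {
    rows <- which(bp$res_i == ct | bp$res_j == ct)
    partners <- ifelse(bp$res_i[rows] == ct, bp$res_j[rows],
                       bp$res_i[rows])
    edges <- ifelse(bp$res_i[rows] == ct, bp$edge_i[rows],
                    bp$edge_j[rows])
    o <- order(partners)
    partners <- partners[o]; edges <- edges[o]
    cmb <- utils::combn(seq_along(partners), 2L)
    for (cc in seq_len(ncol(cmb))) {
      a <- cmb[1, cc]; b <- cmb[2, cc]
      closed <- paste(min(partners[a], partners[b]),
                      max(partners[a], partners[b])) %in% pair_key
      out[[length(out) + 1L]] <- data.frame(
        central = ct, partner_1 = partners[a], partner_2 = partners[b],
        edge_1 = edges[a], edge_2 = edges[b],
        distinct_edges = edges[a] != edges[b], closed = closed)
    }
  }
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res
}

#' Base-pair persistence and fraying candidates over an ensemble
#'
#' Fraction of frames each base pair is present, with a block series
#' resolving when pairing is lost. Pairs whose last-block presence
#' falls below half of their first-block presence are flagged as
#' fraying candidates (the signature of terminal base fraying).
#'
#' @param ensemble An `"ensemble"`.
#' @param criteria [contact_criteria()]; default [pairing_criteria()].
#' @param n_blocks Number of equal frame blocks (default 2).
#' @param window Time window in ns or `NULL`.
#' @return List of class `"pair_persistence"`: `pairs` (res_i, res_j,
#'   persistence, fraying_candidate), `blocks` (long data.frame),
#'   `per_frame` (data.frame of per-frame pair detections).
#' @export
pair_persistence <- function(ensemble, criteria = pairing_criteria(),
                             n_blocks = 2L, window = NULL) {
  idx <- window_frames(ensemble, window)
  if (n_blocks < 1L || n_blocks > length(idx))
    stop("n_blocks must lie in [1, number of window frames]")
  per_frame <- do.call(rbind, lapply(idx, function(f) {
    bp <- detect_base_pairs(frame_xyz(ensemble, f), ensemble$topology,
                            criteria, frame_index = f)
    if (nrow(bp)) cbind(frame = f, bp) else NULL
  }))
  if (is.null(per_frame))
    return(structure(list(pairs = data.frame(), blocks = data.frame(),
                          per_frame = data.frame()),
                     class = "pair_persistence"))
  ukey <- unique(per_frame[, c("res_i", "res_j")])
  block_of <- ceiling(match(per_frame$frame, idx) /
                        (length(idx) / n_blocks))
  frames_per_block <- tabulate(ceiling(seq_along(idx) /
                                         (length(idx) / n_blocks)),
                               n_blocks)
  blocks <- do.call(rbind, lapply(seq_len(nrow(ukey)), function(k) {
    sel <- per_frame$res_i == ukey$res_i[k] &
      per_frame$res_j == ukey$res_j[k]
    cnt <- tabulate(block_of[sel], n_blocks)
    data.frame(res_i = ukey$res_i[k], res_j = ukey$res_j[k],
               block = seq_len(n_blocks),
               presence = cnt / frames_per_block)
  }))
  pairs <- do.call(rbind, lapply(seq_len(nrow(ukey)), function(k) {
    b <- blocks[blocks$res_i == ukey$res_i[k] &
                  blocks$res_j == ukey$res_j[k], ]
    first <- b$presence[1]; last <- b$presence[n_blocks]
    n_present <- sum(per_frame$res_i == ukey$res_i[k] &
                       per_frame$res_j == ukey$res_j[k])
    data.frame(res_i = ukey$res_i[k], res_j = ukey$res_j[k],
               persistence = n_present / length(idx),
               fraying_candidate = n_blocks > 1L && last < first / 2)
  }))
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, blocks = blocks, per_frame = per_frame),
            class = "pair_persistence")
}
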