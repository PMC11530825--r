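# Independent oracles and fixture builders used across the suite.
# Oracles deliberately re-derive results with different algorithms
# (plain loops, closed forms, external implementations) from the code
# paths they check.

# Random parameterized topology + frame: `n_res` full nucleotides with
# coordinates scattered in a box (no chemistry implied).
random_complex <- function(n_res = 4, seed = 1, box = 18,
                           chains = NULL) {
  set.seed(seed)
  nucs <- sample(c("A", "C", "G", "U"), n_res, replace = TRUE)
  if (is.null(chains))
    chains <- rep(c("A", "B"), length.out = n_res)
  built <- lapply(nucs, build_nucleotide)
  residues <- data.frame(residue_index = seq_len(n_res) * 3L,
                         nucleotide = nucs, chain_label = chains)
  atoms <- do.call(rbind, lapply(seq_len(n_res), function(i)
    data.frame(atom_name = built[[i]]$atom_name,
               residue_index = residues$residue_index[i])))
  topo <- build_topology(residues, atoms)
  topo <- attach_nonbonded_params(topo, synthetic_param_table(topo))
  n_atoms <- nrow(topo$atoms)
  frame <- matrix(runif(n_atoms * 3, 0, box), n_atoms, 3)
  list(topology = topo, frame = frame)
}

# Brute-force O(n^2) contact re-implementation: plain scalar loops over
# every atom pair, rules restated from first principles.
brute_force_contacts <- function(frame, topology, criteria) {
  at <- topology$atoms
  res <- topology$residues
  chain <- res$chain_label[match(at$residue_index, res$residue_index)]
  n <- nrow(at)
  sign_of <- ifelse(at$is_charged, -1, 0)
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ri <- at$residue_index[i]; rj <- at$residue_index[j]
      if (ri == rj) next
      if (chain[i] == chain[j] && abs(ri - rj) <= 1) next
      d <- sqrt(sum((frame[i, ] - frame[j, ])^2))
      type <- NULL
      hb_ok <- function(di, ai) {
        if (!(at$is_donor[di] && at$is_heavy[di] &&
                at$is_acceptor[ai] && at$is_heavy[ai])) return(FALSE)
        if (d > criteria$hbond_dist) return(FALSE)
        if (!criteria$use_hydrogen_angle) return(TRUE)
        hn <- rnadyn:::DONOR_HYDROGENS[[at$atom_name[di]]]
        hidx <- which(at$residue_index == at$residue_index[di] &
                        at$atom_name %in% hn)
        if (length(hidx) == 0) return(TRUE)
        for (h in hidx) {
          v1 <- frame[di, ] - frame[h, ]
          v2 <- frame[ai, ] - frame[h, ]
          ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                    sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
          if (ang >= criteria$hbond_angle) return(TRUE)
        }
        FALSE
      }
      if (hb_ok(i, j) || hb_ok(j, i)) {
        type <- "hbond"
      } else if (sign_of[i] * sign_of[j] < 0 && at$is_heavy[i] &&
                   at$is_heavy[j] && d <= criteria$salt_dist) {
        type <- "salt_bridge"
      } else if (at$is_apolar[i] && at$is_apolar[j] && at$is_heavy[i] &&
                   at$is_heavy[j] && d <= criteria$apolar_dist) {
        type <- "apolar"
      }
      if (!is.null(type)) {
        a <- if (ri < rj) i else j
        b <- if (ri < rj) j else i
        out[[length(out) + 1]] <- data.frame(
          res_i = at$residue_index[a], res_j = at$residue_index[b],
          atom_i = at$atom_name[a], atom_j = at$atom_name[b],
          type = type,
          specificity = if (at$role[a] == "base" && at$role[b] == "base")
            "specific" else "nonspecific")
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(res_i = integer(0), res_j = integer(0),
                      atom_i = character(0), atom_j = character(0),
                      type = character(0), specificity = character(0)))
  do.call(rbind, out)
}

contact_key <- function(df) {
  sort(paste(df$res_i, df$res_j, df$atom_i, df$atom_j, df$type,
             df$specificity))
}

# Rotation-matrix dihedral oracle: rotate p4 into the p1 frame built
# explicitly from the central bond, then read the angle in that plane.
dihedral_oracle <- function(p1, p2, p3, p4) {
  ez <- (p3 - p2); ez <- ez / sqrt(sum(ez^2))
  v1 <- (p1 - p2); v1 <- v1 - sum(v1 * ez) * ez
  v4 <- (p4 - p3); v4 <- v4 - sum(v4 * ez) * ez
  ex <- v1 / sqrt(sum(v1^2))
  ey <- c(ez[2] * ex[3] - ez[3] * ex[2],
          ez[3] * ex[1] - ez[1] * ex[3],
          ez[1] * ex[2] - ez[2] * ex[1])
  -atan2(sum(v4 * ey), sum(v4 * ex)) * 180 / pi
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  cbind(
    c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] + q[1] * q[4]),
      2 * (q[2] * q[4] - q[1] * q[3])),
    c(2 * (q[2] * q[3] - q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
      2 * (q[3] * q[4] + q[1] * q[2])),
    c(2 * (q[2] * q[4] + q[1] * q[3]), 2 * (q[3] * q[4] - q[1] * q[2]),
      1 - 2 * (q[2]^2 + q[3]^2)))
}

# One-frame two-residue A-U Watson-Crick scene reused in several files.
wc_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      res <- data.frame(residue_index = c(1L, 5L),
                        nucleotide = c("A", "U"),
                        chain_label = c("B", "A"))
      plan <- data.frame(res_i = 1, res_j = 5,
                         edge_i = "WC", edge_j = "WC")
      cache <<- build_paired_arrangement(res, plan)
    }
    cache
  }
})

# U.A-U triple scene: central adenine pairs one uridine on the WC edge
# and a second on the Hoogsteen edge.
triple_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      res <- data.frame(residue_index = c(21L, 5L, 31L),
                        nucleotide = c("A", "U", "U"),
                        chain_label = c("A", "B", "A"))
      plan <- data.frame(res_i = c(21, 21), res_j = c(5, 31),
                         edge_i = c("WC", "Hoogsteen"),
                         edge_j = c("WC", "WC"))
      cache <<- build_paired_arrangement(res, plan)
    }
    cache
  }
})
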