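test_that("criteria constructor validates ranges", {
  expect_error(contact_criteria(hbond_dist = -1), "positive")
  expect_error(contact_criteria(hbond_angle = 200), "angle")
})

test_that("detection matches an O(n^2) brute-force reimplementation", {
  crit <- contact_criteria()
  for (seed in 1:10) {
    cx <- random_complex(n_res = sample(2:6, 1), seed = seed,
                         box = 14)
    got <- detect_contacts(cx$frame, cx$topology, crit)
    want <- brute_force_contacts(cx$frame, cx$topology, crit)
    expect_identical(contact_key(got), contact_key(want))
  }
})

test_that("textbook geometries classify as expected", {
  ens <- wc_scene()
  recs <- detect_contacts(ens)
  hb <- recs[recs$type == "hbond" & recs$specificity == "specific", ]
  expect_true(all(c("N3", "O4") %in% hb$atom_j))
  # far-apart residues give no contacts
  far <- ens
  idx <- far$topology$atoms$residue_index == 5
  far$xyz[1, idx, 1] <- far$xyz[1, idx, 1] + 100
  expect_equal(nrow(detect_contacts(far)), 0L)
})

test_that("atom pairs are reported once with type precedence", {
  recs <- detect_contacts(wc_scene())
  key <- paste(recs$res_i, recs$res_j, recs$atom_i, recs$atom_j)
  expect_false(anyDuplicated(key) > 0)
})

test_that("contact strength counts every record as one", {
  ens <- wc_scene()
  recs <- detect_contacts(ens)
  expect_equal(contact_strength(recs, c(1, 5)), nrow(recs))
  expect_equal(contact_strength(recs[0, ], c(1, 5)), 0L)
  # multiset tally oracle on synthetic records
  set.seed(42)
  fake <- data.frame(res_i = sample(1:4, 25, TRUE))
  fake$res_j <- fake$res_i + sample(1:3, 25, TRUE)
  for (p in unique(paste(fake$res_i, fake$res_j))) {
    ij <- as.integer(strsplit(p, " ")[[1]])
    expect_equal(contact_strength(fake, ij),
                 sum(fake$res_i == ij[1] & fake$res_j == ij[2]))
  }
})

test_that("series occupancy matches scheduled ground truth", {
  ref <- wc_scene()
  ens <- perturb(ref, 0, n_frames = 500, seed = 2)
  ens <- schedule_contacts(ens, data.frame(res_i = 1, res_j = 5,
                                           occupancy = 0.40), seed = 2)
  ser <- build_series(ens)
  row <- ser$pairs[ser$pairs$res_i == 1 & ser$pairs$res_j == 5, ]
  expect_lt(abs(row$occupancy - 0.40), 1 / 500 + 1e-12)
})

test_that("static repeated frame gives occupancy and strength 1 for a bonded pair", {
  res <- data.frame(residue_index = c(1L, 5L), nucleotide = c("A", "U"),
                    chain_label = c("B", "A"))
  ens <- perturb(wc_scene(), 0, n_frames = 10, seed = 1)
  crit <- contact_criteria(hbond_dist = 2.95, apolar_dist = 0.1,
                           salt_dist = 0.1, hbond_angle = 10)
  ser <- build_series(ens, crit)
  expect_equal(ser$pairs$occupancy, 1)
  expect_true(all(ser$pairs$mean_strength >= 1))
  expect_error(build_series(ens, crit, window = c(100, 200)),
               "no frames")
})

test_that("occupancy filter is strict and order preserving", {
  ser <- build_series(perturb(wc_scene(), 0, 4, seed = 1))
  fake <- ser
  fake$pairs <- data.frame(res_i = 1:4, res_j = 11:14,
                           occupancy = c(0.05, 0.10, 0.101, 0.95),
                           mean_strength = 1, mean_specific = 1,
                           mean_nonspecific = 0)
  fake$presence <- matrix(TRUE, 4, 4)
  fake$strength <- matrix(1L, 4, 4)
  fake$specific <- matrix(1L, 4, 4)
  kept <- occupancy_filter(fake, 0.10)
  expect_equal(kept$pairs$occupancy, c(0.101, 0.95))
  expect_error(occupancy_filter(fake, 0), "strictly inside")
  # random series agree with a direct subset
  set.seed(1)
  occ <- runif(100)
  fake$pairs <- data.frame(res_i = 1:100, res_j = 101:200,
                           occupancy = occ, mean_strength = 1,
                           mean_specific = 1, mean_nonspecific = 0)
  fake$presence <- matrix(TRUE, 100, 4)
  fake$strength <- matrix(1L, 100, 4)
  fake$specific <- matrix(1L, 100, 4)
  expect_equal(occupancy_filter(fake, 0.3)$pairs$occupancy,
               occ[occ > 0.3])
})

test_that("occupancy is invariant under frame reordering", {
  ens <- perturb(wc_scene(), 0.05, n_frames = 30, seed = 8)
  ens <- schedule_contacts(ens, data.frame(res_i = 1, res_j = 5,
                                           occupancy = 0.5), seed = 8)
  ser1 <- build_series(ens)
  perm <- sample(30)
  shuf <- ens
  shuf$xyz <- ens$xyz[perm, , , drop = FALSE]
  ser2 <- build_series(shuf)
  p1 <- ser1$pairs[order(ser1$pairs$res_i, ser1$pairs$res_j), ]
  p2 <- ser2$pairs[order(ser2$pairs$res_i, ser2$pairs$res_j), ]
  expect_equal(p1$occupancy, p2$occupancy)
  expect_equal(p1$mean_strength, p2$mean_strength)
})

test_that("specificity splits add up in contact maps", {
  ens <- perturb(triple_scene(), 0.05, n_frames = 20, seed = 4)
  ser <- build_series(ens)
  spec <- contact_map(ser, "specific")
  nonspec <- contact_map(ser, "nonspecific")
  all_m <- contact_map(ser, "all")
  expect_equal(spec + nonspec, all_m)
  expect_true(all(spec == t(spec)))
  # a specific entry exists (base-base pairing) and classification is
  # consistent with the role partition
  recs <- detect_contacts(ens, frame_index = 1)
  at <- ens$topology$atoms
  for (k in seq_len(nrow(recs))) {
    ri <- which(at$residue_index == recs$res_i[k] &
                  at$atom_name == recs$atom_i[k])
    rj <- which(at$residue_index == recs$res_j[k] &
                  at$atom_name == recs$atom_j[k])
    want <- if (at$role[ri] == "base" && at$role[rj] == "base")
      "specific" else "nonspecific"
    expect_equal(recs$specificity[k], want)
  }
})

test_that("contact evolution resolves scheduled occupancy changes", {
  ens <- perturb(wc_scene(), 0, n_frames = 40, seed = 6)
  # present only in second half: displace residue 5 in frames 1..20
  idx <- which(ens$topology$atoms$residue_index == 5)
  for (f in 1:20) ens$xyz[f, idx, 3] <- ens$xyz[f, idx, 3] + 80
  ser <- build_series(ens)
  ev <- contact_evolution(ser, 2)
  pair_ev <- ev[ev$res_i == 1 & ev$res_j == 5, ]
  expect_equal(pair_ev$occupancy, c(0, 1))
  const <- build_series(perturb(wc_scene(), 0, 12, seed = 1))
  ev2 <- contact_evolution(const, 4)
  expect_true(all(ev2$occupancy == 1))
  expect_error(contact_evolution(const, 13), "exceeds")
})
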