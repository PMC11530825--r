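test_that("RMSD is zero for identical and rigidly moved frames", {
  ens <- perturb(wc_scene(), 0, n_frames = 3, seed = 1)
  tr <- rmsd_trace(ens)
  expect_equal(tr$rmsd, rep(0, 3), tolerance = 1e-10)
  rot <- random_rotation(4)
  moved <- ens
  for (f in 1:3)
    moved$xyz[f, , ] <- sweep(moved$xyz[f, , ] %*% t(rot), 2,
                              c(10, -5, 2), "+")
  tr2 <- rmsd_trace(moved, reference = frame_xyz(ens, 1))
  expect_equal(tr2$rmsd, rep(0, 3), tolerance = 1e-8)
})

test_that("superposed RMSD agrees with the bio3d fit oracle", {
  for (seed in c(3, 13, 23)) {
    set.seed(seed)
    a <- matrix(rnorm(30, sd = 3), 10, 3)
    b <- matrix(rnorm(30, sd = 3), 10, 3)
    ours <- superpose_kabsch(a, b)$rmsd
    oracle <- bio3d::rmsd(as.numeric(t(b)), as.numeric(t(a)),
                          fit = TRUE)  # bio3d reports 3 decimals
    expect_lt(abs(ours - oracle), 5.1e-4)
  }
})

test_that("RMSF recovers generator sigma and leaves static residues at zero", {
  ref <- triple_scene()
  sig <- c(0.5, 0, 0)  # residue 21 mobile, 5 and 31 static
  ens <- perturb(ref, sig, n_frames = 5000, seed = 2)
  rf <- rmsf_per_residue(ens, fit = FALSE)
  mobile <- rf$rmsf[rf$residue_index == 21]
  expect_lt(abs(mobile - 0.5 * sqrt(3)) / (0.5 * sqrt(3)), 0.03)
  expect_lt(max(rf$rmsf[rf$residue_index != 21]), 1e-10)
})

test_that("window choice changes RMSF when motion is confined in time", {
  ref <- wc_scene()
  ens <- perturb(ref, 0, n_frames = 100, seed = 3)
  idx <- which(ens$topology$atoms$residue_index == 5)
  set.seed(9)
  for (f in 51:100)
    ens$xyz[f, idx, ] <- ens$xyz[f, idx, ] +
      matrix(rnorm(length(idx) * 3, sd = 0.8), length(idx), 3)
  full <- rmsf_per_residue(ens, fit = FALSE)
  early <- rmsf_per_residue(ens, window = c(0, 49), fit = FALSE)
  expect_lt(early$rmsf[early$residue_index == 5],
            full$rmsf[full$residue_index == 5] / 5)
  expect_error(rmsf_per_residue(ens, window = c(500, 600)), "no frames")
})

test_that("radius of gyration matches closed forms and a direct sum", {
  res <- data.frame(residue_index = 1, nucleotide = "A")
  atoms <- data.frame(atom_name = c("C2", "C8"), residue_index = 1)
  topo <- build_topology(res, atoms)
  one <- matrix(c(1, 2, 3), 1, 3)
  topo1 <- build_topology(res, atoms[1, , drop = FALSE])
  expect_equal(radius_of_gyration(one, topo1), 0)
  # two equal masses distance d apart -> d / 2
  fr <- rbind(c(0, 0, 0), c(4, 0, 0))
  expect_equal(radius_of_gyration(fr, topo), 2)
  # random frame vs direct sum with masses
  cx <- random_complex(n_res = 1, seed = 8)
  hv <- which(cx$topology$atoms$is_heavy)
  m <- rnadyn:::ATOMIC_MASSES[cx$topology$atoms$element[hv]]
  r <- cx$frame[hv, ]
  com <- colSums(r * m) / sum(m)
  direct <- sqrt(sum(m * rowSums(sweep(r, 2, com)^2)) / sum(m))
  expect_equal(radius_of_gyration(cx$frame, cx$topology), direct)
})

test_that("PCA identifies one-dimensional motion exactly", {
  ref <- wc_scene()
  ens <- perturb(ref, 0, n_frames = 50, seed = 5)
  # single atom oscillating along x
  amp <- seq(-1, 1, length.out = 50)
  for (f in 1:50) ens$xyz[f, 3, 1] <- ens$xyz[f, 3, 1] + amp[f]
  pc <- pca_ensemble(ens, fit = FALSE)
  expect_equal(pc$variance_fractions[1], 1, tolerance = 1e-12)
  expect_lte(sum(pc$eigenvalues > 1e-12), 50 - 1)  # rank bound
  expect_error(pca_ensemble(perturb(ref, 0, 1, seed = 1)), "2 frames")
})

test_that("PCA eigenvalue sum equals total positional variance", {
  ens <- perturb(wc_scene(), 0.3, n_frames = 200, seed = 6)
  pc <- pca_ensemble(ens, fit = FALSE)
  idx <- pc$selection_idx
  x <- t(vapply(1:200, function(f)
    as.numeric(t(ens$xyz[f, idx, ])), numeric(3 * length(idx))))
  total_var <- sum(apply(x, 2, var))
  expect_equal(sum(pc$eigenvalues), total_var, tolerance = 1e-8)
  expect_equal(sum(pc$variance_fractions), 1, tolerance = 1e-8)
  expect_true(all(diff(pc$eigenvalues) <= 1e-12))
})

test_that("isotropic noise has no dominant PCA mode", {
  ens <- perturb(wc_scene(), 0.5, n_frames = 3000, seed = 7)
  pc <- pca_ensemble(ens, fit = FALSE)
  top <- pc$variance_fractions[1:10]
  expect_lt(max(top) / min(top), 3)
})

test_that("descriptors are invariant under global rigid motion", {
  ens <- perturb(wc_scene(), 0.2, n_frames = 10, seed = 10)
  rot <- random_rotation(11)
  moved <- ens
  for (f in 1:10)
    moved$xyz[f, , ] <- sweep(ens$xyz[f, , ] %*% t(rot), 2,
                              c(3, 4, -6), "+")
  expect_equal(rmsd_trace(moved)$rmsd, rmsd_trace(ens)$rmsd,
               tolerance = 1e-8)
  expect_equal(radius_of_gyration(moved)$rg,
               radius_of_gyration(ens)$rg, tolerance = 1e-9)
  expect_equal(rmsf_per_residue(moved)$rmsf, rmsf_per_residue(ens)$rmsf,
               tolerance = 1e-8)
})

test_that("PCA mode ensembles interpolate along a mode", {
  ens <- perturb(wc_scene(), 0.3, n_frames = 30, seed = 12)
  pc <- pca_ensemble(ens, fit = FALSE)
  sweep_ens <- pca_mode_ensemble(pc, ens$topology, mode = 1,
                                 amplitude = 2, n_steps = 5)
  expect_equal(dim(sweep_ens$xyz)[1], 5L)
  mid <- frame_xyz(sweep_ens, 3)
  expect_equal(mid, pc$mean, tolerance = 1e-10, ignore_attr = TRUE)
})
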