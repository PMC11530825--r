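test_that("pair energy matches Coulomb and Lennard-Jones closed forms", {
  # opposite unit charges at 3 A, no LJ
  e <- pair_energy(1, -1, 1, 1, 0, 0, r = 3.0)
  expect_equal(e, -332.0636 / 3, tolerance = 1e-12)
  expect_equal(round(e, 3), -110.688)
  # LJ zero at sigma, minimum -eps at 2^(1/6) sigma
  expect_equal(pair_energy(0, 0, 3.4, 3.4, 0.2, 0.2, r = 3.4), 0)
  expect_equal(pair_energy(0, 0, 3.4, 3.4, 0.2, 0.2,
                           r = 2^(1 / 6) * 3.4), -0.2,
               tolerance = 1e-12)
  # Lorentz-Berthelot combination
  expect_equal(pair_energy(0, 0, 3.0, 4.0, 0.1, 0.4, r = 3.5), 0,
               tolerance = 1e-12)
  expect_equal(pair_energy(0, 0, 3.0, 4.0, 0.1, 0.4,
                           r = 2^(1 / 6) * 3.5), -0.2,
               tolerance = 1e-12)
  expect_equal(pair_energy(1, 1, 3, 3, 0.1, 0.1, r = 11), 0)
  expect_error(pair_energy(1, 1, 3, 3, 0.1, 0.1, r = 0), "positive")
})

test_that("group energy equals a hand-summed 3x3 toy system", {
  res <- data.frame(residue_index = 1:2, nucleotide = c("A", "U"),
                    chain_label = c("A", "B"))
  atoms <- data.frame(atom_name = rep(c("N1", "C2", "O2'"), 2),
                      residue_index = rep(1:2, each = 3))
  topo <- build_topology(res, atoms)
  params <- synthetic_param_table(topo)
  topo <- attach_nonbonded_params(topo, params)
  set.seed(31)
  fr <- matrix(rnorm(18, sd = 2), 6, 3)
  ga <- 1:3; gb <- 4:6
  got <- group_energy(fr, topo, ga, gb)
  manual <- 0
  for (i in ga) for (j in gb) {
    r <- sqrt(sum((fr[i, ] - fr[j, ])^2))
    if (r <= 10) {
      at <- topo$atoms
      sig <- (at$lj_sigma[i] + at$lj_sigma[j]) / 2
      eps <- sqrt(at$lj_epsilon[i] * at$lj_epsilon[j])
      manual <- manual + 332.0636 * at$charge[i] * at$charge[j] / r +
        4 * eps * ((sig / r)^12 - (sig / r)^6)
    }
  }
  expect_equal(got, manual, tolerance = 1e-12)
  expect_equal(group_energy(fr, topo, gb, ga), got)  # symmetry
  expect_error(group_energy(fr, topo, 1:3, 3:6), "overlap")
  # separated groups beyond cutoff
  fr2 <- fr
  fr2[gb, 1] <- fr2[gb, 1] + 50
  expect_equal(group_energy(fr2, topo, ga, gb), 0)
})

test_that("four-group components sum to the undecomposed total", {
  for (seed in c(2, 7)) {
    cx <- random_complex(n_res = 4, seed = seed, box = 16,
                         chains = c("A", "A", "B", "B"))
    ens <- new_ensemble(cx$topology, cx$frame)
    ens <- perturb(ens, 0.2, n_frames = 3, seed = seed)
    ens$topology <- cx$topology
    aso <- cx$topology$residues$residue_index[1:2]
    hp <- cx$topology$residues$residue_index[3:4]
    dec <- four_group_decomposition(ens, aso, hp)
    whole <- mean(vapply(1:3, function(f)
      group_energy(ens$xyz[f, , ], cx$topology,
                   which(cx$topology$atoms$residue_index %in% aso),
                   which(cx$topology$atoms$residue_index %in% hp)),
      numeric(1)))
    expect_equal(dec$total, sum(dec$components))
    expect_equal(dec$total, whole, tolerance = 1e-8)
  }
  # zero parameters give zero components
  cx <- random_complex(n_res = 2, seed = 3)
  cx$topology$atoms$charge <- 0
  cx$topology$atoms$lj_epsilon <- 0
  ens <- new_ensemble(cx$topology, cx$frame)
  dec <- four_group_decomposition(ens,
                                  cx$topology$residues$residue_index[1],
                                  cx$topology$residues$residue_index[2])
  expect_equal(unname(dec$components), rep(0, 4))
})

test_that("residue-pair energy matrix is additive with the decomposition", {
  cx <- random_complex(n_res = 4, seed = 5, box = 15,
                       chains = c("A", "A", "B", "B"))
  ens <- new_ensemble(cx$topology, cx$frame)
  aso <- cx$topology$residues$residue_index[1:2]
  hp <- cx$topology$residues$residue_index[3:4]
  m <- per_residue_pair_matrix(ens)
  dec <- four_group_decomposition(ens, aso, hp)
  block <- m[as.character(aso), as.character(hp)]
  expect_equal(sum(block), dec$total, tolerance = 1e-8)
  # two-residue system: single entry equals the group energy
  cx2 <- random_complex(n_res = 2, seed = 6, chains = c("A", "B"))
  ens2 <- new_ensemble(cx2$topology, cx2$frame)
  m2 <- per_residue_pair_matrix(ens2)
  ga <- which(cx2$topology$atoms$residue_index ==
                cx2$topology$residues$residue_index[1])
  gb <- which(cx2$topology$atoms$residue_index ==
                cx2$topology$residues$residue_index[2])
  expect_equal(m2[1, 2], group_energy(cx2$frame, cx2$topology, ga, gb))
})

test_that("energies are invariant under rigid motion of the frame", {
  cx <- random_complex(n_res = 2, seed = 9, chains = c("A", "B"))
  ga <- which(cx$topology$atoms$residue_index ==
                cx$topology$residues$residue_index[1])
  gb <- setdiff(seq_len(nrow(cx$topology$atoms)), ga)
  e0 <- group_energy(cx$frame, cx$topology, ga, gb)
  rot <- random_rotation(17)
  moved <- sweep(cx$frame %*% t(rot), 2, c(5, -3, 11), "+")
  expect_equal(group_energy(moved, cx$topology, ga, gb), e0,
               tolerance = 1e-9)
})

test_that("free-energy bookkeeping follows dG = dH - TdS", {
  expect_equal(combine_free_energy(-112.4, -58.3)$gibbs, -54.1)
  expect_equal(combine_free_energy(-108.0, -56.4)$gibbs, -51.6)
  expect_equal(combine_free_energy(0, 0)$gibbs, 0)
})

test_that("energy time series smoothing behaves like a moving average", {
  expect_equal(moving_average(rep(2.5, 10), 3), rep(2.5, 10))
  alt <- rep(c(1, -1), 10)
  expect_equal(moving_average(alt, 2)[1:19], rep(0, 19))
  set.seed(20)
  noise <- rnorm(20000)
  sm <- moving_average(noise, 10)
  core <- sm[10:19990]
  expect_lt(abs(var(core) - 1 / 10) / (1 / 10), 0.1)
  expect_error(moving_average(1:5, 6), "exceeds")
  expect_error(moving_average(1:5, 0), "positive")
})

test_that("per-frame component traces smooth and total correctly", {
  cx <- random_complex(n_res = 2, seed = 12, chains = c("A", "B"))
  ens <- perturb(new_ensemble(cx$topology, cx$frame), 0.1, 8, seed = 12)
  ts <- energy_timeseries(ens, cx$topology$residues$residue_index[1],
                          cx$topology$residues$residue_index[2],
                          smoothing_window = 3)
  expect_setequal(unique(ts$component),
                  c("base_base", "bac_bac", "base_bac", "bac_base",
                    "total"))
  tot <- ts[ts$component == "total", "energy"]
  comp_sum <- rowSums(vapply(
    c("base_base", "bac_bac", "base_bac", "bac_base"),
    function(cc) ts[ts$component == cc, "energy"], numeric(8)))
  expect_equal(tot, comp_sum, tolerance = 1e-10)
})
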