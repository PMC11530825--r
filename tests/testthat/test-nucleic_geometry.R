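test_that("dihedral matches planar references and a rotation oracle", {
  p <- list(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, 1, 0))
  expect_equal(dihedral(p[[1]], p[[2]], p[[3]], p[[4]]), 0)
  p_trans <- c(2, -1, 0)
  expect_equal(abs(dihedral(p[[1]], p[[2]], p[[3]], p_trans)), 180)
  for (seed in 1:8) {
    set.seed(seed)
    q <- lapply(1:4, function(i) rnorm(3, sd = 2))
    got <- dihedral(q[[1]], q[[2]], q[[3]], q[[4]])
    want <- dihedral_oracle(q[[1]], q[[2]], q[[3]], q[[4]])
    expect_equal(wrap_angle(got - want), 0, tolerance = 1e-8)
  }
  expect_error(dihedral(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               "degenerate")
})

test_that("pucker phase and conformer recover generator templates", {
  for (cs in list(c("A", "C3'-endo", 18), c("U", "C2'-endo", 162))) {
    nt <- build_nucleotide(cs[1], cs[2])
    ps <- pucker(nt)
    expect_lt(abs(wrap_angle(ps$phase - as.numeric(cs[3]))), 2)
    expect_equal(ps$conformer, cs[2])
    expect_gt(ps$amplitude, 30)
  }
})

test_that("planar ring flags amplitude zero; missing atoms error", {
  flat <- data.frame(
    atom_name = c("C1'", "C2'", "C3'", "C4'", "O4'"),
    x = cos(2 * pi * (0:4) / 5), y = sin(2 * pi * (0:4) / 5), z = 0)
  ps <- pucker(flat)
  expect_equal(ps$amplitude, 0)
  expect_equal(ps$conformer, "planar")
  expect_error(pucker(flat[-2, ]), "missing sugar ring")
})

test_that("pucker and torsions are invariant under rigid motion", {
  nt <- build_nucleotide("G", "C3'-endo", -160)
  m <- as.matrix(nt[, c("x", "y", "z")])
  rownames(m) <- nt$atom_name
  rot <- random_rotation(21)
  moved <- sweep(m %*% t(rot), 2, c(7, -2, 4), "+")
  expect_equal(pucker(moved)$phase, pucker(m)$phase, tolerance = 1e-8)
  ring <- c("O4'", "C1'", "C2'", "C3'")
  expect_equal(
    dihedral(moved[ring[1], ], moved[ring[2], ], moved[ring[3], ],
             moved[ring[4], ]),
    dihedral(m[ring[1], ], m[ring[2], ], m[ring[3], ], m[ring[4], ]),
    tolerance = 1e-8)
})

test_that("circular mean handles the +/-180 wrap", {
  expect_equal(circular_mean(c(179, -179)), 180)
  expect_equal(circular_mean(c(10, 20, 30)), 20, tolerance = 1e-9)
  expect_true(is.na(circular_mean(numeric(0))))
})

test_that("base frames recover identity and applied rotations", {
  for (nuc in c("A", "C", "G", "U")) {
    tpl <- rnadyn:::BASE_TEMPLATES[[nuc]]
    f <- base_frame(tpl, nuc)
    expect_equal(f$axes, diag(3), tolerance = 1e-8)
    expect_equal(f$origin, c(0, 0, 0), tolerance = 1e-8)
    rot <- random_rotation(30 + match(nuc, c("A", "C", "G", "U")))
    shift <- c(2, -1, 3)
    moved <- sweep(tpl %*% t(rot), 2, shift, "+")
    f2 <- base_frame(moved, nuc)
    expect_equal(f2$axes, rot, tolerance = 1e-6)
    expect_equal(f2$origin, shift, tolerance = 1e-6)
  }
  expect_error(base_frame(rnadyn:::BASE_TEMPLATES$A[-2, ], "A"),
               "missing base ring")
})

test_that("step parameters read pure translations and rotations exactly", {
  f1 <- list(origin = c(0, 0, 0), axes = diag(3))
  same <- bp_step_params(f1, f1, type = "step")
  expect_equal(unname(same[1:6]), rep(0, 6), tolerance = 1e-10)
  f_rise <- list(origin = c(0, 0, 3.4), axes = diag(3))
  p <- bp_step_params(f1, f_rise, type = "step")
  expect_equal(p[["rise"]], 3.4, tolerance = 1e-12)
  expect_equal(unname(p[c("shift", "slide", "tilt", "roll", "twist")]),
               rep(0, 5), tolerance = 1e-10)
  f_tw <- list(origin = c(0, 0, 0),
               axes = rnadyn:::rotation_about_axis(c(0, 0, 1), 36))
  p2 <- bp_step_params(f1, f_tw, type = "step")
  expect_equal(p2[["twist"]], 36, tolerance = 1e-10)
  expect_equal(unname(p2[c("shift", "slide", "rise", "tilt", "roll")]),
               rep(0, 5), tolerance = 1e-10)
})

test_that("pair parameters obey strand-swap symmetry rules", {
  for (seed in c(2, 9)) {
    set.seed(seed)
    r1 <- random_rotation(seed)
    r2 <- random_rotation(seed + 50)
    f1 <- list(origin = rnorm(3), axes = r1)
    f2 <- list(origin = rnorm(3), axes = r2)
    p12 <- bp_step_params(f1, f2, type = "pair")
    p21 <- bp_step_params(f2, f1, type = "pair")
    expect_equal(p21[["shear"]], -p12[["shear"]], tolerance = 1e-8)
    expect_equal(p21[["buckle"]], -p12[["buckle"]], tolerance = 1e-8)
    expect_equal(p21[["stretch"]], p12[["stretch"]], tolerance = 1e-8)
    expect_equal(p21[["stagger"]], p12[["stagger"]], tolerance = 1e-8)
    expect_equal(p21[["propeller"]], p12[["propeller"]],
                 tolerance = 1e-8)
    expect_equal(p21[["opening"]], p12[["opening"]], tolerance = 1e-8)
  }
})

test_that("backbone torsions report requested values and NA at termini", {
  ens <- wc_scene()
  tt <- backbone_torsions(frame_xyz(ens, 1), ens$topology)
  # built nucleotides carry gamma = 54 and beta = 178 by construction
  expect_equal(tt$gamma, rep(54, 2), tolerance = 1e-4)
  expect_equal(tt$beta, rep(178, 2), tolerance = 1e-4)
  expect_equal(tt$chi, rep(-160, 2), tolerance = 1e-4)
  # unlinked residues have no phosphodiester neighbors
  expect_true(all(is.na(tt$alpha)))
  expect_true(all(is.na(tt$epsilon)))
})

test_that("geometry profiles are order invariant and validate pairing", {
  ens <- perturb(wc_scene(), 0.05, n_frames = 6, seed = 3)
  pairing <- data.frame(res_i = 1, res_j = 5)
  gp <- geometry_profiles(ens, pairing)
  shuf <- ens
  perm <- c(4, 2, 6, 1, 5, 3)
  shuf$xyz <- ens$xyz[perm, , , drop = FALSE]
  gp2 <- geometry_profiles(shuf, pairing)
  expect_equal(sort(gp$puckers$phase), sort(gp2$puckers$phase))
  expect_equal(sort(gp$bp_params$propeller),
               sort(gp2$bp_params$propeller))
  expect_error(geometry_profiles(ens, data.frame(res_i = 1, res_j = 99)),
               "missing residue")
  one <- geometry_profiles(ens, pairing, window = c(0, 0))
  expect_equal(nrow(one$puckers), 2L)  # point-mass distributions
})

test_that("constructed duplex steps show the constructed twist", {
  # two stacked WC pairs built by rotating/translating the first
  ens <- wc_scene()
  topo <- ens$topology
  fr1 <- frame_xyz(ens, 1)
  rot <- rnadyn:::rotation_about_axis(c(0, 0, 1), 32)
  at <- topo$atoms
  r_a <- which(at$residue_index == 1)
  mk_frame <- function(fr, ri) {
    m <- fr[which(at$residue_index == ri), ]
    rownames(m) <- at$atom_name[at$residue_index == ri]
    base_frame(m, topo$residues$nucleotide[
      match(ri, topo$residues$residue_index)])
  }
  f_a1 <- mk_frame(fr1, 1)
  f_u1 <- mk_frame(fr1, 5)
  mid1 <- attr(bp_step_params(f_a1, f_u1, type = "pair"), "mid_frame")
  # second pair: same geometry rotated 32 deg about mid-frame z + 3.3 A rise
  shift_fr <- function(f) {
    ax <- mid1$axes
    local <- t(ax) %*% (f$origin - mid1$origin)
    new_origin <- mid1$origin + ax %*% (rot %*% local + c(0, 0, 3.3))
    list(origin = as.numeric(new_origin), axes = ax %*% rot %*%
           (t(ax) %*% f$axes))
  }
  f_a2 <- shift_fr(f_a1)
  f_u2 <- shift_fr(f_u1)
  mid2 <- attr(bp_step_params(f_a2, f_u2, type = "pair"), "mid_frame")
  st <- bp_step_params(mid1, mid2, type = "step")
  expect_equal(st[["twist"]], 32, tolerance = 1e-6)
  expect_equal(st[["rise"]], 3.3, tolerance = 1e-6)
})
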