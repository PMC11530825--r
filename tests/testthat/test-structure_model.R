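test_that("role partition is total and exclusive for every residue template", {
  for (nuc in c("A", "C", "G", "U")) {
    nt <- build_nucleotide(nuc)
    roles <- classify_atom_roles(nt$atom_name, nuc)
    expect_length(roles, nrow(nt))
    expect_true(all(roles %in% c("base", "backbone")))
    # phosphate and sugar atoms backbone, ring/exocyclic base
    expect_equal(roles[nt$atom_name == "OP1"], "backbone")
    expect_equal(roles[nt$atom_name == "C1'"], "backbone")
    if (nuc %in% c("A", "G"))
      expect_equal(roles[nt$atom_name == "N7"], "base")
  }
  expect_error(classify_atom_roles("XX9", "A"), "unrecognized atom name")
})

test_that("O2' role is configurable but backbone by default", {
  expect_equal(classify_atom_roles("O2'", "A"), "backbone")
  expect_equal(classify_atom_roles("O2'", "A", o2prime_role = "base"),
               "base")
})

test_that("topology construction validates residues and regions", {
  res <- data.frame(residue_index = 1:2, nucleotide = c("A", "U"))
  atoms <- data.frame(atom_name = c("P", "C1'", "N1"),
                      residue_index = c(1, 1, 2))
  topo <- build_topology(res, atoms,
                         region_map = list(aso = 1, hairpin_strand1 = 2))
  expect_s3_class(topo, "topology")
  expect_equal(topo$residues$region, c("aso", "hairpin_strand1"))
  expect_error(build_topology(data.frame(residue_index = 1,
                                         nucleotide = "T"),
                              atoms[1, ]), "unsupported residue")
  expect_error(build_topology(res, atoms,
                              region_map = list(aso = 1:2,
                                                hairpin_strand1 = 2)),
               "overlaps")
})

test_that("nonbonded parameter attachment reports all missing atoms", {
  sc <- wc_scene()
  topo <- sc$topology
  params <- synthetic_param_table(topo)
  full <- attach_nonbonded_params(topo, params)
  expect_false(anyNA(full$atoms$charge))
  drop <- params[!(params$residue == "A" & params$atom == "N7"), ]
  expect_error(attach_nonbonded_params(topo, drop), "A N7")
})

test_that("net charge equals the sum of table entries", {
  sc <- wc_scene()
  topo <- sc$topology
  params <- synthetic_param_table(topo)
  params$charge_e <- rep_len(c(0.5, -0.5), nrow(params))
  full <- attach_nonbonded_params(topo, params)
  key <- paste(topo$atoms$nucleotide, topo$atoms$atom_name)
  pkey <- paste(params$residue, params$atom)
  expect_equal(sum(full$atoms$charge),
               sum(params$charge_e[match(key, pkey)]))
})

test_that("multi-model PDB write/read round trip preserves coordinates", {
  sc <- demo_ens <- perturb(wc_scene(), 0.3, n_frames = 10, seed = 7)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(demo_ens, path)
  back <- read_multimodel_pdb(path)
  expect_equal(dim(back$xyz), dim(demo_ens$xyz))
  expect_lt(max(abs(back$xyz - demo_ens$xyz)), 1e-3 + 1e-9)
  # residue renumbering is a bijection onto a contiguous 1-based scheme
  expect_equal(back$topology$residues$residue_index,
               seq_len(nrow(back$topology$residues)))
  expect_equal(back$topology$residues$nucleotide,
               demo_ens$topology$residues$nucleotide)
})

test_that("single-model PDB gives a one-frame ensemble unchanged", {
  ens <- wc_scene()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, path)
  back <- read_multimodel_pdb(path)
  expect_equal(dim(back$xyz)[1], 1L)
  expect_equal(dim(back$xyz)[2], nrow(ens$topology$atoms))
})

test_that("mismatched atom counts across models name the model", {
  ens <- perturb(wc_scene(), 0.1, n_frames = 3, seed = 1)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, path)
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  atom_lines <- grep("^ATOM", lines)
  drop <- max(atom_lines[atom_lines > starts[2] &
                           atom_lines < grep("^ENDMDL", lines)[2]])
  writeLines(lines[-drop], path)
  expect_error(read_multimodel_pdb(path), "model 2")
})

test_that("non-nucleotide residues are rejected", {
  lines <- c(
    "MODEL     1",
    "ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ENDMDL", "END")
  expect_error(read_multimodel_pdb(lines), "non-nucleotide")
})
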