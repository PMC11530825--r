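# rnadyn

Trajectory analysis of antisense-oligonucleotide (ASO) / RNA-hairpin
complexes in R: dynamic residue-pair contact maps with
specific/nonspecific classification and occupancy filtering, four-group
nonbonded interaction-energy decomposition, base-pair / Hoogsteen-edge /
triple-base-pair detection, ensemble descriptors (RMSD, per-residue
RMSF, radius of gyration, PCA), and nucleic-acid geometry (backbone
torsions, sugar pucker pseudorotation, base-pair and step helical
parameters). A seeded synthetic-ensemble generator with known ground
truth makes every stage testable without external trajectory data.

The package is written for structural bioinformaticians studying why an
ASO binds its target hairpin stably — or fails to: which base-base
contacts persist, where Hoogsteen edges and base triples form, how the
interaction energy splits between sequence-reading (base-base) and
backbone-mediated terms, and where fraying begins.

## The statistics at the core

* **Contacts.** Per frame, typed atom contacts (hydrogen bond, salt
  bridge, apolar) aggregate to residue pairs with *unit weight*: every
  contact counts 1, so pair strength is a simultaneous-contact count. A
  contact is *specific* iff both atoms are nucleobase atoms; anything
  touching the sugar-phosphate backbone is *nonspecific*. Pairs present
  in more than 10% of the analysis window survive the occupancy filter
  (strict inequality); block-wise series resolve rearrangements in
  time.
* **Energies.** Short-range Coulomb + Lennard-Jones,
  E = k q_i q_j / r + 4ε[(σ/r)¹² − (σ/r)⁶] with k = 332.0636
  kcal·Å·mol⁻¹·e⁻², Lorentz–Berthelot combination, 10 Å cutoff,
  decomposed over the four base/backbone group crossings
  (ASOBase–hairpinBase, ASOBac–hairpinBac, ASOBase–hairpinBac,
  ASOBac–hairpinBase); the total is identically their sum. Free-energy
  bookkeeping: ΔG = ΔH − TΔS.
* **Geometry.** Pseudorotation phase from the five endocyclic torsions,
  tan P = ((ν₄+ν₁) − (ν₃+ν₀)) / (2ν₂(sin 36° + sin 72°)), with 18°
  conformer sectors (C3′-endo at 18°, C2′-endo at 162°, …); base-pair
  (shear, stretch, stagger, buckle, propeller, opening) and step
  (shift, slide, rise, tilt, roll, twist) parameters from
  standard-reference-frame mid-frame algebra.
* **Pairing.** Base pairs from base-base H-bond sets with per-base edge
  classification (Watson-Crick / Hoogsteen / sugar); a base pairing two
  partners is the center of a triple (e.g. U·A–U: WC + Hoogsteen edges
  on the central adenine); declining block-wise persistence flags
  fraying.

See `vignettes/rnadyn-methods.Rmd` for assumptions, parameter defaults,
and design rationale.

## Worked example

```r
library(rnadyn)

# U.A-U triple: central adenine pairs one uridine on its WC edge and
# a second on its Hoogsteen edge
res  <- data.frame(residue_index = c(21, 5, 31),
                   nucleotide = c("A", "U", "U"),
                   chain_label = c("A", "B", "A"))
plan <- data.frame(res_i = c(21, 21), res_j = c(5, 31),
                   edge_i = c("WC", "Hoogsteen"), edge_j = c("WC", "WC"))
scene <- build_paired_arrangement(res, plan)

bp <- detect_base_pairs(scene)
bp
#>   res_i res_j n_hbonds    edge_i edge_j     category
#> 2     5    21        2        WC     WC watson_crick
#> 1    21    31        2 Hoogsteen     WC    hoogsteen

detect_triples(bp)
#>   central partner_1 partner_2 edge_1    edge_2 distinct_edges closed
#> 1      21         5        31     WC Hoogsteen           TRUE  FALSE
```

The adenine (residue 21) reads as the center of one triple, engaging
uridine 5 through its Watson-Crick face and uridine 31 through its
Hoogsteen face — the motif that anchors ASO binding beyond plain
sequence complementarity.

Reported per-system group means recombine under the decomposition's
total rule (stage 4 of the analysis prints):

```
  unmodified  total  -304.7 kcal/mol (reported  -304.7)
  truncated   total  -228.2 kcal/mol (reported  -228.2)
Gibbs bookkeeping dG = dH - TdS (2 M salt):
  unmodified  dG  -54.1 kcal/mol (reported  -54.1)
  AAtoCC      dG  -51.6 kcal/mol (reported  -51.6)
```

## The analysis workflow

Numbered drivers under `analysis/` run the full workflow on the
built-in synthetic scene and write their tables to `results/`:

```sh
Rscript analysis/01_simulate.R     # generate ensemble, PDB round trip
Rscript analysis/02_descriptors.R  # RMSD/Rg traces, RMSF, PCA
Rscript analysis/03_contacts.R     # contact maps, 10% filter, evolution
Rscript analysis/04_energies.R     # four-group decomposition, matrices
Rscript analysis/05_geometry.R     # torsions, puckers, bp/step params
Rscript analysis/06_pairing.R      # pairs, triples, fraying
```

Each script states what it found; for example stage 3 reports the
scheduled 60%-occupancy contact recovered at 0.600 and stage 2 finds
the two residues the generator made mobile. `run_pipeline()` bundles
the same stages behind one validated configuration with deterministic,
provenance-headed outputs.

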