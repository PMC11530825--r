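---
title: "Methods: contact dynamics, energetics, and geometry of ASO-RNA ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact dynamics, energetics, and geometry of ASO-RNA ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

rnadyn analyses structural ensembles of antisense-oligonucleotide (ASO)
RNA-hairpin complexes: ordered coordinate frames over a fixed topology,
as produced by molecular-dynamics simulation or NMR. This vignette is
the package's own account of the methods, their assumptions, the
tunable parameters, and the choices made where the design was open.

## The system and its representation

The topology partitions every atom into exactly one of two roles:
*base* (ring and exocyclic atoms of the nucleobase) or *backbone*
(phosphate and sugar, including C1'). The 2'-hydroxyl is counted as
backbone by default -- it is a sugar substituent -- and the assignment
is configurable (`o2prime_role`). This dichotomy drives the package's
central distinction: an interaction is **specific** when both atoms are
base-role (the sequence-reading contacts), and **nonspecific** when at
least one backbone atom is involved.

Residues carry region labels (`aso`, `hairpin_strand1`,
`hairpin_strand2`) supplied by an explicit mapping, never inferred from
chain identifiers. The default profile places the ASO at residues 1-10
and the hairpin at 11-42, treated as two strands (11-26, 27-42) for
helical-parameter purposes. Frame times are in ns and taken from the
ensemble's time stamps; they are never assumed uniform.

Multi-model PDB is the baseline exchange format (read via bio3d, with a
pre-scan so that a model with a deviant atom count is reported by model
number; written by a fixed-column formatter at the format's 3-decimal
precision). Hydrogens are optional throughout: every heavy-atom
analysis works without them, and the hydrogen-bond angle criterion
degrades to a distance-only criterion when they are absent.

## Contact dynamics

Per frame, typed atom contacts are detected:

* **hydrogen bond** -- donor and acceptor heavy atoms within
  `hbond_dist` (default 3.0 Å) and, when the donor's hydrogens are in
  the topology and `use_hydrogen_angle` is `TRUE`, a donor-H...acceptor
  angle of at least `hbond_angle` (default 135°);
* **salt bridge** -- heavy atoms of oppositely charged formal-charge
  groups within `salt_dist` (default 4.0 Å). An RNA-RNA complex has no
  formally cationic group, so the default cation set is empty and salt
  bridges appear only if the user declares one;
* **apolar** -- two carbon atoms within `apolar_dist` (default 4.0 Å).
  Base-base apolar contacts double as the proxy for stacking; there is
  no dedicated stacking-geometry test.

The numeric defaults follow common MD-analysis practice; all are
configurable and recorded in every output. An atom pair is reported at
most once per frame, with precedence hydrogen bond > salt bridge >
apolar, so the unit-weight strengths below are never double-counted.
Same-residue pairs and covalent neighbours (|i-j| <= 1 within one
chain) are excluded.

Contacts aggregate to residue pairs with **unit weight**: every contact
counts 1 regardless of type, deliberately flattening the very different
energetics of hydrogen bonds, salt bridges and apolar contacts into a
simple simultaneous-contact count. Occupancy is the fraction of
analysis-window frames with at least one contact; the occupancy filter
keeps pairs **strictly above** the threshold (default 0.10 -- "present
more than 10% of the time"). The strict inequality is a deliberate
reading; it is configurable. Block-wise evolution splits the window
into equal frame blocks to resolve contact-network rearrangements in
time.

## Nonbonded energetics

Pair energies are short-range force-field terms:
Coulomb `k q_i q_j / r` with `k = 332.0636 kcal Å mol^-1 e^-2` plus
Lennard-Jones `4 eps [ (sig/r)^12 - (sig/r)^6 ]` under
Lorentz-Berthelot combination (arithmetic sigma, geometric epsilon --
the AMBER-family convention), truncated at a plain 10 Å cutoff with no
switching function and no long-range correction. That mirrors how
short-range interaction-energy groups are reported by MD engines; the
cutoff is configurable.

The four-group decomposition crosses the base/backbone partition with
the ASO/hairpin split: base-base (the specific group), plus
backbone-backbone, base-backbone and backbone-base (the nonspecific
groups). The total is, identically, the sum of the four components --
a bookkeeping contract the tests enforce to 1e-8 relative on arbitrary
synthetic inputs, and which also recombines reported per-system group
means into their published totals. Free-energy bookkeeping is the
identity `dG = dH - TdS`, with TdS supplied as the
temperature-weighted entropy term.

Intramolecular energies are refused rather than computed wrongly: the
1-2/1-3/1-4 bonded exclusions a force field would apply are irrelevant
for inter-group (ASO vs hairpin) energies and are not implemented, so
overlapping groups raise an error. The per-residue-pair energy matrix
is the force-field nonbonded analogue of an implicit-solvent
decomposition -- it contains no solvation or entropy terms and is
labelled accordingly in outputs.

## Ensemble descriptors

RMSD is measured after optimal least-squares (Kabsch) superposition
over the selection (default heavy atoms); a no-fit variant is
available. RMSF superposes frames to the iterated window mean, takes
per-atom `sqrt(<|r - <r>|^2>)`, and averages unweighted over each
residue's heavy atoms. The radius of gyration is mass-weighted with
standard atomic masses. PCA superposes to the mean and
eigendecomposes the 3N-coordinate covariance (via `prcomp`); the
variance fraction of mode k is `lambda_k / sum(lambda)`.

One design point deserves emphasis. Superposition is the right default
for real trajectories, where frames arrive in arbitrary lab frames.
But for ensembles already expressed in a common frame -- exactly what
the synthetic generator produces -- fitting is harmful: the small
random rotations that best-fit a noisy frame leak the mobile residues'
noise into the static ones (at the 1e-2 Å level), and a collective
motion along one direction is partially absorbed into the removed
rigid translation. `rmsf_per_residue()` and `pca_ensemble()` therefore
take `fit = FALSE` for pre-aligned ensembles; the parameter-recovery
tests use that mode, and their exact zeros (static residues below
1e-10 Å; a one-dimensional motion giving a PC1 fraction of exactly 1)
are only meaningful in it.

Moving averages are centered with truncated windows at the ends, used
identically for descriptor traces and energy component traces
(default smoothing 5 frames in the pipeline; 1 ns is the natural
window when frames are 1 ns apart).

## Nucleic-acid geometry

Torsions use the standard atan2 dihedral on (-180°, 180°]; angle
averages are circular means. Sugar pucker follows the
pseudorotation construction on the five endocyclic torsions:

`tan P = ((nu4 + nu1) - (nu3 + nu0)) / (2 nu2 (sin 36° + sin 72°))`

with the amplitude `nu_max = nu2 / cos P` and conformers assigned by
18°-wide sectors: envelopes centered at 18° (C3'-endo), 54° (C4'-exo),
162° (C2'-endo), 342° (C2'-exo) and so on around the wheel, twists
between them. A flat ring (all nu = 0) reports amplitude 0 and
conformer "planar". Beta and delta are computed alongside the
alpha/gamma/epsilon/zeta/chi set for completeness.

Base-pair and step parameters use the standard-reference-frame
mid-frame algebra: a planar base template in its standard frame is
least-squares fitted to the observed ring atoms, the strand-2 frame is
flipped (y and z reversed), the relative rotation is split into a
twist about the mean z-axis and a roll-tilt rotation about the hinge,
and translations are expressed in the mid frame. This is the
conventional reference-frame construction, not a curvilinear-axis
analysis: values agree in convention but not bit-for-bit with
curvilinear tools, and groove widths or axis bending are out of scope.
The parameters obey the required strand-swap rules (shear and buckle
change sign; stretch, stagger, propeller, opening are invariant),
which the tests check on random frames.

## Base pairs, edges, and triples

Base pairs are read off the base-base hydrogen-bond set. Pair
*detection* deliberately uses looser, structure-annotation-style
criteria than contact *counting*: donor-acceptor heavy atoms within
3.5 Å and no hydrogen-angle requirement (`pairing_criteria()`), the
convention of structure-annotation tools, which keeps detection robust
to thermal jitter. Each H-bond-capable base atom belongs to exactly
one edge class (Watson-Crick, Hoogsteen, or sugar). Two conventions
resolve atoms that serve several faces: O6 of guanine is assigned to
the WC face (its Hoogsteen engagements are still identified by the N7
signature), and per-pair edge calls take the majority class of the
participating atoms with ties resolved Hoogsteen > WC > sugar. Under
these rules a G·U wobble classifies as WC-edge while an A·U Hoogsteen
pair classifies as Hoogsteen, as they should.

A pair is `watson_crick` when both bases engage through WC edges with
at least 2 hydrogen bonds, `hoogsteen` when either base engages its
Hoogsteen face with at least 1, and `other` otherwise; the minimum
counts are configurable and were chosen for robustness to jitter, not
taken from any reference. A residue pairing two partners is the
center of a triple; the report records the edge used toward each
partner, whether the edges differ, and whether the partners also pair
each other (closed triangle) -- both open and closed triples are
reported, flagged, since the field's usage covers both. Fraying shows
up as declining block-wise pair persistence; a pair whose last-block
presence falls below half its first-block presence is flagged as a
fraying candidate.

## The synthetic generator: what it emulates, and what it does not

The generator builds scenes from idealized nucleotides: planar base
templates in their standard reference frames, a furanose ring realized
at any requested pseudorotation phase by penalized least squares over
the ring coordinates (torsion targets `nu_j = nu_max cos(P + 144°(j-2))`
with `nu_max = 38°`, hit to well under the 2° contract), glycosidic
and backbone torsions set by construction (chi default -160°, gamma
54°, beta 178°, A-form-like), and polar hydrogens placed with ideal
sp2 geometry. Pairing plans pose partner residues rigidly by
restrained least squares: requested donor-acceptor pairs at
2.9 Å, donor-H...acceptor near-linearity, base-plane coplanarity, and
a clash penalty, from eight rotational starts. Plans that force
residues within 1.5 Å are rejected as sterically impossible.

Dynamics are deliberately simple: independent isotropic Gaussian
displacement per atom with a per-residue sigma (so per-atom RMSF
converges to `sigma * sqrt(3)`), and scheduled contacts that keep the
mobile residue's in-contact coordinates in a seed-chosen fraction of
frames and displace it radially outward past every cutoff otherwise.
The on-frame count is `ceiling(occupancy * n_frames)` -- the smallest
count not below the target -- so a 15% schedule over 200 frames gives
exactly 30 contact frames while a 10.1% schedule over 500 frames
(50.5) realizes 51 and strictly exceeds the 10% filter, as the filter
semantics require. One root seed drives per-operation child streams;
equal (specification, seed) gives bit-identical ensembles.

What this does *not* emulate: bonded strain (residues move rigidly or
with unphysical per-atom noise), phosphodiester connectivity between
posed residues (alpha/epsilon/zeta are undefined on unlinked
residues), solvent and counterions, correlated collective motions, and
any force-field energetics. Passing tests therefore demonstrate that
the analysis machinery recovers known geometric and statistical ground
truth -- occupancies, fluctuation amplitudes, pucker phases, pairing
motifs -- not that it reproduces the physics of a real trajectory.
The synthetic nonbonded parameter set is likewise labelled synthetic:
element-based charges placing the formal charge on the phosphate with
near-neutral dipolar bases, adequate for testing summation, cutoff and
partition contracts, not for energetics of real RNA.

## Problem sizes and numerics

The test-suite and acceptance computations run on deliberately small
ensembles chosen to make the statistical contracts sharp: 500 frames
for occupancy recovery (resolution 1/500), 5000 frames for
sigma-recovery within 3%, 100 jittered poses for pairing robustness,
and random 50-200-atom frames for brute-force contact equivalence.
Degenerate inputs fail loudly: zero interatomic distance in a pair
energy, empty analysis windows, empty atom selections, planar rings,
missing ring atoms, unparameterized atoms (reported as a complete
list, never zero-filled), and overlapping energy groups all raise
errors. Ring construction caches per conformer; pairing poses are
deterministic (fixed optimizer starts, no randomness), so the whole
pipeline is a pure function of (inputs, configuration, seed).

## Known limitations

Curvilinear helical axes, groove geometry, cis/trans (full
Leontis-Westhof) pair annotation, literature triple-compatibility
tables, water-mediated contacts and ion bridges, implicit-solvent
energies and normal-mode entropies are all out of scope; the
free-energy layer is bookkeeping only. Modified nucleotides and
protein residues are rejected at parse time. The per-residue-pair
energy matrix is a force-field nonbonded analogue and should not be
read as a binding free-energy decomposition.
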