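#!/usr/bin/env Rscript
# Stage 5: nucleic-acid geometry -- backbone/glycosidic torsions, sugar
# pucker pseudorotation with conformer classes, and intra-base-pair
# plus step helical parameters for the stem pairs.
#
# Ground truth: every built nucleotide is C3'-endo (phase near 18 deg)
# with chi = -160, gamma = 54, beta = 178; jitter of 0.05 A broadens
# but does not shift the distributions.

suppressMessages(library(rnadyn))
dir.create("results", showWarnings = FALSE)

scene <- demo_scene(seed = 1, n_frames = 100)
gp <- geometry_profiles(scene$ensemble, pairing = scene$pairing,
                        window = c(0, 49))
write.csv(gp$torsions, "results/torsions.csv", row.names = FALSE)
write.csv(gp$puckers, "results/puckers.csv", row.names = FALSE)
write.csv(gp$bp_params, "results/bp_params.csv", row.names = FALSE)
write.csv(gp$step_params, "results/step_params.csv", row.names = FALSE)

cat("Sugar pucker conformer frequencies (all residues, 50 frames):\n")
print(round(table(gp$puckers$conformer) / nrow(gp$puckers), 3))
# residue 3 carries a 0.4 A sigma that scrambles its ring geometry, so
# summarize with the (robust) median rather than the mean
cat(sprintf("Median pucker phase: %.1f deg (built at 18 deg)\n",
            median(gp$puckers$phase)))

chi_mean <- circular_mean(gp$torsions$chi)
gamma_mean <- circular_mean(gp$torsions$gamma)
cat(sprintf("Circular-mean chi %.1f deg (built -160), gamma %.1f (built 54)\n",
            chi_mean, gamma_mean))

cat("Window-mean intra-bp parameters of the stem pairs:\n")
agg <- aggregate(gp$bp_params[, c("shear", "stretch", "stagger",
                                  "buckle", "propeller", "opening")],
                 by = list(res_i = gp$bp_params$res_i,
                           res_j = gp$bp_params$res_j), mean)
print(agg, digits = 2)
cat("Wrote results/torsions.csv, puckers.csv, bp_params.csv,",
    "step_params.csv\n")
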