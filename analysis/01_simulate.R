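#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Generates a synthetic cohort with the structure the downstream analyses
# assume: bimodal ESR1/PGR/ERBB2 receptor expression, centroid-structured
# subtype signal with immune/stromal admixture, TIL percentages
# rank-correlated with the immune admixture, per-subtype pCR rates and
# survival hazards. Writes the expression matrix, clinical table, TIL table
# and ground truth under results/sim/.

suppressPackageStartupMessages(library(tnbctype4))

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- cohort_config(n_samples = 1000, seed = 2026)
cohort <- generate_cohort(cfg)

write_expression(cohort$expression, file.path(out, "expression.tsv"))
write_centroids(cohort$centroids, file.path(out, "centroids.tsv"))
write.csv(cohort$clinical, file.path(out, "clinical.csv"), row.names = FALSE)
write.csv(cohort$til, file.path(out, "til.csv"), row.names = FALSE)
write.csv(cohort$truth, file.path(out, "truth.csv"), row.names = FALSE)

cat(sprintf("simulated %d samples (%d true TNBC, %.1f%%)\n",
            cfg$n_samples, sum(cohort$truth$is_tnbc),
            100 * mean(cohort$truth$is_tnbc)))
cat("subtype truth distribution:\n")
print(round(table(cohort$truth$subtype) / cfg$n_samples, 3))
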