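#!/usr/bin/env Rscript
# Stage 3 — choose the scaling method.
#
# Fits all nine pretreatment methods on the Kennard-Stone training rows,
# scores each fitted PLS-DA model with the composite score
# 0.15 R2X + 0.15 R2Y + 0.20 Q2 + 0.15 (1-RMSEE) + 0.30 (1-RMSEP)
# + 0.01/0.02/0.02 accuracies, and writes the ranking.

library(oliveauth)

seed <- 1L
tab <- read_table("results/curated_table.csv")
samp <- subset_roles(tab, "sample")
split <- kennard_stone(
  apply_scaling(samp, fit_scaling(samp, "pareto"))$intensities, 51)

ranking <- rank_scalings(tab, split, n_lv = 3, k = 5, seed = seed)
dir.create("results", showWarnings = FALSE)
write.csv(ranking, "results/scaling_ranking.csv", row.names = FALSE)

message("scaling ranking (composite score):")
for (i in seq_len(nrow(ranking)))
  message(sprintf("  %-12s %.3f", ranking$method[i], ranking$score[i]))
message(sprintf("selected: %s", ranking$method[1]))
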