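#!/usr/bin/env Rscript
# Stage 2 — curate the feature table.
#
# Removes features dominated by the procedural blank (3x mean-fold rule) and
# collapses near-duplicate features (5 mDa / 0.1 min, single linkage, most
# intense member kept). Writes the curated tables under results/.

library(oliveauth)

tab <- read_table("results/data/feature_table.csv")
suspects <- read_table("results/data/suspect_table.csv")

p0 <- nrow(tab$features)
tab <- filter_blank_features(tab, fold = 3)
p1 <- nrow(tab$features)
tab <- merge_duplicates(tab, mz_tol = 0.005, rt_tol = 0.1)
p2 <- nrow(tab$features)
message(sprintf("curation: %d features -> %d after blank removal -> %d after duplicate merging",
                p0, p1, p2))

keep <- match(tab$features$feature_id, suspects$features$feature_id)
suspects <- feature_table(suspects$intensities[, keep, drop = FALSE],
                          tab$features, suspects$samples)

write_table(tab, "results/curated_table.csv")
write_table(suspects, "results/curated_suspects.csv")
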