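#!/usr/bin/env Rscript
# Stage 5 — marker discovery and annotation.
#
# Selects marker features above the 0.83 VIP cutoff, derives pairwise
# OPLS-DA VIP profiles (one orthogonal + one predictive component per class
# pair), checks recovery against the generator truth, and annotates the
# markers against the packaged candidate list of olive phenolics (5 mDa mass
# window, 1.8 min retention-time rule).

library(oliveauth)

res <- readRDS("scratch/pipeline_result.rds")
truth <- read.csv("results/data/truth.csv", stringsAsFactors = FALSE)
truth_markers <- truth$feature_id[!is.na(truth$marker_class) &
                                    is.na(truth$duplicate_of)]

markers <- res$markers
message(sprintf("VIP > 0.83 selected %d of %d features; all %d truth markers recovered: %s",
                nrow(markers), nrow(res$vip), length(truth_markers),
                all(truth_markers %in% markers$feature)))

pw <- res$pairwise_vip
tab <- merge(markers, pw, by = "feature", sort = FALSE)
tab <- merge(tab, truth[, c("feature_id", "marker_class")],
             by.x = "feature", by.y = "feature_id", all.x = TRUE, sort = FALSE)
tab <- tab[order(-tab$vip), ]

cands <- read_candidates(system.file("extdata", "olive_candidates.csv",
                                     package = "oliveauth"))
feat <- res$curated$features
top <- utils::head(tab, 30)
ann <- do.call(rbind, lapply(top$feature, function(f) {
  i <- match(f, feat$feature_id)
  hits <- search_candidates(feat$mz[i], feat$rt[i], cands)
  if (!nrow(hits)) return(NULL)
  cbind(feature = f, hits[1, c("name", "formula", "theoretical_mz",
                               "mass_error_mda", "rt_error_min")])
}))
n_ann <- if (is.null(ann)) 0 else nrow(ann)
message(sprintf("%d of the top %d markers match a candidate within 5 mDa",
                n_ann, nrow(top)))
# synthetic m/z values are random, so matches here are coincidental; with
# real data this stage yields the identification shortlist

write.csv(tab, "results/marker_table.csv", row.names = FALSE)
if (n_ann) write.csv(ann, "results/marker_annotations.csv", row.names = FALSE)
message("wrote results/marker_table.csv")
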