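#!/usr/bin/env Rscript
# Stage 4 — fit and validate the classification model.
#
# Pareto-scales with parameters from the 51 Kennard-Stone training rows, fits
# a 3-latent-variable PLS-DA, and validates it: training/CV/test error, ROC
# AUC per class, R2X/R2Y/Q2, RMSEE/RMSEP, a 20-permutation test of Q2, T2/Q
# outlier diagnostics, and classification of the harvest-year suspect set.

suppressPackageStartupMessages({
  library(oliveauth)
  library(jsonlite)
})

seed <- 1L
tab <- read_table("results/curated_table.csv")
suspects <- read_table("results/curated_suspects.csv")

res <- run_pipeline(tab, suspect_table = suspects, scaling = "pareto",
                    n_train = 51, n_lv = 3, k = 5, n_perm = 20, seed = seed)

met <- res$metrics
aucs <- vapply(res$roc, `[[`, numeric(1), "auc")
message(sprintf("misclassification error: train %.2f | 5-fold CV %.2f | test %.2f",
                met$error_train, met$error_cv, met$error_test))
message(sprintf("R2X %.3f  R2Y %.3f  Q2 %.3f  RMSEE %.3f  RMSEP %.3f",
                met$r2x, met$r2y, met$q2, met$rmsee, met$rmsep))
message(sprintf("one-vs-rest AUC: %s",
                paste(sprintf("%s %.2f", names(aucs), aucs), collapse = ", ")))
message(sprintf("permutation test (%d perms): observed Q2 %.3f, max permuted %.3f, p = %.3f",
                res$permutation$n_perm, res$permutation$observed_q2,
                max(res$permutation$permuted_q2), res$permutation$p_value))
n_out <- sum(res$diagnostics$outlier)
message(sprintf("training outliers beyond both 95%% limits: %d", n_out))
message(sprintf("suspect assignments: %s",
                paste(sprintf("%s=%d", names(table(res$suspects$class)),
                              table(res$suspects$class)), collapse = ", ")))

report <- list(
  seed = seed, scaling = res$scaling, n_lv = res$n_lv,
  n_train = length(res$split$train_ids), n_test = length(res$split$test_ids),
  error = list(train = met$error_train, cv = met$error_cv,
               test = met$error_test),
  r2x = met$r2x, r2y = met$r2y, q2 = met$q2,
  rmsee = met$rmsee, rmsep = met$rmsep,
  auc = as.list(aucs),
  sensitivity = as.list(met$sensitivity),
  specificity = as.list(met$specificity),
  permutation = list(n_perm = res$permutation$n_perm,
                     observed_q2 = res$permutation$observed_q2,
                     permuted_q2 = res$permutation$permuted_q2,
                     p_value = res$permutation$p_value),
  outliers = list(t2_limit = res$diagnostics$t2_limit_95,
                  q_limit = res$diagnostics$q_limit_95,
                  n_flagged = n_out),
  suspect_classes = res$suspects$class
)
write_json(report, "results/validation_report.json", auto_unbox = TRUE,
           digits = 6, pretty = TRUE)
dir.create("scratch", showWarnings = FALSE)
saveRDS(res, "scratch/pipeline_result.rds")  # large; scratch only
message("wrote results/validation_report.json")
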