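#!/usr/bin/env Rscript
# Stage 6 — targeted method-performance figures of merit.
#
# Simulates an internal-standard-normalized standard-addition experiment for a
# panel of phenolic analytes (10 levels spanning 0.02-10 mg/kg, 3 replicates,
# known slopes, mild heteroscedastic noise, ~10% ion suppression) and computes
# the validation table: LOD/LOQ from the low-range curve (0.02-1 mg/kg),
# r-squared over the full range, recovery at 0.5 mg/kg, slope-ratio matrix
# effect, and intra-/inter-day precision.

library(oliveauth)

set.seed(101)
analytes <- data.frame(
  name = c("Gallic acid", "p-Coumaric acid", "Ferulic acid", "Hydroxytyrosol",
           "Tyrosol", "Oleuropein", "Apigenin", "Luteolin"),
  slope = c(0.11, 0.04, 0.037, 0.09, 0.031, 0.13, 0.25, 0.03),
  suppression = runif(8, 0.80, 0.92)  # matrix/solvent slope ratio
)
levels_full <- c(0.02, 0.05, 0.1, 0.2, 0.5, 1, 2, 5, 7.5, 10)

rows <- lapply(seq_len(nrow(analytes)), function(i) {
  a <- analytes[i, ]
  sim_resp <- function(conc, slope) {
    spiked <- 5000 * (0.02 + slope * conc) *
      exp(rnorm(length(conc), 0, 0.03))
    normalized_response(spiked, 5000 * 0.02, 5000)
  }
  lev <- rep(levels_full, each = 3)
  cal_full <- fit_calibration(lev, sim_resp(lev, a$slope))
  low <- lev[lev <= 1]
  cal_low <- fit_calibration(low, sim_resp(low, a$slope))
  meas <- sim_resp(rep(0.5, 8), a$slope) / cal_full$slope
  day2 <- sim_resp(rep(0.5, 3), a$slope) / cal_full$slope
  data.frame(
    analyte = a$name,
    lod = lod(cal_low), loq = loq(cal_low),
    r2 = cal_full$r2,
    recovery_pct = mean(recovery(meas, 0.5)),
    matrix_effect_pct = matrix_effect(a$slope * a$suppression, a$slope),
    rsd_intra = precision(meas[1:3] * 0.5, "intra"),
    rsd_inter = precision(c(meas[1:3], day2) * 0.5, "inter")
  )
})
report <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.csv(report, "results/method_performance.csv", row.names = FALSE)

message("method performance (simulated standard additions):")
for (i in seq_len(nrow(report)))
  message(sprintf("  %-16s LOD %.3f LOQ %.3f r2 %.4f RE %.1f%% ME %.1f%% RSDr %.1f%% RSDR %.1f%%",
                  report$analyte[i], report$lod[i], report$loq[i],
                  report$r2[i], report$recovery_pct[i],
                  report$matrix_effect_pct[i], report$rsd_intra[i],
                  report$rsd_inter[i]))
message(sprintf("LOQ/LOD ratio identical for all analytes: %.4f",
                unique(round(report$loq / report$lod, 4))))
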