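# shared fixtures and independent oracles

# printed reference values for the 26 identified markers: molecular formula
# and theoretical [M-H]- m/z (4 decimal places)
MARKER_MZ <- data.frame(
  formula = c("C6H6O2", "C8H10O3", "C7H8O2", "C8H10O2", "C4H6O5", "C7H12O6",
              "C15H10O5", "C15H10O6", "C15H10O6", "C18H30O2", "C18H32O2",
              "C18H34O2", "C18H30O3", "C18H32O3", "C18H30O4", "C18H32O4",
              "C17H24O11", "C17H24O11", "C17H24O11", "C25H28O13", "C25H32O13",
              "C25H36O13", "C29H36O15", "C29H36O15", "C29H36O16", "C9H8O4"),
  mz = c(109.0295, 153.0557, 123.0452, 137.0608, 133.0142, 191.0561,
         269.0455, 285.0405, 285.0405, 277.2173, 279.2330, 281.2486,
         293.2122, 295.2279, 309.2071, 311.2228, 403.1246, 403.1246,
         403.1246, 535.1457, 539.1770, 543.2083, 623.1981, 623.1981,
         639.1931, 179.0350)
)

# a tiny deterministic 3x2 feature table
tiny_table <- function() {
  feature_table(
    intensities = matrix(c(1, 2, 3, 10, 20, 30), nrow = 3,
                         dimnames = list(NULL, c("Fa", "Fb"))),
    features = data.frame(feature_id = c("Fa", "Fb"), mz = c(100.1, 200.2),
                          rt = c(1.5, 5.0)),
    samples = data.frame(sample_id = c("s1", "s2", "s3"),
                         role = "sample",
                         class_label = c("A", "A", "B"))
  )
}

# reduced-size synthetic study for fast tests
small_spec <- function(seed = 7L, ...) {
  args <- list(
    n_per_class = c(Greece = 8, Egypt = 9, Chile = 7),
    n_features = 150, n_markers_per_class = 4, n_qc = 3, n_blank = 2,
    n_duplicates = 3, n_suspect = 4, seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(synthetic_spec, args)
}

small_bundle <- function(seed = 7L, ...) generate_bundle(small_spec(seed, ...))

truth_marker_ids <- function(bundle, cls = NULL) {
  tr <- bundle$truth
  keep <- !is.na(tr$marker_class) & is.na(tr$duplicate_of)
  if (!is.null(cls)) keep <- keep & tr$marker_class == cls
  tr$feature_id[keep]
}

# scale on training rows only, split by a Kennard-Stone object: the standard
# modelling path used across tests (mirrors the analysis workflow)
modelling_path <- function(bundle, n_train, n_lv, method = "pareto") {
  samp <- subset_roles(bundle$table, "sample")
  pareto_all <- fit_scaling(samp, "pareto")
  split <- kennard_stone(apply_scaling(samp, pareto_all)$intensities, n_train)
  idx_tr <- match(split$train_ids, samp$samples$sample_id)
  idx_te <- match(split$test_ids, samp$samples$sample_id)
  qc <- subset_roles(bundle$table, "qc")
  train_ft <- feature_table(samp$intensities[idx_tr, , drop = FALSE],
                            samp$features, samp$samples[idx_tr, , drop = FALSE])
  fit_ft <- feature_table(
    rbind(samp$intensities[idx_tr, , drop = FALSE], qc$intensities),
    samp$features, rbind(samp$samples[idx_tr, , drop = FALSE], qc$samples))
  params <- fit_scaling(fit_ft, method)
  test_ft <- feature_table(samp$intensities[idx_te, , drop = FALSE],
                           samp$features, samp$samples[idx_te, , drop = FALSE])
  list(split = split, params = params,
       X_train = apply_scaling(train_ft, params)$intensities,
       X_test = apply_scaling(test_ft, params)$intensities,
       y_train = train_ft$samples$class_label,
       y_test = test_ft$samples$class_label,
       model = fit_plsda(apply_scaling(train_ft, params)$intensities,
                         train_ft$samples$class_label, n_lv))
}

# --- independent oracles ------------------------------------------------

# Mann-Whitney AUC: P(score_pos > score_neg) + 0.5 P(tie), via ranks
mann_whitney_auc <- function(score, positive) {
  r <- rank(score)
  n_pos <- sum(positive); n_neg <- sum(!positive)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# closed-form OLS with standard errors
ols_oracle <- function(x, y) {
  n <- length(x)
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  b <- sum((x - xb) * (y - yb)) / sxx
  a <- yb - b * xb
  res <- y - a - b * x
  s2 <- sum(res^2) / (n - 2)
  list(slope = b, intercept = a,
       slope_se = sqrt(s2 / sxx),
       intercept_se = sqrt(s2 * (1 / n + xb^2 / sxx)),
       r2 = 1 - sum(res^2) / sum((y - yb)^2))
}

# brute-force isotope pattern: full multinomial enumeration, no pruning.
# Returns raw isotopologue probabilities (summing to 1) and their masses.
isotope_oracle <- function(formula) {
  counts <- parse_formula(formula)
  isotopes <- get("ISOTOPES", envir = asNamespace("oliveauth"))
  states <- list(data.frame(mass = 0, prob = 1))
  for (el in names(counts)) {
    iso <- isotopes[[el]]
    k <- counts[[el]]
    combos <- compositions(k, nrow(iso))
    el_states <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
      cnt <- combos[i, ]
      data.frame(mass = sum(cnt * iso$mass),
                 prob = exp(lfactorial(k) - sum(lfactorial(cnt)) +
                              sum(cnt * log(iso$abundance))))
    }))
    states <- list(merge_states(states[[1]], el_states))
  }
  st <- states[[1]]
  st[order(st$mass), ]
}

compositions <- function(k, parts) {
  if (parts == 1) return(matrix(k, 1, 1))
  out <- NULL
  for (first in 0:k) {
    sub <- compositions(k - first, parts - 1)
    out <- rbind(out, cbind(first, sub))
  }
  unname(out)
}

merge_states <- function(a, b) {
  mass <- outer(a$mass, b$mass, "+")
  prob <- outer(a$prob, b$prob)
  data.frame(mass = as.vector(mass), prob = as.vector(prob))
}

# sum oracle isotopologues within a window around (monoisotopic + offset)
oracle_cluster_abundance <- function(oracle, mono, offset, width = 0.25) {
  sel <- abs(oracle$mass - (mono + offset)) < width
  100 * sum(oracle$prob[sel]) / max(oracle$prob)
}
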