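#' Specification of a synthetic three-class olive study
#'
#' Describes the generative model used to emulate a 65-sample non-target LC-MS
#' authenticity study: three geographical classes (20/24/21 samples), ~2000
#' aligned features with log-normal baseline abundances, a small set of
#' class-elevated marker features, pooled-QC rows, procedural blanks carrying a
#' contaminant subset of features, injected near-duplicate feature pairs, and
#' an extra "suspect" set drawn from the first class with a harvest-year shift.
#'
#' @param n_per_class named integer vector of biological samples per class.
#' @param n_features number of true features before duplicate injection.
#' @param n_markers_per_class number of marker features elevated in each class.
#' @param marker_fold_change multiplicative elevation of a marker in its class
#'   (must be > 1 unless exactly 1 for null simulations).
#' @param base_log_mean,base_log_sd meanlog/sdlog of the log-normal baseline
#'   feature abundance.
#' @param dilution_sd sdlog of the per-sample multiplicative dilution factor.
#' @param noise_cv coefficient of variation of multiplicative measurement noise.
#' @param n_qc,n_blank number of pooled-QC and procedural blank rows.
#' @param blank_contaminant_fraction fraction of features that are background
#'   contaminants (present in blanks at sample-comparable level).
#' @param n_duplicates number of near-duplicate feature pairs injected
#'   (|dm/z| <= 3 mDa, |dRT| <= 0.05 min from their source feature).
#' @param n_suspect number of suspect samples from the first class.
#' @param year_shift_sd sdlog of the per-feature year-effect factor shared by
#'   all suspect samples.
#' @param seed integer seed; the same spec yields a byte-identical bundle.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class = c(Greece = 20, Egypt = 24, Chile = 21),
                           n_features = 2000,
                           n_markers_per_class = 10,
                           marker_fold_change = 5.0,
                           base_log_mean = 10,
                           base_log_sd = 1,
                           dilution_sd = 0.2,
                           noise_cv = 0.1,
                           n_qc = 6,
                           n_blank = 4,
                           blank_contaminant_fraction = 0.05,
                           n_duplicates = 8,
                           n_suspect = 11,
                           year_shift_sd = 0.3,
                           seed = 1L) {
  spec <- list(
    n_per_class = n_per_class, n_features = as.integer(n_features),
    n_markers_per_class = as.integer(n_markers_per_class),
    marker_fold_change = marker_fold_change,
    base_log_mean = base_log_mean, base_log_sd = base_log_sd,
    dilution_sd = dilution_sd, noise_cv = noise_cv,
    n_qc = as.integer(n_qc), n_blank = as.integer(n_blank),
    blank_contaminant_fraction = blank_contaminant_fraction,
    n_duplicates = as.integer(n_duplicates),
    n_suspect = as.integer(n_suspect), year_shift_sd = year_shift_sd,
    seed = as.integer(seed)
  )
  if (spec$n_features <= 0) stop("n_features must be positive")
  counts <- c(spec$n_per_class, spec$n_markers_per_class, spec$n_qc,
              spec$n_blank, spec$n_duplicates, spec$n_suspect)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (spec$marker_fold_change < 1) stop("marker_fold_change must be >= 1")
  n_special <- spec$n_markers_per_class * length(spec$n_per_class) +
    spec$n_duplicates +
    ceiling(spec$blank_contaminant_fraction * spec$n_features)
  if (n_special > spec$n_features)
    stop("markers + duplicates + contaminants exceed n_features")
  if (is.null(names(spec$n_per_class)))
    names(spec$n_per_class) <- paste0("class", seq_along(spec$n_per_class))
  class(spec) <- "synthetic_spec"
  spec
}

#' Generate a synthetic feature-table bundle
#'
#' Draws a complete study from a [synthetic_spec()]: intensity of feature j in
#' sample i is `baseline_j * class_effect * dilution_i * noise_ij`, where
#' `class_effect = marker_fold_change` when j is a marker of sample i's class
#' and 1 otherwise. QC rows are the pooled mean of all biological sample rows
#' plus measurement noise; blanks contain only the contaminant features, at the
#' same background level those features have in the samples. Suspect samples
#' follow the first class's generative model with an extra per-feature
#' year-effect factor common to the whole suspect set.
#'
#' @param spec a [synthetic_spec()].
#' @return A list of class `synthetic_bundle` with elements `table` (samples +
#'   QCs + blanks), `suspect_table`, and `truth` (per-feature data frame with
#'   `feature_id`, `marker_class`, `duplicate_of`, `is_contaminant`).
#' @export
generate_bundle <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  p <- spec$n_features
  classes <- names(spec$n_per_class)
  # m/z on a 10 mDa grid with <=2 mDa jitter: non-duplicate features can never
  # fall inside the 5 mDa merge tolerance of one another
  grid <- seq(80, 1000, by = 0.01)
  mz <- sort(sample(grid, p)) + stats::runif(p, -0.002, 0.002)
  rt <- stats::runif(p, 0.5, 15)

  # disjoint special feature sets: markers per class, contaminants, dup sources
  n_contam <- ceiling(spec$blank_contaminant_fraction * p)
  n_mark <- spec$n_markers_per_class
  pool <- sample.int(p, p)  # random order over all features
  marker_of <- rep(NA_character_, p)
  for (k in seq_along(classes)) {
    idx <- pool[seq_len(n_mark) + (k - 1L) * n_mark]
    marker_of[idx] <- classes[k]
  }
  contam_idx <- pool[n_mark * length(classes) + seq_len(n_contam)]
  # duplicate sources must be isolated in (m/z, rt) so that an injected copy
  # can only ever merge with its own source feature
  rest <- pool[-seq_len(n_mark * length(classes) + n_contam)]
  isolated <- vapply(rest, function(i) {
    near <- abs(mz - mz[i]) <= 0.012 & abs(rt - rt[i]) <= 0.3
    sum(near) == 1L
  }, logical(1))
  if (sum(isolated) < spec$n_duplicates)
    stop("feature space too crowded to inject isolated duplicates")
  dup_src <- rest[isolated][seq_len(spec$n_duplicates)]

  baseline <- stats::rlnorm(p, spec$base_log_mean, spec$base_log_sd)
  # contaminants sit at a low background level shared by samples and blanks
  baseline[contam_idx] <- baseline[contam_idx] * 0.01

  n_samp <- sum(spec$n_per_class)
  class_label <- rep(classes, spec$n_per_class)
  sdlog_noise <- sqrt(log(1 + spec$noise_cv^2))
  draw_rows <- function(n, labels, extra_log = 0) {
    dil <- stats::rlnorm(n, 0, spec$dilution_sd)
    eff <- matrix(1, n, p)
    for (k in seq_along(classes)) {
      rows <- which(labels == classes[k])
      cols <- which(marker_of == classes[k])
      if (length(rows) && length(cols))
        eff[rows, cols] <- spec$marker_fold_change
    }
    noise <- matrix(stats::rlnorm(n * p, 0, sdlog_noise), n, p)
    list(mat = (dil * eff) * rep(baseline, each = n) * noise *
           exp(rep(extra_log, each = n)),
         dilution = dil)
  }
  samp <- draw_rows(n_samp, class_label)

  qc_base <- colMeans(samp$mat)
  qc <- matrix(stats::rlnorm(spec$n_qc * p, 0, sdlog_noise),
               spec$n_qc, p) * rep(qc_base, each = spec$n_qc)

  blank <- matrix(0, spec$n_blank, p)
  if (spec$n_blank > 0 && length(contam_idx)) {
    blank[, contam_idx] <-
      matrix(stats::rlnorm(spec$n_blank * length(contam_idx), 0, sdlog_noise),
             spec$n_blank, length(contam_idx)) *
      rep(baseline[contam_idx], each = spec$n_blank)
  }

  year_shift <- stats::rnorm(p, 0, spec$year_shift_sd)
  susp <- draw_rows(spec$n_suspect, rep(classes[1], spec$n_suspect),
                    extra_log = year_shift)

  feature_id <- sprintf("F%04d", seq_len(p))
  features <- data.frame(feature_id = feature_id, mz = mz, rt = rt,
                         stringsAsFactors = FALSE)
  truth <- data.frame(feature_id = feature_id, marker_class = marker_of,
                      duplicate_of = NA_character_,
                      is_contaminant = seq_len(p) %in% contam_idx,
                      stringsAsFactors = FALSE)

  # inject near-duplicates: dimmer copies of their source features
  if (spec$n_duplicates > 0) {
    dmz <- stats::runif(spec$n_duplicates, -0.003, 0.003)
    drt <- stats::runif(spec$n_duplicates, -0.05, 0.05)
    dup_id <- sprintf("F%04d_dup", dup_src)
    features <- rbind(features, data.frame(
      feature_id = dup_id, mz = mz[dup_src] + dmz,
      rt = pmax(0, rt[dup_src] + drt), stringsAsFactors = FALSE))
    truth <- rbind(truth, data.frame(
      feature_id = dup_id, marker_class = marker_of[dup_src],
      duplicate_of = feature_id[dup_src],
      is_contaminant = dup_src %in% contam_idx, stringsAsFactors = FALSE))
    dup_cols <- function(m) m[, dup_src, drop = FALSE] * 0.6
    samp$mat <- cbind(samp$mat, dup_cols(samp$mat))
    qc <- cbind(qc, dup_cols(qc))
    blank <- cbind(blank, dup_cols(blank))
    susp$mat <- cbind(susp$mat, dup_cols(susp$mat))
  }

  samples <- data.frame(
    sample_id = c(sprintf("S%02d", seq_len(n_samp)),
                  sprintf("QC%02d", seq_len(spec$n_qc)),
                  sprintf("B%02d", seq_len(spec$n_blank))),
    role = c(rep("sample", n_samp), rep("qc", spec$n_qc),
             rep("blank", spec$n_blank)),
    class_label = c(class_label, rep(NA_character_, spec$n_qc + spec$n_blank)),
    stringsAsFactors = FALSE
  )
  tab <- feature_table(rbind(samp$mat, qc, blank), features, samples)

  susp_samples <- data.frame(
    sample_id = sprintf("Y%02d", seq_len(spec$n_suspect)),
    role = rep("suspect", spec$n_suspect),
    class_label = rep(classes[1], spec$n_suspect),
    stringsAsFactors = FALSE
  )
  suspect_table <- feature_table(susp$mat, features, susp_samples)

  structure(list(table = tab, suspect_table = suspect_table, truth = truth,
                 dilution = samp$dilution, spec = spec),
            class = "synthetic_bundle")
}

#' Write a synthetic bundle to disk
#'
#' Writes the main and suspect feature tables (see [write_table()]) and a
#' truth table CSV (`feature_id`, `marker_class`, `duplicate_of`,
#' `is_contaminant`).
#'
#' @param bundle a [generate_bundle()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(bundle$table, file.path(dir, "feature_table.csv"))
  write_table(bundle$suspect_table, file.path(dir, "suspect_table.csv"))
  utils::write.csv(bundle$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

# save/restore the global RNG state so seeded generators do not perturb
# the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
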