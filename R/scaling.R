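#' @title Scaling and normalization of feature tables
#' @description Nine pretreatment methods commonly compared in LC-MS
#'   chemometrics. Parameters are always estimated on training rows with
#'   [fit_scaling()] and applied to any rows with [apply_scaling()], so test
#'   and suspect samples never leak into parameter estimation.
#' @name scaling
NULL

SCALING_METHODS <- c("pareto", "mean_center", "autoscale", "range", "vast",
                     "level", "glog_vsn", "log2_center", "pqn_pareto")

#' Fit scaling parameters on training rows
#'
#' Per-feature means, standard deviations (n-1 denominator) and ranges are
#' computed from the supplied table only. For `pqn_pareto` the PQN reference
#' spectrum is the per-feature median of the table's QC rows (falling back to
#' the median of sample rows when no QCs are present), and the Pareto
#' parameters are fitted on the PQN-normalized sample rows. For `glog_vsn` the
#' transform parameter `lambda` is the median non-zero training intensity and
#' the transformed columns are mean-centered.
#'
#' @param ft a [feature_table()] holding the training rows (QC rows may be
#'   present; parameter estimation uses rows with role `sample` plus, for the
#'   PQN reference, the QC rows).
#' @param method one of `"pareto"`, `"mean_center"`, `"autoscale"`, `"range"`,
#'   `"vast"`, `"level"`, `"glog_vsn"`, `"log2_center"`, `"pqn_pareto"`.
#' @return An object of class `scaling_params`.
#' @export
fit_scaling <- function(ft, method = "pareto") {
  method <- match.arg(method, SCALING_METHODS)
  X <- ft$intensities[ft$samples$role == "sample", , drop = FALSE]
  if (nrow(X) == 0) X <- ft$intensities
  if (nrow(X) < 2) stop("need >= 2 training rows")
  params <- list(method = method, feature_id = ft$features$feature_id)
  if (method == "pqn_pareto") {
    qc <- ft$intensities[ft$samples$role == "qc", , drop = FALSE]
    ref <- if (nrow(qc) > 0) apply(qc, 2, stats::median)
           else apply(X, 2, stats::median)
    if (all(ref == 0)) stop("PQN reference spectrum is all zero")
    params$reference <- ref
    X <- pqn_normalize(X, ref)$normalized
  }
  if (method == "glog_vsn") {
    nz <- X[X > 0]
    params$lambda <- if (length(nz)) stats::median(nz) else 1
    X <- glog(X, params$lambda)
  }
  if (method == "log2_center") X <- log2(X + 1)
  params$mean <- colMeans(X)
  params$sd <- apply(X, 2, stats::sd)
  params$min <- apply(X, 2, min)
  params$max <- apply(X, 2, max)
  class(params) <- "scaling_params"
  params
}

glog <- function(x, lambda) log((x + sqrt(x^2 + lambda^2)) / 2)

#' Apply fitted scaling parameters to a table
#'
#' Transforms each row of `ft` using parameters estimated by [fit_scaling()].
#' Degenerate 0/0 columns (constant under autoscale/vast, zero mean under
#' level) map to 0, keeping the matrix finite. Pareto scaling divides the
#' centered value by the square root of the training standard deviation.
#'
#' @param ft a [feature_table()] with the same features as the fit.
#' @param params a `scaling_params` object.
#' @return A `feature_table` of scaled values (may be negative).
#' @export
apply_scaling <- function(ft, params) {
  stopifnot(inherits(params, "scaling_params"))
  if (!identical(ft$features$feature_id, params$feature_id))
    stop("feature set does not match scaling fit")
  X <- ft$intensities
  m <- params$method
  if (m == "pqn_pareto") X <- pqn_normalize(X, params$reference)$normalized
  if (m == "glog_vsn") X <- glog(X, params$lambda)
  if (m == "log2_center") X <- log2(X + 1)
  ctr <- sweep(X, 2, params$mean)
  safe_div <- function(num, den) {
    den[den == 0] <- Inf  # 0/0 convention: constant columns scale to 0
    sweep(num, 2, den, "/")
  }
  Z <- switch(m,
    mean_center = ctr,
    pareto = ,
    pqn_pareto = safe_div(ctr, sqrt(params$sd)),
    autoscale = safe_div(ctr, params$sd),
    range = safe_div(ctr, params$max - params$min),
    vast = {
      u <- safe_div(ctr, params$sd)
      f <- params$mean / params$sd
      f[!is.finite(f)] <- 0
      sweep(u, 2, f, "*")
    },
    level = safe_div(ctr, params$mean),
    glog_vsn = ,
    log2_center = ctr
  )
  out <- ft
  out$intensities <- Z
  # scaled tables carry negative values by design; skip the constructor's
  # non-negativity check but keep structure intact
  out
}

# inverse of apply_scaling on methods where it is defined; used by tests
invert_scaling <- function(Z, params) {
  m <- params$method
  unctr <- function(x) sweep(x, 2, params$mean, "+")
  X <- switch(m,
    mean_center = unctr(Z),
    pareto = unctr(sweep(Z, 2, sqrt(params$sd), "*")),
    autoscale = unctr(sweep(Z, 2, params$sd, "*")),
    range = unctr(sweep(Z, 2, params$max - params$min, "*")),
    level = unctr(sweep(Z, 2, params$mean, "*")),
    log2_center = 2^unctr(Z) - 1,
    glog_vsn = {
      y <- exp(unctr(Z))
      y - params$lambda^2 / (4 * y)
    },
    stop("no inverse for method ", m)
  )
  X
}

#' Probabilistic quotient normalization
#'
#' Estimates one dilution factor per row as the median of the quotients of the
#' row's intensities to a reference spectrum, taken over features where both
#' are positive, and divides the row by its factor. Multiplying a row by any
#' positive constant leaves its normalized row unchanged.
#'
#' @param x numeric matrix (rows = samples) or [feature_table()].
#' @param reference reference spectrum (length = number of features), e.g. the
#'   per-feature median of pooled-QC rows.
#' @return list with `normalized` (same shape as input) and `factors`
#'   (per-row dilution factors).
#' @export
pqn_normalize <- function(x, reference) {
  mat <- if (inherits(x, "feature_table")) x$intensities else as.matrix(x)
  if (length(reference) != ncol(mat)) stop("reference length != feature count")
  if (all(reference <= 0)) stop("reference spectrum is all zero")
  factors <- apply(mat, 1, function(row) {
    use <- reference > 0 & row > 0
    if (!any(use)) stop("sample has no positive overlap with reference")
    stats::median(row[use] / reference[use])
  })
  norm <- mat / factors
  if (inherits(x, "feature_table")) {
    out <- x
    out$intensities <- norm
    list(normalized = out, factors = factors)
  } else list(normalized = norm, factors = factors)
}

#' Composite score for a scaling method
#'
#' Weighted combination of model-quality statistics used to rank pretreatment
#' methods:
#' `0.15*R2X + 0.15*R2Y + 0.20*Q2 + 0.15*(1-RMSEE) + 0.30*(1-RMSEP) +
#'  0.01*acc_train + 0.02*acc_test + 0.02*acc_cv`.
#'
#' @param r2x,r2y,q2 explained-variance statistics of the fitted PLS-DA model.
#' @param rmsee,rmsep root-mean-square error of estimation (training) and
#'   prediction (test) on the class dummy variables.
#' @param acc_train,acc_test,acc_cv classification accuracies (fractions).
#' @return A list of class `scaling_score` with all components plus `score`.
#' @export
score_scaling_method <- function(r2x, r2y, q2, rmsee, rmsep,
                                 acc_train, acc_test, acc_cv) {
  comp <- list(r2x = r2x, r2y = r2y, q2 = q2, rmsee = rmsee, rmsep = rmsep,
               acc_train = acc_train, acc_test = acc_test, acc_cv = acc_cv)
  if (any(vapply(comp, function(v) is.null(v) || is.na(v), logical(1))))
    stop("missing score component")
  comp$score <- 0.15 * r2x + 0.15 * r2y + 0.20 * q2 + 0.15 * (1 - rmsee) +
    0.30 * (1 - rmsep) + 0.01 * acc_train + 0.02 * acc_test + 0.02 * acc_cv
  class(comp) <- "scaling_score"
  comp
}

#' Rank scaling methods by the composite score
#'
#' For each method: fit scaling parameters on the training rows, scale training
#' and test rows, fit a PLS-DA model, compute the model-quality components and
#' the composite score, and sort the methods by descending score.
#'
#' @param ft a [feature_table()] (QCs used for the PQN reference).
#' @param split a [kennard_stone()] split of the sample rows.
#' @param methods character vector of methods (default: all nine).
#' @param n_lv latent variables for the comparison model (default 3).
#' @param k cross-validation folds (default 5).
#' @param seed seed for the CV fold assignment.
#' @return data frame of methods and score components, sorted by score.
#' @export
rank_scalings <- function(ft, split, methods = SCALING_METHODS, n_lv = 3,
                          k = 5, seed = 1L) {
  rows <- lapply(methods, function(m) {
    sc <- scaled_split(ft, split, m)
    model <- fit_plsda(sc$X_train, sc$y_train, n_lv = n_lv)
    met <- compute_metrics(model, sc$X_train, sc$y_train, sc$X_test,
                           sc$y_test, k = k, seed = seed)
    s <- score_scaling_method(met$r2x, met$r2y, met$q2, met$rmsee, met$rmsep,
                              met$acc_train, met$acc_test, met$acc_cv)
    data.frame(method = m, score = s$score, r2x = s$r2x, r2y = s$r2y,
               q2 = s$q2, rmsee = s$rmsee, rmsep = s$rmsep,
               acc_train = s$acc_train, acc_test = s$acc_test,
               acc_cv = s$acc_cv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$score), , drop = FALSE]
}

# fit scaling on training rows, return scaled train/test matrices + labels
scaled_split <- function(ft, split, method) {
  samp <- subset_roles(ft, c("sample", "qc"))
  idx_train <- match(split$train_ids, samp$samples$sample_id)
  idx_test <- match(split$test_ids, samp$samples$sample_id)
  train_ft <- feature_table(samp$intensities[idx_train, , drop = FALSE],
                            samp$features, samp$samples[idx_train, , drop = FALSE])
  qc_rows <- which(samp$samples$role == "qc")
  fit_ft <- feature_table(
    samp$intensities[c(idx_train, qc_rows), , drop = FALSE], samp$features,
    samp$samples[c(idx_train, qc_rows), , drop = FALSE])
  params <- fit_scaling(fit_ft, method)
  test_ft <- feature_table(samp$intensities[idx_test, , drop = FALSE],
                           samp$features, samp$samples[idx_test, , drop = FALSE])
  list(
    X_train = apply_scaling(train_ft, params)$intensities,
    X_test = apply_scaling(test_ft, params)$intensities,
    y_train = train_ft$samples$class_label,
    y_test = test_ft$samples$class_label,
    params = params
  )
}
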