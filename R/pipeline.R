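#' Run the full authenticity workflow
#'
#' Orchestrates the stages in order: curation (blank-based feature removal,
#' duplicate merging) -> scaling-method choice (fixed method or composite-score
#' ranking with `scaling = "auto"`) -> Kennard-Stone division (distances on the
#' Pareto-scaled sample matrix) -> PLS-DA training (fixed or CV-selected
#' latent-variable count) -> validation (metrics, ROC, permutation test,
#' outlier diagnostics) -> VIP marker selection with pairwise OPLS-DA ->
#' optional candidate annotation of the markers -> optional suspect-set
#' classification. Every stochastic step is driven by `seed`; rerunning the
#' same configuration reproduces the result exactly.
#'
#' @param table a [feature_table()] with sample, QC and (optionally) blank
#'   rows.
#' @param suspect_table optional [feature_table()] of suspect rows.
#' @param candidates optional candidate data frame for [search_candidates()].
#' @param scaling a scaling method name, or `"auto"` to rank all methods by
#'   the composite score and use the best.
#' @param n_train training-set size for the Kennard-Stone split (or `NULL`
#'   with `train_frac`).
#' @param train_frac training fraction used when `n_train` is `NULL`
#'   (default 51/65).
#' @param n_lv latent variables, or `"auto"` for CV selection up to `max_lv`.
#' @param max_lv upper bound for `"auto"` selection (default 10).
#' @param k cross-validation folds (default 5).
#' @param vip_cutoff VIP marker threshold (default 0.83).
#' @param n_perm label permutations for the permutation test (default 20; 0
#'   skips the test).
#' @param blank_fold,mz_tol,rt_tol curation parameters (see
#'   [filter_blank_features()] and [merge_duplicates()]); blank filtering is
#'   skipped when the table has no blank rows.
#' @param seed integer seed for fold assignment and permutations.
#' @return list of class `pipeline_result` with the curated table, scaling
#'   ranking (when `"auto"`), split, model, metrics, ROC curves, permutation
#'   result, outlier diagnostics, VIP table, selected markers, pairwise VIPs,
#'   marker annotations, and suspect classification.
#' @export
run_pipeline <- function(table, suspect_table = NULL, candidates = NULL,
                         scaling = "pareto", n_train = NULL,
                         train_frac = 51 / 65, n_lv = 3, max_lv = 10, k = 5,
                         vip_cutoff = 0.83, n_perm = 20, blank_fold = 3,
                         mz_tol = 0.005, rt_tol = 0.1, seed = 1L) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  cur <- stage("curate", {
    t1 <- if (any(table$samples$role == "blank"))
      filter_blank_features(table, fold = blank_fold) else table
    merge_duplicates(t1, mz_tol = mz_tol, rt_tol = rt_tol)
  })
  susp <- if (!is.null(suspect_table)) stage("curate", {
    keep <- match(cur$features$feature_id, suspect_table$features$feature_id)
    if (anyNA(keep)) stop("suspect table lacks curated features")
    feature_table(suspect_table$intensities[, keep, drop = FALSE],
                  cur$features, suspect_table$samples)
  }) else NULL

  n_samp <- sum(cur$samples$role == "sample")
  if (is.null(n_train)) n_train <- round(train_frac * n_samp)

  split <- stage("split", {
    samp <- subset_roles(cur, "sample")
    pareto <- fit_scaling(samp, "pareto")
    kennard_stone(apply_scaling(samp, pareto)$intensities, n_train)
  })

  ranking <- NULL
  if (identical(scaling, "auto")) {
    ranking <- stage("scale", rank_scalings(cur, split, n_lv = if (is.numeric(n_lv)) n_lv else 3,
                                            k = k, seed = seed))
    scaling <- ranking$method[1]
  }
  sc <- stage("scale", scaled_split(cur, split, scaling))

  if (identical(n_lv, "auto")) {
    sel <- stage("train", select_n_lv(sc$X_train, sc$y_train, max_lv = max_lv,
                                      k = k, seed = seed))
    n_lv <- sel$n_lv
  }
  model <- stage("train", fit_plsda(sc$X_train, sc$y_train, n_lv = n_lv))

  metrics <- stage("validate", compute_metrics(model, sc$X_train, sc$y_train,
                                               sc$X_test, sc$y_test,
                                               k = k, seed = seed))
  all_X <- rbind(sc$X_train, sc$X_test)
  all_y <- c(sc$y_train, sc$y_test)
  roc <- stage("validate", roc_curves(predict(model, all_X)$prob, all_y))
  perm <- if (n_perm > 0)
    stage("validate", permutation_test(sc$X_train, sc$y_train, n_lv = n_lv,
                                       n_perm = n_perm, k = k, seed = seed))
    else NULL
  diagnostics <- stage("validate", outlier_diagnostics(model, sc$X_train))

  vip_tab <- stage("markers", vip(model))
  markers <- stage("markers", select_markers(vip_tab, cutoff = vip_cutoff))
  pairwise <- stage("markers", pairwise_oplsda_vip(sc$X_train, sc$y_train))

  annotations <- if (!is.null(candidates) && nrow(markers)) stage("annotate", {
    idx <- match(markers$feature, cur$features$feature_id)
    res <- lapply(seq_len(nrow(markers)), function(i) {
      hits <- search_candidates(cur$features$mz[idx[i]],
                                cur$features$rt[idx[i]], candidates)
      if (nrow(hits)) cbind(feature = markers$feature[i], hits[1, ],
                            stringsAsFactors = FALSE) else NULL
    })
    do.call(rbind, res)
  }) else NULL

  suspects <- if (!is.null(susp))
    stage("suspects", classify_suspects(model, sc$params, susp,
                                        X_train = sc$X_train))
    else NULL

  structure(list(
    curated = cur, scaling = scaling, ranking = ranking, split = split,
    n_lv = n_lv, model = model, metrics = metrics, roc = roc,
    permutation = perm, diagnostics = diagnostics, vip = vip_tab,
    markers = markers, pairwise_vip = pairwise, annotations = annotations,
    suspects = suspects, seed = seed
  ), class = "pipeline_result")
}
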