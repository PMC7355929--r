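#' Model quality statistics for a fitted PLS-DA model
#'
#' Computes the standard chemometric validation battery: `r2x` (cumulative
#' fraction of X variance captured by the score/loading reconstruction), `r2y`
#' (goodness of fit on the training dummy matrix), `q2` (cross-validated
#' `1 - PRESS/SS`), `rmsee`/`rmsep` (root-mean-square dummy residual on the
#' training/test set), total error rates and per-class sensitivity and
#' specificity from the confusion matrices.
#'
#' @param model a fitted [fit_plsda()] model.
#' @param X_train,y_train training matrix and labels the model was fitted on.
#' @param X_test,y_test independent test matrix and labels.
#' @param k cross-validation folds for `q2` and the CV error (default 5).
#' @param seed fold-assignment seed.
#' @return list of class `model_metrics`.
#' @export
compute_metrics <- function(model, X_train, y_train, X_test, y_test,
                            k = 5, seed = 1L) {
  if (!length(y_test)) stop("empty test set")
  classes <- model$class_map
  Y <- dummy_matrix(as.character(y_train), classes)
  Yc <- sweep(Y, 2, colMeans(Y))
  pred_tr <- predict(model, X_train)
  res_tr <- Y - pred_tr$dummy
  r2y <- 1 - sum(res_tr^2) / sum(Yc^2)
  r2x <- 1 - model$ss_x_residual / model$ss_x_total
  rmsee <- sqrt(mean(res_tr^2))

  Y_te <- dummy_matrix(as.character(y_test), classes)
  pred_te <- predict(model, X_test)
  rmsep <- sqrt(mean((Y_te - pred_te$dummy)^2))

  folds <- stratified_folds(y_train, k, seed)
  press <- 0
  cv_wrong <- 0
  for (f in unique(folds)) {
    hold <- folds == f
    m <- fit_plsda(X_train[!hold, , drop = FALSE], y_train[!hold], model$n_lv)
    pr <- predict(m, X_train[hold, , drop = FALSE])
    press <- press + sum((dummy_matrix(as.character(y_train[hold]), classes) -
                            pr$dummy)^2)
    cv_wrong <- cv_wrong + sum(pr$class != y_train[hold])
  }
  q2 <- 1 - press / sum(Yc^2)

  cm_tr <- confusion(y_train, pred_tr$class, classes)
  cm_te <- confusion(y_test, pred_te$class, classes)
  structure(list(
    r2x = r2x, r2y = r2y, q2 = q2, rmsee = rmsee, rmsep = rmsep,
    error_train = 1 - sum(diag(cm_tr)) / sum(cm_tr),
    error_test = 1 - sum(diag(cm_te)) / sum(cm_te),
    error_cv = cv_wrong / length(y_train),
    acc_train = sum(diag(cm_tr)) / sum(cm_tr),
    acc_test = sum(diag(cm_te)) / sum(cm_te),
    acc_cv = 1 - cv_wrong / length(y_train),
    confusion_train = cm_tr, confusion_test = cm_te,
    sensitivity = class_sensitivity(cm_te),
    specificity = class_specificity(cm_te)
  ), class = "model_metrics")
}

confusion <- function(truth, pred, classes) {
  table(factor(truth, classes), factor(pred, classes), dnn = c("truth", "pred"))
}

class_sensitivity <- function(cm) diag(cm) / pmax(rowSums(cm), 1)

class_specificity <- function(cm) {
  vapply(seq_len(nrow(cm)), function(i) {
    tn <- sum(cm[-i, -i]); fp <- sum(cm[-i, i])
    if (tn + fp == 0) return(1)
    tn / (tn + fp)
  }, numeric(1), USE.NAMES = FALSE) |> stats::setNames(rownames(cm))
}

#' One-vs-rest ROC curves and AUC
#'
#' Sweeps a threshold over each class's assigned probability (one class
#' against the rest), recording `(100 - specificity, sensitivity)` points, and
#' integrates the area under the curve by the trapezoid rule. The threshold
#' grid is the set of unique scores extended by +/- infinity.
#'
#' @param probabilities matrix of class probabilities, rows summing to 1,
#'   columns named by class.
#' @param labels true class labels.
#' @return named list of per-class lists with `points` (data frame
#'   `fpr_percent`, `sensitivity`) and `auc`.
#' @export
roc_curves <- function(probabilities, labels) {
  classes <- colnames(probabilities)
  labels <- as.character(labels)
  missing_cls <- setdiff(classes, labels)
  if (length(missing_cls))
    stop("class absent from labels: ", paste(missing_cls, collapse = ", "))
  out <- lapply(classes, function(cl) {
    score <- probabilities[, cl]
    pos <- labels == cl
    thr <- c(Inf, sort(unique(score), decreasing = TRUE), -Inf)
    sens <- vapply(thr, function(t) mean(score[pos] >= t), numeric(1))
    spec <- vapply(thr, function(t) mean(score[!pos] < t), numeric(1))
    fpr <- 1 - spec
    auc <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
    list(points = data.frame(fpr_percent = 100 * fpr, sensitivity = sens),
         auc = auc)
  })
  stats::setNames(out, classes)
}

#' Permutation test of R2Y and Q2
#'
#' Refits the model and its cross-validation under `n_perm` uniformly random
#' permutations of the class labels; a well-determined model shows observed
#' Q2 far above every permuted Q2. The empirical p-value uses the add-one
#' estimator `(1 + #{perm q2 >= observed}) / (n_perm + 1)`.
#'
#' @param X scaled feature matrix.
#' @param labels class labels.
#' @param n_lv latent variables.
#' @param n_perm number of permutations (default 20).
#' @param k CV folds (default 5).
#' @param seed seed for permutation draws and fold assignment.
#' @return list of class `permutation_result` with `observed_q2`,
#'   `observed_r2y`, `permuted_q2`, `permuted_r2y`, `p_value`.
#' @export
permutation_test <- function(X, labels, n_lv, n_perm = 20, k = 5, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  obs <- fit_q2_r2y(X, labels, n_lv, k, seed)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  perm <- replicate(n_perm, {
    lp <- sample(labels)
    unlist(fit_q2_r2y(X, lp, n_lv, k, seed))
  })
  p_value <- (1 + sum(perm["q2", ] >= obs$q2)) / (n_perm + 1)
  structure(list(observed_q2 = obs$q2, observed_r2y = obs$r2y,
                 permuted_q2 = unname(perm["q2", ]),
                 permuted_r2y = unname(perm["r2y", ]),
                 n_perm = n_perm, p_value = p_value),
            class = "permutation_result")
}

# R2Y and k-fold Q2 for a label assignment; folds are stratified when every
# class has >= k members, otherwise unstratified (permuted labels can starve
# a fold)
fit_q2_r2y <- function(X, labels, n_lv, k, seed) {
  classes <- sort(unique(as.character(labels)))
  model <- fit_plsda(X, labels, n_lv)
  Y <- dummy_matrix(as.character(labels), classes)
  Yc <- sweep(Y, 2, colMeans(Y))
  r2y <- 1 - sum((Y - predict(model, X)$dummy)^2) / sum(Yc^2)
  counts <- table(labels)
  folds <- if (all(counts >= k)) stratified_folds(labels, k, seed) else {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    sample(rep_len(seq_len(k), length(labels)))
  }
  press <- 0
  for (f in unique(folds)) {
    hold <- folds == f
    if (length(unique(labels[!hold])) < 2) { press <- Inf; break }
    m <- fit_plsda(X[!hold, , drop = FALSE], labels[!hold], n_lv)
    pr <- predict(m, X[hold, , drop = FALSE])$dummy
    press <- press + sum((Y[hold, colnames(pr), drop = FALSE] - pr)^2)
  }
  list(q2 = 1 - press / sum(Yc^2), r2y = r2y)
}

#' Hotelling's T2 and Q-residual outlier diagnostics
#'
#' For each row: `T2 = sum_a t_a^2 / var(t_a)` (score variances from the
#' training scores) and `Q = ||x_c - t P'||^2` (squared reconstruction
#' residual). The 95% T2 limit is `A(n-1)/(n-A) * F_0.95(A, n-A)`; the 95% Q
#' limit uses the Jackson-Mudholkar approximation from the eigenvalues of the
#' training residual covariance.
#'
#' @param model a fitted [fit_plsda()] model.
#' @param X rows to diagnose (same feature space as training).
#' @param X_train training matrix (for the residual eigenvalues of the Q
#'   limit); defaults to the model's stored scores/residual statistics being
#'   recomputed from `X` — pass the training matrix for calibrated limits.
#' @return list of class `outlier_diagnostics` with per-row `t2`, `q`,
#'   `t2_limit_95`, `q_limit_95`, and logical `outlier` (both limits
#'   exceeded).
#' @export
outlier_diagnostics <- function(model, X, X_train = NULL) {
  A <- model$n_lv
  n <- nrow(model$T)
  if (A >= n) stop("A must be < n for the T2 limit")
  score_var <- apply(model$T, 2, stats::var)
  Xc <- sweep(as.matrix(X), 2, model$x_mean)
  Tn <- Xc %*% model$Wstar
  t2 <- rowSums(sweep(Tn^2, 2, score_var, "/"))
  resid <- Xc - Tn %*% t(model$P)
  q <- rowSums(resid^2)

  t2_lim <- A * (n - 1) / (n - A) * stats::qf(0.95, A, n - A)

  if (is.null(X_train)) {
    resid_train <- resid
  } else {
    Xtc <- sweep(as.matrix(X_train), 2, model$x_mean)
    resid_train <- Xtc - (Xtc %*% model$Wstar) %*% t(model$P)
  }
  ev <- svd(resid_train, nu = 0, nv = 0)$d^2 / (nrow(resid_train) - 1)
  ev <- ev[ev > max(ev) * 1e-12]
  th1 <- sum(ev); th2 <- sum(ev^2); th3 <- sum(ev^3)
  q_lim <- if (th1 == 0) 0 else {
    h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
    if (h0 < 1e-3) h0 <- 1e-3
    ca <- stats::qnorm(0.95)
    th1 * (ca * sqrt(2 * th2 * h0^2) / th1 + 1 +
             th2 * h0 * (h0 - 1) / th1^2)^(1 / h0)
  }
  structure(list(t2 = t2, q = q, t2_limit_95 = t2_lim, q_limit_95 = q_lim,
                 outlier = t2 > t2_lim & q > q_lim),
            class = "outlier_diagnostics")
}

#' Classify suspect samples through a fitted pipeline
#'
#' Scales the suspect rows with the training scaling parameters, predicts
#' their classes, and flags rows falling outside the model's 95% T2/Q limits.
#'
#' @param model a fitted [fit_plsda()] model.
#' @param params training [fit_scaling()] parameters.
#' @param suspect_table a [feature_table()] of suspect rows.
#' @param X_train scaled training matrix (for the Q-limit calibration).
#' @return list with `class`, `prob`, `diagnostics`, `flagged`.
#' @export
classify_suspects <- function(model, params, suspect_table, X_train = NULL) {
  Xs <- apply_scaling(suspect_table, params)$intensities
  pred <- predict(model, Xs)
  diag <- outlier_diagnostics(model, Xs, X_train = X_train)
  list(class = pred$class, prob = pred$prob, diagnostics = diag,
       flagged = diag$outlier)
}
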