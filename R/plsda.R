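#' Fit a PLS-DA model by NIPALS
#'
#' Partial least squares discriminant analysis: NIPALS PLS2 regression of a
#' one-hot class dummy matrix on the (scaled) feature matrix. X and Y are
#' mean-centered internally; after each component both blocks are deflated.
#' Convergence tolerance 1e-10, at most 500 iterations per component.
#'
#' @param X numeric matrix, samples x features (already scaled as desired).
#' @param labels character/factor class labels, length `nrow(X)`; at least two
#'   classes.
#' @param n_lv number of latent variables (>= 1, <= rank of X).
#' @return An object of class `plsda` with weights `W` (p x A), loadings `P`
#'   (p x A), scores `T` (n x A), Y-loadings `C` (q x A), `class_map` (ordered
#'   class labels), centering vectors, per-component explained Y sum of
#'   squares `ssy`, and regression coefficients `B`.
#' @export
fit_plsda <- function(X, labels, n_lv) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need >= 2 classes")
  if (n_lv < 1) stop("n_lv must be >= 1")
  Y <- dummy_matrix(labels, classes)
  x_mean <- colMeans(X)
  y_mean <- colMeans(Y)
  E <- sweep(X, 2, x_mean)
  F <- sweep(Y, 2, y_mean)
  n <- nrow(E); p <- ncol(E); q <- ncol(F)
  if (n_lv > min(n - 1, p)) stop("n_lv exceeds matrix rank bound")
  feat <- colnames(X)
  W <- matrix(0, p, n_lv, dimnames = list(feat, NULL))
  P <- matrix(0, p, n_lv, dimnames = list(feat, NULL))
  Tm <- matrix(0, n, n_lv); C <- matrix(0, q, n_lv)
  ssy <- numeric(n_lv)
  for (a in seq_len(n_lv)) {
    u <- F[, which.max(apply(F, 2, stats::var)), drop = TRUE]
    t_old <- rep(0, n)
    for (it in seq_len(500)) {
      w <- drop(crossprod(E, u))
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14) break  # X fully deflated
      w <- w / nw
      tt <- drop(E %*% w)
      cc <- drop(crossprod(F, tt)) / sum(tt^2)
      u <- drop(F %*% cc) / sum(cc^2)
      if (sqrt(sum((tt - t_old)^2)) < 1e-10 * max(sqrt(sum(tt^2)), 1e-300)) {
        t_old <- tt; break
      }
      t_old <- tt
    }
    tt <- t_old
    if (sum(tt^2) < 1e-28) { W <- W[, seq_len(a - 1), drop = FALSE]
      P <- P[, seq_len(a - 1), drop = FALSE]
      Tm <- Tm[, seq_len(a - 1), drop = FALSE]
      C <- C[, seq_len(a - 1), drop = FALSE]
      ssy <- ssy[seq_len(a - 1)]
      n_lv <- a - 1L
      break }
    pp <- drop(crossprod(E, tt)) / sum(tt^2)
    cc <- drop(crossprod(F, tt)) / sum(tt^2)
    ss_before <- sum(F^2)
    E <- E - tcrossprod(tt, pp)
    F <- F - tcrossprod(tt, cc)
    ssy[a] <- ss_before - sum(F^2)  # Y sum of squares explained by component a
    W[, a] <- w; P[, a] <- pp; Tm[, a] <- tt; C[, a] <- cc
  }
  if (n_lv == 0) stop("no usable components (X has no variance)")
  # W* maps X directly onto scores: T = Xc W (P'W)^-1
  Wstar <- W %*% solve(crossprod(P, W))
  B <- Wstar %*% t(C)
  structure(list(
    n_lv = n_lv, W = W, P = P, T = Tm, C = C, Wstar = Wstar, B = B,
    class_map = classes, x_mean = x_mean, y_mean = y_mean, ssy = ssy,
    ss_x_total = sum(sweep(X, 2, x_mean)^2),
    ss_x_residual = sum(E^2),
    training_ids = rownames(X)
  ), class = "plsda")
}

dummy_matrix <- function(labels, classes) {
  Y <- matrix(0, length(labels), length(classes),
              dimnames = list(NULL, classes))
  Y[cbind(seq_along(labels), match(labels, classes))] <- 1
  Y
}

#' Predict classes from a PLS-DA model
#'
#' Projects new rows into the model and converts the predicted dummy values to
#' class assignments (argmax; ties resolved to the first class in the model's
#' class order) and class probabilities.
#'
#' @param object a fitted [fit_plsda()] model.
#' @param X matrix with the same feature count as the training data.
#' @param prob one of `"softmax"` (default; softmax of the predicted dummy
#'   values) or `"clip"` (dummy values clipped to `[0, 1]` and renormalized).
#' @param ... unused.
#' @return list with `dummy` (n x q predicted dummy matrix), `class`
#'   (character assignments) and `prob` (rows sum to 1).
#' @export
predict.plsda <- function(object, X, prob = c("softmax", "clip"), ...) {
  prob <- match.arg(prob)
  X <- as.matrix(X)
  if (ncol(X) != length(object$x_mean)) stop("feature count mismatch")
  Yhat <- sweep(X, 2, object$x_mean) %*% object$B
  Yhat <- sweep(Yhat, 2, object$y_mean, "+")
  colnames(Yhat) <- object$class_map
  cls <- object$class_map[max.col(Yhat, ties.method = "first")]
  P <- if (prob == "softmax") {
    e <- exp(Yhat - apply(Yhat, 1, max))
    e / rowSums(e)
  } else {
    cl <- pmin(pmax(Yhat, 0), 1)
    rs <- rowSums(cl)
    bad <- rs == 0
    if (any(bad)) cl[bad, ] <- 1 / ncol(cl)
    cl / rowSums(cl)
  }
  list(dummy = Yhat, class = cls, prob = P)
}

#' Cross-validated selection of the number of latent variables
#'
#' Stratified k-fold cross-validation of the misclassification error for each
#' candidate component count; returns the smallest count attaining the minimal
#' mean error (ties favour the smaller model). `k = n` gives leave-one-out.
#'
#' @param X scaled feature matrix.
#' @param labels class labels.
#' @param max_lv largest component count to try.
#' @param k folds (default 5); every class must have at least `k` members
#'   unless `k == n`.
#' @param seed seed controlling the fold assignment.
#' @return list with `n_lv` and `cv_error` (mean misclassification per A).
#' @export
select_n_lv <- function(X, labels, max_lv, k = 5, seed = 1L) {
  folds <- stratified_folds(labels, k, seed)
  err <- vapply(seq_len(max_lv), function(a) {
    cv_misclassification(X, labels, a, folds)
  }, numeric(1))
  list(n_lv = which.min(err), cv_error = err)
}

# stratified fold ids; k = n gives leave-one-out
stratified_folds <- function(labels, k, seed) {
  n <- length(labels)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k exceeds sample count")
  fold <- integer(n)
  if (k == n) return(seq_len(n))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      stop("class '", cl, "' has fewer members (", length(idx),
           ") than folds (", k, ")")
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

cv_misclassification <- function(X, labels, n_lv, folds) {
  wrong <- 0
  for (f in unique(folds)) {
    hold <- folds == f
    m <- fit_plsda(X[!hold, , drop = FALSE], labels[!hold], n_lv)
    pred <- predict(m, X[hold, , drop = FALSE])$class
    wrong <- wrong + sum(pred != labels[hold])
  }
  wrong / length(labels)
}

#' Variable importance in projection
#'
#' Wold VIP scores:
#' `VIP_j = sqrt(p * sum_a SSY_a (w_aj / ||w_a||)^2 / sum_a SSY_a)` with
#' `SSY_a` the Y sum of squares explained by component a. The mean of the
#' squared VIPs over all features is exactly 1.
#'
#' @param model a fitted [fit_plsda()] model.
#' @return data frame with `feature` (column name or index) and `vip`.
#' @export
vip <- function(model) {
  W <- model$W
  p <- nrow(W)
  wn <- sweep(W, 2, sqrt(colSums(W^2)), "/")^2
  v <- sqrt(p * drop(wn %*% model$ssy) / sum(model$ssy))
  feat <- rownames(W)
  if (is.null(feat)) feat <- as.character(seq_len(p))
  data.frame(feature = feat, vip = v, stringsAsFactors = FALSE)
}

#' Select marker features by VIP cutoff
#'
#' @param vip_records data frame with columns `feature` and `vip`
#'   (see [vip()]).
#' @param cutoff threshold; features with `vip > cutoff` (strict) are kept.
#' @return The selected rows, sorted by descending VIP.
#' @export
select_markers <- function(vip_records, cutoff = 0.83) {
  sel <- vip_records[vip_records$vip > cutoff, , drop = FALSE]
  sel[order(-sel$vip), , drop = FALSE]
}

#' Pairwise OPLS-DA VIP values
#'
#' For each (ordered) pair of classes the rows of the two classes are
#' extracted, one orthogonal component is removed (orthogonal signal
#' correction), a single predictive PLS component is fitted to the binary
#' dummy, and VIP values are computed on that predictive component. A marker
#' elevated only in class A scores high in both pairs containing A and low in
#' the remaining pair.
#'
#' @param X scaled feature matrix.
#' @param labels class labels.
#' @param class_pairs list of length-2 character vectors; default all
#'   unordered pairs in sorted class order.
#' @return data frame with one `vip_<A>_vs_<B>` column per pair plus
#'   `feature`.
#' @export
pairwise_oplsda_vip <- function(X, labels, class_pairs = NULL) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (is.null(class_pairs)) {
    class_pairs <- utils::combn(classes, 2, simplify = FALSE)
  }
  feat <- colnames(X)
  if (is.null(feat)) feat <- as.character(seq_len(ncol(X)))
  out <- data.frame(feature = feat, stringsAsFactors = FALSE)
  for (pr in class_pairs) {
    keep <- labels %in% pr
    if (!all(pr %in% labels)) stop("pair class absent from labels")
    fit <- oplsda_binary(X[keep, , drop = FALSE], labels[keep], pr)
    out[[paste0("vip_", pr[1], "_vs_", pr[2])]] <- fit$vip
  }
  out
}

# two-class OPLS: remove one orthogonal component, fit one predictive
# component, return its VIP profile and scores
oplsda_binary <- function(X, labels, pr) {
  y <- ifelse(labels == pr[1], 1, 0)
  E <- sweep(X, 2, colMeans(X))
  f <- y - mean(y)
  w <- drop(crossprod(E, f)); w <- w / sqrt(sum(w^2))
  tt <- drop(E %*% w)
  p_load <- drop(crossprod(E, tt)) / sum(tt^2)
  w_orth <- p_load - drop(crossprod(w, p_load)) * w
  n_orth <- sqrt(sum(w_orth^2))
  if (n_orth > 1e-12) {
    w_orth <- w_orth / n_orth
    t_orth <- drop(E %*% w_orth)
    p_orth <- drop(crossprod(E, t_orth)) / sum(t_orth^2)
    E <- E - tcrossprod(t_orth, p_orth)
  } else {
    t_orth <- rep(0, nrow(E))
  }
  # predictive component on the OSC-filtered block
  w2 <- drop(crossprod(E, f)); w2 <- w2 / sqrt(sum(w2^2))
  t2 <- drop(E %*% w2)
  p <- length(w2)
  vip1 <- sqrt(p) * abs(w2)  # single component: SSY weights cancel
  list(vip = vip1, scores = t2, orth_scores = t_orth, weights = w2)
}
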