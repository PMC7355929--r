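sep_toy <- function(n = 10) {
  # two classes perfectly separated along the first variable
  x <- cbind(c(rnorm(n, -4, 0.3), rnorm(n, 4, 0.3)), matrix(rnorm(2 * n * 3), 2 * n))
  list(X = x, y = rep(c("A", "B"), each = n))
}

test_that("first NIPALS component matches the singular-vector oracle", {
  set.seed(20)
  X <- matrix(rnorm(24), 6, 4)
  y <- c("A", "A", "B", "B", "C", "C")
  m <- fit_plsda(X, y, n_lv = 2)
  Xc <- scale(X, scale = FALSE)
  Y <- oliveauth:::dummy_matrix(y, sort(unique(y)))
  Yc <- scale(Y, scale = FALSE)
  sv <- svd(crossprod(Xc, Yc))
  w_oracle <- sv$u[, 1]
  align <- sign(sum(w_oracle * m$W[, 1]))
  expect_equal(unname(m$W[, 1]), align * w_oracle, tolerance = 1e-6)
  expect_equal(unname(m$T[, 1]), drop(Xc %*% (align * w_oracle)),
               tolerance = 1e-6)
})

test_that("a separable one-variable problem is solved with one component", {
  set.seed(21)
  toy <- sep_toy()
  m <- fit_plsda(toy$X, toy$y, n_lv = 1)
  pred <- predict(m, toy$X)
  expect_equal(pred$class, toy$y)
  expect_equal(unname(rowSums(pred$prob)), rep(1, 20), tolerance = 1e-9)
  sel <- select_n_lv(toy$X, toy$y, max_lv = 4, k = 5, seed = 1)
  expect_equal(sel$n_lv, 1)
  expect_equal(sel$cv_error[1], 0)
})

test_that("degenerate fits are rejected", {
  set.seed(22)
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_plsda(X, rep("A", 10), 1), "classes")
  expect_error(fit_plsda(X, rep(c("A", "B"), 5), 0), "n_lv")
  expect_error(fit_plsda(X, rep(c("A", "B"), 5), 5), "rank")
  expect_error(select_n_lv(X, c(rep("A", 8), "B", "B"), max_lv = 2, k = 5,
                           seed = 1), "fewer members")
})

test_that("training R2Y is non-decreasing in the component count", {
  set.seed(23)
  X <- matrix(rnorm(30 * 12), 30)
  y <- rep(c("A", "B", "C"), each = 10)
  r2y <- vapply(1:5, function(a) {
    m <- fit_plsda(X, y, a)
    Y <- oliveauth:::dummy_matrix(y, m$class_map)
    1 - sum((Y - predict(m, X)$dummy)^2) / sum(scale(Y, scale = FALSE)^2)
  }, numeric(1))
  expect_true(all(diff(r2y) > -1e-10))
})

test_that("random labels on noise overfit: R2Y > 0 but CV Q2 near or below zero", {
  set.seed(24)
  X <- matrix(rnorm(24 * 30), 24)
  y <- sample(rep(c("A", "B"), each = 12))
  res <- oliveauth:::fit_q2_r2y(X, y, n_lv = 3, k = 4, seed = 1)
  expect_gt(res$r2y, 0)
  expect_lt(res$q2, 0.2)
  expect_lt(res$q2, res$r2y)
})

test_that("VIP normalization: mean squared VIP is one for any model", {
  expect_equal(mean(vip(fit_plsda(matrix(c(1, 2, 3, 7, 8, 9), ncol = 1),
                                  rep(c("A", "B"), each = 3), 1))$vip^2), 1)
  set.seed(25)
  for (rep_i in 1:5) {
    X <- matrix(rnorm(20 * 15), 20)
    y <- sample(rep(c("A", "B", "C"), length.out = 20))
    m <- fit_plsda(X, y, sample(1:4, 1))
    expect_equal(mean(vip(m)$vip^2), 1, tolerance = 1e-6)
  }
})

test_that("equal weights across features give unit VIPs", {
  # p copies of the same informative variable: symmetric weights
  set.seed(26)
  base <- c(rnorm(6, -2, 0.1), rnorm(6, 2, 0.1))
  X <- matrix(rep(base, 4), ncol = 4)
  m <- fit_plsda(X, rep(c("A", "B"), each = 6), 1)
  expect_equal(unname(vip(m)$vip), rep(1, 4), tolerance = 1e-8)
})

test_that("predictions are invariant to feature reordering", {
  set.seed(27)
  toy <- sep_toy()
  colnames(toy$X) <- paste0("F", 1:4)
  m1 <- fit_plsda(toy$X, toy$y, 2)
  perm <- c(3, 1, 4, 2)
  m2 <- fit_plsda(toy$X[, perm], toy$y, 2)
  expect_equal(predict(m1, toy$X)$dummy, predict(m2, toy$X[, perm])$dummy,
               tolerance = 1e-9)
})

test_that("marker selection uses a strict cutoff and sorts by VIP", {
  rec <- data.frame(feature = c("a", "b", "c"), vip = c(0.5, 0.83, 0.84))
  sel <- select_markers(rec, 0.83)
  expect_equal(sel$feature, "c")
  expect_equal(nrow(select_markers(rec[0, ], 0.83)), 0)
})

test_that("OPLS orthogonal scores are uncorrelated with the predictive scores", {
  set.seed(28)
  X <- matrix(rnorm(30 * 20), 30)
  X[, 1] <- X[, 1] + rep(c(-2, 2), each = 15)       # predictive direction
  X[, 2] <- X[, 2] + rnorm(30, 0, 3)                # strong orthogonal noise
  y <- rep(c("A", "B"), each = 15)
  fit <- oliveauth:::oplsda_binary(X, y, c("A", "B"))
  expect_lt(abs(cor(fit$scores, fit$orth_scores)), 1e-6)
})

test_that("pairwise VIPs isolate each marker's own class pairs", {
  b <- small_bundle(seed = 31L)
  mp <- modelling_path(b, n_train = 19, n_lv = 3)
  pw <- pairwise_oplsda_vip(mp$X_train, mp$y_train)
  pairs <- setdiff(names(pw), "feature")
  for (cls in c("Greece", "Egypt", "Chile")) {
    own <- grep(cls, pairs, value = TRUE)
    third <- setdiff(pairs, own)
    rows <- pw[pw$feature %in% truth_marker_ids(b, cls), ]
    expect_true(all(as.matrix(rows[, own]) > 0.83))
    expect_true(all(rows[[third]] < apply(as.matrix(rows[, own]), 1, min)))
  }
  expect_error(pairwise_oplsda_vip(mp$X_train, mp$y_train,
                                   list(c("Greece", "Mars"))), "absent")
})

test_that("PCA explains rank-structure and clusters as constructed", {
  r1 <- matrix(1:4, 4) %*% t(c(2, 1, 3))
  pc <- fit_pca(r1, 1)
  expect_equal(pc$explained[1], 1)
  # two clusters displaced along one axis: PC1 separates them
  set.seed(29)
  x <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
             sweep(matrix(rnorm(40, 0, 0.1), 20, 2), 2, c(5, 0), "+"))
  pc2 <- fit_pca(x, 2)
  expect_true(all(diff(pc2$explained) <= 0))
  s1 <- pc2$scores[1:20, 1]; s2 <- pc2$scores[21:40, 1]
  expect_true(max(s1) < min(s2) || min(s1) > max(s2))
})

test_that("QC rows cluster tighter than biological samples in PCA score space", {
  b <- small_bundle(seed = 37L)
  keep <- b$table$samples$role %in% c("sample", "qc")
  lt <- log1p(b$table$intensities[keep, ])
  pc <- fit_pca(lt, 2)
  spread <- function(rows) mean(dist(pc$scores[rows, ]))
  expect_lt(spread(b$table$samples$role[keep] == "qc"),
            spread(b$table$samples$role[keep] == "sample"))
})
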