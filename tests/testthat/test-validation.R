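test_that("trapezoid AUC equals the Mann-Whitney oracle", {
  set.seed(40)
  for (i in 1:10) {
    n <- 30
    labels <- sample(rep(c("pos", "neg"), c(12, 18)))
    prob_pos <- runif(n)
    if (i %% 2 == 0) prob_pos <- round(prob_pos, 1)  # force ties
    probs <- cbind(pos = prob_pos, neg = 1 - prob_pos)
    roc <- roc_curves(probs, labels)
    expect_equal(roc$pos$auc,
                 mann_whitney_auc(prob_pos, labels == "pos"),
                 tolerance = 1e-9)
  }
})

test_that("ROC endpoints, symmetry, and separation behave canonically", {
  labels <- rep(c("pos", "neg"), each = 10)
  perfect <- cbind(pos = c(runif(10, 0.8, 1), runif(10, 0, 0.2)))
  perfect <- cbind(perfect, neg = 1 - perfect[, 1])
  roc <- roc_curves(perfect, labels)
  expect_equal(roc$pos$auc, 1)
  expect_true(any(roc$pos$points$fpr_percent == 0 &
                    roc$pos$points$sensitivity == 1))
  inv <- cbind(pos = 1 - perfect[, "pos"], neg = perfect[, "pos"])
  expect_equal(roc_curves(inv, labels)$pos$auc, 0)
  set.seed(41)
  rnd <- runif(200)
  aucs <- roc_curves(cbind(pos = rnd, neg = 1 - rnd),
                     sample(rep(c("pos", "neg"), 100)))$pos$auc
  expect_lt(abs(aucs - 0.5), 0.15)
  expect_error(roc_curves(perfect, rep("pos", 20)), "absent")
})

test_that("an exactly linear dummy response gives R2Y = 1 and RMSEE = 0", {
  X <- cbind(c(0, 0, 1, 1), c(0, 1, 0, 1))
  y <- c("A", "A", "B", "B")
  m <- fit_plsda(X, y, 2)
  met <- compute_metrics(m, X, y, X, y, k = 2, seed = 1)
  expect_equal(met$r2y, 1, tolerance = 1e-9)
  expect_equal(met$rmsee, 0, tolerance = 1e-9)
  expect_equal(met$error_train, 0)
  expect_equal(unname(rowSums(met$confusion_test)), c(2, 2))
  expect_equal(met$error_test, 1 - sum(diag(met$confusion_test)) /
                 sum(met$confusion_test))
})

test_that("Q2 does not exceed R2Y on the seeded synthetic bundle", {
  b <- small_bundle(seed = 43L)
  mp <- modelling_path(b, n_train = 19, n_lv = 2)
  met <- compute_metrics(mp$model, mp$X_train, mp$y_train, mp$X_test,
                         mp$y_test, k = 3, seed = 1)
  expect_lte(met$q2, met$r2y)
  expect_gt(met$q2, 0.5)
})

test_that("permutation test separates a real model from label noise", {
  b <- small_bundle(seed = 47L)
  mp <- modelling_path(b, n_train = 19, n_lv = 2)
  pt <- permutation_test(mp$X_train, mp$y_train, n_lv = 2, n_perm = 10,
                         k = 3, seed = 5)
  expect_length(pt$permuted_q2, 10)
  expect_true(all(pt$permuted_q2 < pt$observed_q2))
  expect_equal(pt$p_value, 1 / 11)
  pt1 <- permutation_test(mp$X_train, mp$y_train, n_lv = 2, n_perm = 1,
                          k = 3, seed = 5)
  expect_length(pt1$permuted_q2, 1)
})

test_that("permutation p-values are roughly uniform under the null", {
  set.seed(48)
  pvals <- replicate(30, {
    X <- matrix(rnorm(12 * 5), 12)
    y <- rep(c("A", "B"), each = 6)
    permutation_test(X, y, n_lv = 1, n_perm = 9, k = 3,
                     seed = sample.int(1e6, 1))$p_value
  })
  expect_gt(mean(pvals), 0.3)
  expect_lt(mean(pvals), 0.8)
  expect_gt(length(unique(pvals)), 3)
})

test_that("T2 and Q vanish at the model center and plane; outliers exceed limits", {
  set.seed(49)
  X <- matrix(rnorm(30 * 8), 30)
  y <- rep(c("A", "B", "C"), each = 10)
  m <- fit_plsda(X, y, 2)
  center <- matrix(m$x_mean, 1)
  dc <- outlier_diagnostics(m, center, X_train = X)
  expect_equal(dc$t2, 0, tolerance = 1e-18, ignore_attr = TRUE)
  # a point inside the model plane: reconstruct from its own scores
  t_pt <- matrix(c(2, -1), 1)
  in_plane <- t_pt %*% t(m$P) + rep(m$x_mean, each = 1)
  dp <- outlier_diagnostics(m, in_plane, X_train = X)
  expect_lt(dp$q, 1e-16)
})

test_that("a grossly inflated sample exceeds both 95% limits", {
  b <- small_bundle(seed = 53L)
  mp <- modelling_path(b, n_train = 19, n_lv = 2)
  bad <- mp$X_test[1, , drop = FALSE] * 10
  d <- outlier_diagnostics(mp$model, rbind(mp$X_train, bad),
                           X_train = mp$X_train)
  n_tr <- nrow(mp$X_train)
  expect_gt(d$t2[n_tr + 1], d$t2_limit_95)
  expect_gt(d$q[n_tr + 1], d$q_limit_95)
  expect_true(d$outlier[n_tr + 1])
  # training rows are mostly inside their own 95% limits
  expect_lt(mean(d$outlier[seq_len(n_tr)]), 0.2)
})

test_that("suspect classification follows the training pipeline", {
  b <- small_bundle(seed = 59L)
  mp <- modelling_path(b, n_train = 19, n_lv = 3)
  res <- classify_suspects(mp$model, mp$params, b$suspect_table,
                           X_train = mp$X_train)
  expect_true(all(res$class == "Greece"))
  # a suspect identical to a training sample gets that sample's assignment
  tr_id <- mp$split$train_ids[1]
  samp <- subset_roles(b$table, "sample")
  row <- samp$intensities[samp$samples$sample_id == tr_id, , drop = FALSE]
  clone <- feature_table(row, samp$features,
                         data.frame(sample_id = "clone", role = "suspect",
                                    class_label = NA))
  pred_clone <- classify_suspects(mp$model, mp$params, clone,
                                  X_train = mp$X_train)
  tr_pred <- predict(mp$model, mp$X_train)$class
  expect_equal(pred_clone$class,
               tr_pred[match(tr_id, mp$split$train_ids)])
  # a suspect drawn from another class's generative model is not called Greece
  other <- subset_roles(b$table, "sample")
  egy <- other$intensities[other$samples$class_label == "Egypt", , drop = FALSE][1, , drop = FALSE]
  fake <- feature_table(egy, other$features,
                        data.frame(sample_id = "fake", role = "suspect",
                                   class_label = NA))
  expect_false(classify_suspects(mp$model, mp$params, fake,
                                 X_train = mp$X_train)$class == "Greece")
})
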