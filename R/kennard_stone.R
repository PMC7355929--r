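#' Kennard-Stone division into training and test sets
#'
#' Deterministic space-filling selection of a training subset using Euclidean
#' distances. The canonical max-min algorithm (`variant = "maxmin"`) seeds the
#' training set with the two mutually farthest samples and then repeatedly
#' adds the sample whose minimum distance to the current training set is
#' largest, until `n_train` samples are selected; the remainder is the test
#' set. Ties are broken by the lowest sample index, so the split is fully
#' deterministic given the input order.
#'
#' The `"alternating"` variant instead assigns successive farthest pairs
#' alternately to the training and test sets, yielding a near 50/50 division;
#' it is provided for completeness, the max-min variant is the default used by
#' the workflow.
#'
#' @param x numeric matrix (rows = samples) or a [feature_table()]; when a
#'   feature table is given, only rows with role `sample` are split. Distances
#'   are computed on the matrix as supplied — scale it first if the analysis
#'   scales before splitting.
#' @param n_train number of training samples, `2 <= n_train <= n`.
#' @param variant `"maxmin"` (default) or `"alternating"`.
#' @return A list of class `ks_split` with `train_ids` and `test_ids`
#'   (sample ids when a feature table was supplied, otherwise row indices as
#'   character), `train_idx` and `test_idx` (integer row indices).
#' @export
kennard_stone <- function(x, n_train, variant = c("maxmin", "alternating")) {
  variant <- match.arg(variant)
  if (inherits(x, "feature_table")) {
    keep <- x$samples$role == "sample"
    mat <- x$intensities[keep, , drop = FALSE]
    ids <- x$samples$sample_id[keep]
  } else {
    mat <- as.matrix(x)
    ids <- rownames(mat)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(mat)))
  }
  n <- nrow(mat)
  if (n_train < 2 || n_train > n) stop("n_train out of range [2, n]")
  d <- as.matrix(stats::dist(mat))

  if (variant == "maxmin") {
    seed_pair <- which(d == max(d), arr.ind = TRUE)
    seed_pair <- seed_pair[order(seed_pair[, 1], seed_pair[, 2]), , drop = FALSE]
    train <- sort(unname(seed_pair[1, ]))
    while (length(train) < n_train) {
      rest <- setdiff(seq_len(n), train)
      mind <- apply(d[rest, train, drop = FALSE], 1, min)
      train <- c(train, rest[which.max(mind)])  # which.max: lowest index on ties
    }
  } else {
    # alternating farthest-pair assignment: odd pairs to train, even to test
    remaining <- seq_len(n)
    train <- integer(0); test <- integer(0); to_train <- TRUE
    while (length(remaining) > 1) {
      dd <- d[remaining, remaining, drop = FALSE]
      pr <- which(dd == max(dd), arr.ind = TRUE)
      pr <- pr[order(pr[, 1], pr[, 2]), , drop = FALSE][1, ]
      pair <- sort(remaining[pr])
      if (to_train) train <- c(train, pair) else test <- c(test, pair)
      to_train <- !to_train
      remaining <- setdiff(remaining, pair)
    }
    if (length(remaining)) {
      if (to_train) train <- c(train, remaining) else test <- c(test, remaining)
    }
  }
  test <- setdiff(seq_len(n), train)
  structure(list(train_ids = ids[train], test_ids = ids[test],
                 train_idx = train, test_idx = test),
            class = "ks_split")
}
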