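#' Principal component analysis of a feature matrix
#'
#' Thin wrapper around [stats::prcomp()] (mean-centered, unscaled) returning
#' scores, loadings and per-component explained-variance fractions; used for
#' exploratory inspection of samples, QCs and blanks before supervised
#' modelling.
#'
#' @param x numeric matrix (rows = samples) or [feature_table()] (all rows
#'   used).
#' @param n_components number of components to keep
#'   (`<= min(nrow - 1, ncol)`).
#' @return list of class `pca_result` with `scores`, `loadings`,
#'   `explained` (fractions, non-increasing) and `center`.
#' @export
fit_pca <- function(x, n_components) {
  mat <- if (inherits(x, "feature_table")) x$intensities else as.matrix(x)
  if (!nrow(mat) || !ncol(mat)) stop("empty matrix")
  if (n_components > min(nrow(mat) - 1, ncol(mat)))
    stop("n_components exceeds matrix rank bound")
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  keep <- seq_len(n_components)
  structure(list(scores = pc$x[, keep, drop = FALSE],
                 loadings = pc$rotation[, keep, drop = FALSE],
                 explained = expl[keep],
                 center = pc$center),
            class = "pca_result")
}
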