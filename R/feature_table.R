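#' Construct a feature table
#'
#' The central container of the workflow: an aligned samples-by-features
#' intensity matrix with per-feature m/z and retention-time descriptors and
#' per-sample role/class metadata, as produced by LC-MS peak picking and
#' alignment.
#'
#' @param intensities numeric matrix, one row per sample, one column per
#'   feature; no negative entries.
#' @param features data frame with columns `feature_id` (unique character),
#'   `mz` (Da, > 0) and `rt` (min, >= 0), one row per matrix column.
#' @param samples data frame with columns `sample_id` (unique character),
#'   `role` (one of `"sample"`, `"qc"`, `"blank"`, `"suspect"`) and
#'   `class_label` (character or `NA`; required for `role == "sample"`,
#'   must be `NA` for QCs and blanks), one row per matrix row.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(intensities, features, samples) {
  intensities <- as.matrix(intensities)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!"class_label" %in% names(samples)) samples$class_label <- NA_character_
  samples$class_label <- as.character(samples$class_label)
  ft <- structure(
    list(intensities = intensities, features = features, samples = samples),
    class = "feature_table"
  )
  validate_feature_table(ft)
  dimnames(ft$intensities) <- list(samples$sample_id, features$feature_id)
  ft
}

validate_feature_table <- function(ft) {
  stopifnot(is.matrix(ft$intensities), is.numeric(ft$intensities))
  if (nrow(ft$intensities) != nrow(ft$samples))
    stop("intensity rows (", nrow(ft$intensities), ") != sample records (",
         nrow(ft$samples), ")")
  if (ncol(ft$intensities) != nrow(ft$features))
    stop("intensity columns (", ncol(ft$intensities), ") != feature records (",
         nrow(ft$features), ")")
  if (anyNA(ft$intensities) || any(ft$intensities < 0))
    stop("intensities must be non-negative and non-missing")
  if (anyDuplicated(ft$features$feature_id))
    stop("duplicate feature_id")
  if (anyDuplicated(ft$samples$sample_id))
    stop("duplicate sample_id")
  if (any(!is.na(ft$features$mz) & ft$features$mz <= 0))
    stop("feature m/z must be > 0")
  if (any(!is.na(ft$features$rt) & ft$features$rt < 0))
    stop("feature rt must be >= 0")
  bad_role <- setdiff(unique(ft$samples$role), c("sample", "qc", "blank", "suspect"))
  if (length(bad_role))
    stop("unknown sample role: ", paste(bad_role, collapse = ", "))
  need_class <- ft$samples$role == "sample"
  if (any(need_class & is.na(ft$samples$class_label)))
    stop("role 'sample' requires a class_label")
  if (any(ft$samples$role %in% c("qc", "blank") & !is.na(ft$samples$class_label)))
    stop("QCs and blanks must not carry a class_label")
  invisible(ft)
}

#' @export
print.feature_table <- function(x, ...) {
  tab <- table(x$samples$role)
  cat("feature_table: ", nrow(x$samples), " rows x ", nrow(x$features),
      " features\n  roles: ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n", sep = "")
  cls <- x$samples$class_label[x$samples$role == "sample"]
  if (length(cls)) {
    ct <- table(cls)
    cat("  classes: ", paste(sprintf("%s=%d", names(ct), ct), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Subset the rows of a feature table by role
#'
#' @param ft a [feature_table()].
#' @param roles character vector of roles to keep.
#' @return A `feature_table` with only the requested rows.
#' @export
subset_roles <- function(ft, roles) {
  keep <- ft$samples$role %in% roles
  feature_table(ft$intensities[keep, , drop = FALSE], ft$features,
                ft$samples[keep, , drop = FALSE])
}

#' Read / write a feature table as CSV
#'
#' The on-disk layout is one header row of feature ids preceded by the three
#' metadata columns (`sample_id`, `role`, `class_label`), then two descriptor
#' rows (tagged `#mz` and `#rt` in the `sample_id` column) holding the feature
#' m/z and retention times, then one row per sample. UTF-8, comma separated,
#' period decimal. `read_table(write_table(t))` round-trips exactly.
#'
#' @param path file path.
#' @return `read_table` returns a [feature_table()]; `write_table` returns
#'   `path` invisibly.
#' @export
read_table <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 4) stop("expected sample_id, role, class_label + features")
  if (!identical(names(raw)[1:3], c("sample_id", "role", "class_label")))
    stop("first three columns must be sample_id, role, class_label")
  if (!identical(raw$sample_id[1:2], c("#mz", "#rt")))
    stop("rows 1-2 must be the #mz and #rt descriptor rows")
  fid <- names(raw)[-(1:3)]
  num <- function(v) as.numeric(v)
  features <- data.frame(
    feature_id = fid,
    mz = num(unlist(raw[1, -(1:3)], use.names = FALSE)),
    rt = num(unlist(raw[2, -(1:3)], use.names = FALSE)),
    stringsAsFactors = FALSE
  )
  body <- raw[-(1:2), , drop = FALSE]
  samples <- data.frame(
    sample_id = body$sample_id,
    role = body$role,
    class_label = ifelse(body$class_label == "", NA_character_, body$class_label),
    stringsAsFactors = FALSE
  )
  mat <- as.matrix(as.data.frame(lapply(body[, -(1:3), drop = FALSE], num)))
  colnames(mat) <- fid
  feature_table(mat, features, samples)
}

#' @rdname read_table
#' @param ft a [feature_table()] to write.
#' @export
write_table <- function(ft, path) {
  validate_feature_table(ft)
  meta <- data.frame(
    sample_id = c("#mz", "#rt", ft$samples$sample_id),
    role = c("", "", ft$samples$role),
    class_label = c("", "", ifelse(is.na(ft$samples$class_label), "",
                                   ft$samples$class_label)),
    stringsAsFactors = FALSE
  )
  vals <- rbind(ft$features$mz, ft$features$rt, ft$intensities)
  out <- cbind(meta, as.data.frame(vals, optional = TRUE))
  names(out) <- c("sample_id", "role", "class_label", ft$features$feature_id)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Remove features dominated by the procedural blank
#'
#' A feature is kept only when its mean intensity across biological samples is
#' at least `fold` times its mean intensity across procedural blanks; features
#' absent from the blanks (blank mean 0) are always kept. The blank rows are
#' dropped from the returned table. The operation is idempotent.
#'
#' @param ft a [feature_table()] containing at least one blank row.
#' @param fold sample/blank mean-intensity ratio below which a feature is
#'   discarded (default 3).
#' @return A curated `feature_table` without blank rows.
#' @export
filter_blank_features <- function(ft, fold = 3.0) {
  is_blank <- ft$samples$role == "blank"
  if (!any(is_blank)) stop("no blank rows present")
  is_sample <- ft$samples$role == "sample"
  sm <- colMeans(ft$intensities[is_sample, , drop = FALSE])
  bm <- colMeans(ft$intensities[is_blank, , drop = FALSE])
  keep <- sm >= fold * bm
  feature_table(ft$intensities[!is_blank, keep, drop = FALSE],
                ft$features[keep, , drop = FALSE],
                ft$samples[!is_blank, , drop = FALSE])
}

#' Merge near-duplicate features
#'
#' Features closer than `mz_tol` in m/z and `rt_tol` in retention time are
#' grouped by single linkage; each group is replaced by its member with the
#' highest mean intensity (ties broken by ascending m/z, then feature order).
#' Retained intensity values are never altered, columns are only dropped.
#'
#' @param ft a [feature_table()].
#' @param mz_tol m/z tolerance in Da (default 0.005).
#' @param rt_tol retention-time tolerance in min (default 0.1).
#' @return A `feature_table` with duplicates collapsed.
#' @export
merge_duplicates <- function(ft, mz_tol = 0.005, rt_tol = 0.1) {
  if (mz_tol < 0 || rt_tol < 0) stop("tolerances must be non-negative")
  p <- nrow(ft$features)
  if (p < 2) return(ft)
  ord <- order(ft$features$mz, seq_len(p))
  mz <- ft$features$mz[ord]
  rt <- ft$features$rt[ord]
  # union-find over pairs within both tolerances; candidates found by scanning
  # the m/z-sorted order so the pass is near-linear for well-spread tables
  parent <- seq_len(p)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(p - 1L)) {
    j <- i + 1L
    while (j <= p && mz[j] - mz[i] <= mz_tol) {
      if (abs(rt[j] - rt[i]) <= rt_tol) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
      j <- j + 1L
    }
  }
  root <- vapply(seq_len(p), find, integer(1))
  means <- colMeans(ft$intensities[ft$samples$role %in% c("sample", "suspect"),
                                   ord, drop = FALSE])
  if (all(is.na(means)) || !length(means))
    means <- colMeans(ft$intensities[, ord, drop = FALSE])
  keep_sorted <- vapply(split(seq_len(p), root), function(grp) {
    grp[order(-means[grp], mz[grp], grp)][1]
  }, integer(1))
  keep <- sort(ord[keep_sorted])
  feature_table(ft$intensities[, keep, drop = FALSE],
                ft$features[keep, , drop = FALSE],
                ft$samples)
}
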