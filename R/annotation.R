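#' @title Compound annotation ladder
#' @description Formula mass arithmetic, deprotonated-ion m/z, mass errors,
#'   isotope-pattern simulation and fit, MS/MS similarity, candidate search
#'   with retention-time plausibility, and tiered identification-confidence
#'   assignment for negative-mode HRMS marker identification.
#' @name annotation
NULL

# IUPAC/CODATA isotope masses (Da) and natural abundances, pinned here so the
# arithmetic is bit-stable across platforms
ISOTOPES <- list(
  C  = data.frame(mass = c(12.0, 13.00335484), abundance = c(0.9893, 0.0107)),
  H  = data.frame(mass = c(1.00782503207, 2.01410177785),
                  abundance = c(0.999885, 0.000115)),
  N  = data.frame(mass = c(14.00307400486, 15.00010889894),
                  abundance = c(0.99636, 0.00364)),
  O  = data.frame(mass = c(15.99491461956, 16.99913170, 17.99916107),
                  abundance = c(0.99757, 0.00038, 0.00205)),
  P  = data.frame(mass = 30.97376163, abundance = 1.0),
  S  = data.frame(mass = c(31.97207100, 32.97145876, 33.96786690, 35.96708076),
                  abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  Na = data.frame(mass = 22.98976928, abundance = 1.0),
  Cl = data.frame(mass = c(34.96885268, 36.96590259),
                  abundance = c(0.7576, 0.2424)),
  K  = data.frame(mass = c(38.96370668, 39.96399848, 40.96182576),
                  abundance = c(0.932581, 0.000117, 0.067302))
)

PROTON_MASS <- 1.00727646

#' Parse a molecular formula
#'
#' @param formula character like `"C6H6O2"` or a named integer vector; element
#'   symbols limited to C, H, N, O, P, S, Na, Cl, K.
#' @return named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula)) {
    counts <- formula
  } else {
    stopifnot(is.character(formula), length(formula) == 1, nzchar(formula))
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
    toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
    if (sum(nchar(toks)) != nchar(formula))
      stop("cannot parse formula: ", formula)
    el <- sub("[0-9]*$", "", toks)
    nn <- as.integer(ifelse(sub("^[A-Z][a-z]?", "", toks) == "", "1",
                            sub("^[A-Z][a-z]?", "", toks)))
    tt <- tapply(nn, el, sum)
    counts <- stats::setNames(as.integer(tt), names(tt))
  }
  bad <- setdiff(names(counts), names(ISOTOPES))
  if (length(bad)) stop("unknown element: ", paste(bad, collapse = ", "))
  counts <- counts[counts > 0]
  if (!length(counts)) stop("empty formula")
  storage.mode(counts) <- "integer"
  counts
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of most-abundant-isotope masses (12C exactly 12 Da by definition).
#'
#' @param formula formula string or named count vector (see
#'   [parse_formula()]).
#' @return mass in Da.
#' @export
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  mono <- vapply(names(counts), function(el) {
    iso <- ISOTOPES[[el]]
    iso$mass[which.max(iso$abundance)]
  }, numeric(1))
  sum(mono * counts)
}

#' m/z of the deprotonated molecular ion [M-H]-
#'
#' @param formula formula containing at least one hydrogen.
#' @return monoisotopic mass minus one proton mass (1.00727646 Da).
#' @export
mz_deprotonated <- function(formula) {
  counts <- parse_formula(formula)
  if (is.na(counts["H"]) || counts["H"] < 1)
    stop("no hydrogen to remove for [M-H]-")
  monoisotopic_mass(counts) - PROTON_MASS
}

#' Mass error between theoretical and observed m/z
#'
#' Sign convention: `mDa = (theoretical - observed) * 1000`, so an observed
#' mass above theory gives a negative error (e.g. theory 109.0295 vs observed
#' 109.0299 is -0.4 mDa).
#'
#' @param theoretical,observed m/z in Da, both positive.
#' @return list with `mda` and `ppm`.
#' @export
mass_error <- function(theoretical, observed) {
  stopifnot(theoretical > 0, observed > 0)
  mda <- (theoretical - observed) * 1000
  list(mda = mda, ppm = mda * 1000 / theoretical)
}

#' Theoretical isotope pattern of a formula
#'
#' Full polynomial expansion over natural isotope abundances by repeated
#' convolution across atoms; isotopologue peaks closer than 1 mDa are
#' aggregated (abundance-weighted centroid), abundances are normalized to a
#' base peak of 100 and truncated at `abundance_threshold` (percent).
#'
#' @param formula formula string or named count vector.
#' @param abundance_threshold minimum relative abundance kept, in percent of
#'   the base peak (default 0.01).
#' @return data frame of class `isotope_pattern` with `mz` (sorted) and
#'   `abundance` (max = 100).
#' @export
isotope_pattern <- function(formula, abundance_threshold = 0.01) {
  counts <- parse_formula(formula)
  dist <- data.frame(mz = 0, prob = 1)
  for (el in names(counts)) {
    iso <- ISOTOPES[[el]]
    atom <- data.frame(mz = iso$mass, prob = iso$abundance)
    k <- counts[[el]]
    # distribution of k atoms by binary exponentiation of the convolution
    acc <- NULL
    while (k > 0) {
      if (k %% 2 == 1) acc <- if (is.null(acc)) atom else convolve_iso(acc, atom)
      k <- k %/% 2
      if (k > 0) atom <- convolve_iso(atom, atom)
    }
    dist <- convolve_iso(dist, acc)
  }
  dist <- aggregate_peaks(dist, 0.001)
  dist <- dist[order(dist$mz), ]
  ab <- 100 * dist$prob / max(dist$prob)
  keep <- ab >= abundance_threshold
  out <- data.frame(mz = dist$mz[keep], abundance = ab[keep])
  class(out) <- c("isotope_pattern", "data.frame")
  out
}

convolve_iso <- function(a, b, prune = 1e-12) {
  mz <- outer(a$mz, b$mz, "+")
  pr <- outer(a$prob, b$prob)
  d <- data.frame(mz = as.vector(mz), prob = as.vector(pr))
  d <- aggregate_peaks(d, 0.0005)
  d[d$prob > prune, , drop = FALSE]
}

# merge peaks within tol Da into abundance-weighted centroids
aggregate_peaks <- function(d, tol) {
  d <- d[order(d$mz), , drop = FALSE]
  grp <- cumsum(c(1, diff(d$mz) > tol))
  data.frame(
    mz = vapply(split(seq_len(nrow(d)), grp), function(i)
      sum(d$mz[i] * d$prob[i]) / sum(d$prob[i]), numeric(1)),
    prob = vapply(split(d$prob, grp), sum, numeric(1))
  )
}

#' Isotope-pattern fit score
#'
#' Matches theoretical and observed peaks within 5 mDa and scores
#' `1000 * (1 - cosine similarity)` over the aligned abundance vectors, with
#' unmatched peaks on either side entering as zeros. 0 means identical
#' patterns; disjoint patterns give 1000. Conventional acceptance threshold:
#' score < 100.
#'
#' @param theoretical,observed [isotope_pattern()]-like data frames with `mz`
#'   and `abundance`.
#' @param tol match tolerance in Da (default 0.005).
#' @return numeric score in `[0, 1000]`.
#' @export
isotope_fit <- function(theoretical, observed, tol = 0.005) {
  if (!nrow(theoretical) || !nrow(observed)) stop("empty pattern")
  al <- align_peaks(theoretical$mz, theoretical$abundance,
                    observed$mz, observed$abundance, tol)
  cs <- sum(al$a * al$b) / (sqrt(sum(al$a^2)) * sqrt(sum(al$b^2)))
  1000 * (1 - cs)
}

# greedy nearest-m/z alignment of two peak lists; returns aligned intensity
# vectors over the union of peaks (unmatched -> 0 on the other side)
align_peaks <- function(mz_a, int_a, mz_b, int_b, tol) {
  used_b <- rep(FALSE, length(mz_b))
  match_of <- rep(NA_integer_, length(mz_a))
  for (i in order(-int_a)) {  # most intense first: deterministic greedy
    dm <- abs(mz_b - mz_a[i])
    dm[used_b] <- Inf
    j <- which.min(dm)
    if (length(j) && dm[j] <= tol) { match_of[i] <- j; used_b[j] <- TRUE }
  }
  a <- c(int_a, rep(0, sum(!used_b)))
  b <- c(ifelse(is.na(match_of), 0, int_b[match_of]), int_b[!used_b])
  list(a = a, b = b, n_matched = sum(!is.na(match_of)))
}

#' MS/MS spectral similarity
#'
#' Greedy highest-intensity-first peak matching within `tol`, then the cosine
#' of the square-root-intensity-weighted aligned vectors (unmatched peaks
#' count as zeros). Symmetric and bounded in `[0, 1]`.
#'
#' @param a,b spectra: data frames / matrices with columns `mz` and
#'   `intensity`, or 2-column matrices.
#' @param tol fragment match tolerance in Da (default 0.01).
#' @return list with `score` (cosine) and `n_matched`.
#' @export
msms_similarity <- function(a, b, tol = 0.01) {
  if (tol < 0) stop("negative tolerance")
  a <- as_spectrum(a); b <- as_spectrum(b)
  if (!nrow(a) || !nrow(b)) stop("empty spectrum")
  al <- align_peaks(a$mz, sqrt(a$intensity), b$mz, sqrt(b$intensity), tol)
  denom <- sqrt(sum(al$a^2)) * sqrt(sum(al$b^2))
  score <- if (denom == 0) 0 else sum(al$a * al$b) / denom
  list(score = score, n_matched = al$n_matched)
}

as_spectrum <- function(x) {
  x <- as.data.frame(x)
  if (ncol(x) < 2) stop("spectrum needs mz and intensity columns")
  if (!all(c("mz", "intensity") %in% names(x))) names(x)[1:2] <- c("mz", "intensity")
  if (any(x$intensity < 0)) stop("negative intensity")
  x[, c("mz", "intensity")]
}

#' Search a candidate list for an observed feature
#'
#' Retains candidates whose deprotonated theoretical m/z lies within `mz_tol`
#' (strict) of the observed m/z; candidates with a predicted retention time
#' are dropped when `|rt error| >= rt_max_err`. Survivors are ranked by
#' absolute mass error, then by isotope fit when an observed pattern is given.
#'
#' @param observed_mz observed m/z in Da.
#' @param rt observed retention time in min (may be `NA`).
#' @param candidates data frame with columns `name`, `formula`, optional
#'   `predicted_rt`.
#' @param mz_tol mass tolerance in Da (default 0.005 = 5 mDa).
#' @param rt_max_err maximum allowed |rt error| in min (default 1.8).
#' @param observed_pattern optional observed isotope pattern for fit scoring.
#' @return data frame of ranked candidate annotations with `name`, `formula`,
#'   `theoretical_mz`, `mass_error_mda`, `ppm`, `rt_error_min`, `isotope_fit`.
#' @export
search_candidates <- function(observed_mz, rt, candidates, mz_tol = 0.005,
                              rt_max_err = 1.8, observed_pattern = NULL) {
  if (!nrow(candidates)) stop("candidate list is empty")
  theo <- vapply(candidates$formula, mz_deprotonated, numeric(1),
                 USE.NAMES = FALSE)
  err <- vapply(theo, function(t) mass_error(t, observed_mz)$mda, numeric(1))
  keep <- abs(err) < mz_tol * 1000
  res <- data.frame(
    name = candidates$name[keep], formula = candidates$formula[keep],
    theoretical_mz = theo[keep], mass_error_mda = err[keep],
    ppm = err[keep] * 1000 / theo[keep],
    stringsAsFactors = FALSE
  )
  res$rt_error_min <- if (!is.null(candidates$predicted_rt) && !is.na(rt))
    rt - candidates$predicted_rt[keep] else rep(NA_real_, nrow(res))
  drop_rt <- !is.na(res$rt_error_min) & abs(res$rt_error_min) >= rt_max_err
  res <- res[!drop_rt, , drop = FALSE]
  res$isotope_fit <- rep(NA_real_, nrow(res))
  if (!is.null(observed_pattern) && nrow(res)) {
    res$isotope_fit <- vapply(res$formula, function(f)
      isotope_fit(isotope_pattern(f), observed_pattern), numeric(1),
      USE.NAMES = FALSE)
    res <- res[order(abs(res$mass_error_mda), res$isotope_fit), , drop = FALSE]
  } else if (nrow(res)) {
    res <- res[order(abs(res$mass_error_mda)), , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

#' Read a candidate compound list from CSV
#'
#' Expected columns: `name`, `formula`, optional `predicted_rt` (min) and
#' optional `msms` — a semicolon-separated reference fragment list, either
#' bare m/z values (`"109.0295;91.0189"`) or `mz:intensity` pairs
#' (`"109.0295:100;91.0189:25"`). Parsed spectra are attached as a list column
#' `msms_spectrum` (data frames with `mz`, `intensity`; intensity `NA` when
#' the library gives none).
#'
#' @param path CSV file path.
#' @return data frame of candidates.
#' @export
read_candidates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "formula") %in% names(df)))
    stop("candidate CSV needs name and formula columns")
  if ("msms" %in% names(df)) {
    df$msms_spectrum <- lapply(df$msms, function(s) {
      if (is.na(s) || !nzchar(s)) return(NULL)
      parts <- strsplit(strsplit(s, ";")[[1]], ":")
      data.frame(
        mz = as.numeric(vapply(parts, `[`, "", 1)),
        intensity = vapply(parts, function(p)
          if (length(p) > 1) as.numeric(p[2]) else NA_real_, numeric(1))
      )
    })
  }
  df
}

#' Assign an identification confidence level
#'
#' Tiered confidence ladder for HRMS identification: 1 = confirmed by
#' reference standard; 2a = library MS/MS match (cosine >= 0.7, or >= 3
#' matched fragments when the library spectrum has no intensities); 2b =
#' library evidence that cannot distinguish isomers; 3 = literature/in-silico
#' MS/MS or retention-time prioritization only; 4 = unequivocal formula from
#' exact mass plus isotope fit (< 100) only; 5 = exact mass only.
#'
#' @param reference_standard candidate confirmed against an authentic
#'   standard.
#' @param msms_score library MS/MS cosine score (`NA` if unavailable).
#' @param n_matched_fragments matched fragment count against a library
#'   spectrum without intensities (`NA` if not applicable).
#' @param isomer_indistinguishable library evidence matches an isomer set
#'   rather than a unique structure.
#' @param insilico_or_rt_only evidence limited to in-silico fragmentation,
#'   literature spectra, or retention-time prioritization.
#' @param isotope_fit isotope fit score (`NA` if not computed).
#' @param formula_assigned a unique molecular formula was assigned.
#' @return one of `"1"`, `"2a"`, `"2b"`, `"3"`, `"4"`, `"5"`.
#' @export
assign_level <- function(reference_standard = FALSE,
                         msms_score = NA_real_,
                         n_matched_fragments = NA_integer_,
                         isomer_indistinguishable = FALSE,
                         insilico_or_rt_only = FALSE,
                         isotope_fit = NA_real_,
                         formula_assigned = FALSE) {
  if (reference_standard && !formula_assigned &&
      is.na(msms_score) && is.na(n_matched_fragments))
    stop("reference-standard flag without any candidate evidence")
  if (reference_standard) return("1")
  library_match <- (!is.na(msms_score) && msms_score >= 0.7) ||
    (is.na(msms_score) && !is.na(n_matched_fragments) &&
       n_matched_fragments >= 3)
  if (library_match) return(if (isomer_indistinguishable) "2b" else "2a")
  if (insilico_or_rt_only) return("3")
  if (formula_assigned && !is.na(isotope_fit) && isotope_fit < 100) return("4")
  "5"
}
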