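test_that("formula parsing and monoisotopic masses are exact", {
  expect_equal(monoisotopic_mass("C"), 12)
  expect_equal(monoisotopic_mass("H2O"), 18.01056, tolerance = 1e-5)
  expect_equal(monoisotopic_mass("C6H6O2"), 110.03678, tolerance = 1e-5)
  expect_equal(parse_formula("C6H6O2"), c(C = 6L, H = 6L, O = 2L),
               ignore_attr = FALSE)
  expect_error(parse_formula("C6Xx2"), "unknown element|parse")
  expect_error(monoisotopic_mass("Zz"), "unknown element|parse")
  expect_error(mz_deprotonated("C2O4"), "hydrogen")
})

test_that("all 26 marker [M-H]- m/z values reproduce at 4 decimal places", {
  for (i in seq_len(nrow(MARKER_MZ))) {
    expect_lt(abs(mz_deprotonated(MARKER_MZ$formula[i]) - MARKER_MZ$mz[i]),
              5e-5)
  }
})

test_that("deprotonation is exactly one proton below the neutral mass", {
  for (f in c("C6H6O2", "C25H32O13", "C18H34O2", "H2O")) {
    expect_equal(mz_deprotonated(f) + 1.00727646, monoisotopic_mass(f),
                 tolerance = 1e-12)
  }
})

test_that("mass errors follow the theoretical-minus-observed convention", {
  err <- mass_error(mz_deprotonated("C6H6O2"), 109.0299)
  expect_equal(round(err$mda, 1), -0.4)
  expect_equal(mass_error(100, 100), list(mda = 0, ppm = 0))
  err2 <- mass_error(100.0000, 99.9990)
  expect_equal(err2$mda, 1.0, tolerance = 1e-9)
  expect_equal(err2$ppm, 10, tolerance = 1e-9)
})

test_that("isotope patterns match the brute-force multinomial oracle", {
  for (f in c("C", "C6H6O2", "C4H6O5", "Cl2")) {
    oracle <- isotope_oracle(f)
    expect_equal(sum(oracle$prob), 1, tolerance = 1e-9)  # probability mass
    pat <- isotope_pattern(f, abundance_threshold = 0)
    mono <- monoisotopic_mass(f)
    for (offset in c(0, 1, 2)) {
      oracle_ab <- oracle_cluster_abundance(oracle, mono, offset)
      pat_ab <- sum(pat$abundance[abs(pat$mz - (mono + offset)) < 0.25])
      if (oracle_ab > 0.01)
        expect_equal(pat_ab, oracle_ab, tolerance = 1e-6,
                     info = paste(f, "A +", offset))
    }
  }
})

test_that("single-carbon and catechol isotope abundances are canonical", {
  pc <- isotope_pattern("C")
  expect_equal(pc$mz, c(12, 13.00335484), tolerance = 1e-7)
  expect_equal(pc$abundance[2], 100 * 0.0107 / 0.9893, tolerance = 1e-4)
  cat_pat <- isotope_pattern("C6H6O2")
  # dominant A+1 peak (13C + 17O, unresolved at 1 mDa): ~6.5% of base;
  # frozen from the brute-force multinomial oracle
  a1 <- sum(cat_pat$abundance[abs(cat_pat$mz - 111.0401) < 0.002])
  expect_equal(a1, 6.5656, tolerance = 1e-3)
  expect_equal(nrow(isotope_pattern("C6H6O2", abundance_threshold = 100)), 1)
})

test_that("the isotope fit score maps cosine distance onto 0..1000", {
  pat <- isotope_pattern("C6H6O2")
  expect_equal(isotope_fit(pat, pat), 0, tolerance = 1e-9)
  disjoint <- data.frame(mz = pat$mz + 0.5, abundance = pat$abundance)
  expect_equal(isotope_fit(pat, disjoint), 1000)
  # observed pattern missing all isotopologues: closed-form cosine of
  # (100, a) vs (100, 0)
  two <- data.frame(mz = c(100, 101.00336), abundance = c(100, 8))
  base_only <- data.frame(mz = 100, abundance = 100)
  expected <- 1000 * (1 - 100 / sqrt(100^2 + 8^2))
  expect_equal(isotope_fit(two, base_only), expected, tolerance = 1e-9)
  bigger <- data.frame(mz = c(100, 101.00336), abundance = c(100, 20))
  expect_gt(isotope_fit(bigger, base_only), isotope_fit(two, base_only))
})

test_that("MS/MS similarity is an identity-normalized symmetric cosine", {
  catechol <- data.frame(
    mz = c(65.0033, 81.0346, 91.0189, 108.0217, 109.0295),
    intensity = c(40, 100, 25, 60, 80))
  self <- msms_similarity(catechol, catechol)
  expect_equal(self$score, 1, tolerance = 1e-12)
  expect_equal(self$n_matched, 5)
  far <- data.frame(mz = catechol$mz + 0.5, intensity = catechol$intensity)
  expect_equal(msms_similarity(catechol, far), list(score = 0, n_matched = 0))
  set.seed(60)
  for (i in 1:5) {
    a <- data.frame(mz = runif(6, 50, 500), intensity = rexp(6))
    b <- data.frame(mz = runif(4, 50, 500), intensity = rexp(4))
    ab <- msms_similarity(a, b)$score
    ba <- msms_similarity(b, a)$score
    expect_equal(ab, ba, tolerance = 1e-12)
    expect_gte(ab, 0); expect_lte(ab, 1)
  }
})

test_that("candidate search applies the 5 mDa and 1.8 min rules and ranks", {
  cands <- data.frame(
    name = c("catechol", "resorcinol_like", "far_off"),
    formula = c("C6H6O2", "C6H6O2", "C10H8O4"),
    predicted_rt = c(5.0, 7.0, 4.0),
    stringsAsFactors = FALSE
  )
  hits <- search_candidates(109.0299, rt = 4.14, cands)
  # isobaric twin at predicted rt 7.0 is >= 1.8 min away -> dropped
  expect_equal(hits$name, "catechol")
  expect_equal(round(hits$mass_error_mda, 1), -0.4)
  expect_equal(nrow(search_candidates(200.0, rt = NA, cands)), 0)
  no_rt <- cands[, c("name", "formula")]
  hits2 <- search_candidates(109.0299, rt = 4.14, no_rt)
  expect_equal(sort(hits2$name), c("catechol", "resorcinol_like"))
})

test_that("the packaged candidate list parses and resolves the worked example", {
  path <- system.file("extdata", "olive_candidates.csv", package = "oliveauth")
  cands <- read_candidates(path)
  expect_true(all(c("name", "formula", "predicted_rt", "msms_spectrum") %in%
                    names(cands)))
  expect_gt(nrow(cands), 20)
  # every formula parses and yields a deprotonated mass
  mzs <- vapply(cands$formula, mz_deprotonated, numeric(1))
  expect_true(all(mzs > 100 & mzs < 700))
  hits <- search_candidates(109.0299, rt = 4.14, cands)
  expect_equal(hits$name[1], "Catechol")
  cat_spec <- cands$msms_spectrum[[match("Catechol", cands$name)]]
  expect_equal(nrow(cat_spec), 5)
  expect_true(all(is.na(cat_spec$intensity)))  # library list without intensities
})

test_that("identification levels follow the evidence ladder", {
  expect_equal(assign_level(reference_standard = TRUE, formula_assigned = TRUE),
               "1")
  expect_equal(assign_level(msms_score = 0.966), "2a")
  expect_equal(assign_level(msms_score = NA, n_matched_fragments = 3L), "2a")
  expect_equal(assign_level(msms_score = 0.9, isomer_indistinguishable = TRUE),
               "2b")
  expect_equal(assign_level(insilico_or_rt_only = TRUE), "3")
  expect_equal(assign_level(formula_assigned = TRUE, isotope_fit = 9.4), "4")
  expect_equal(assign_level(formula_assigned = TRUE, isotope_fit = 150), "5")
  expect_equal(assign_level(), "5")
  expect_equal(assign_level(msms_score = 0.5, formula_assigned = TRUE,
                            isotope_fit = 20), "4")
  expect_error(assign_level(reference_standard = TRUE), "without")
})
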