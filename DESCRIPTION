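Package: oliveauth
Title: Non-Target LC-MS Chemometrics for Table Olive Origin Authentication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested implementation of a non-target high-resolution mass
    spectrometry chemometric workflow for authenticating the geographical origin
    of table olives. Provides feature-table curation (blank-based feature removal,
    duplicate merging), a suite of nine scaling/normalization methods including
    probabilistic quotient normalization with a pooled-QC reference, a composite
    score for scaling-method selection, Kennard-Stone sample splitting, NIPALS
    PLS-DA with cross-validated latent-variable selection, VIP-based marker
    discovery with pairwise OPLS-DA, model validation (R2X/R2Y/Q2, RMSEE/RMSEP,
    ROC curves, permutation testing, Hotelling's T2 and Q-residual outlier
    diagnostics), a tiered compound-annotation ladder (monoisotopic mass
    arithmetic, isotope-pattern simulation and fit, MS/MS similarity,
    identification confidence levels), and targeted method-performance
    calculations (standard-addition calibration, LOD/LOQ, recovery, matrix
    effect, precision). A seeded synthetic-data generator emulates a 65-sample
    three-class study design so the whole pipeline is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
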