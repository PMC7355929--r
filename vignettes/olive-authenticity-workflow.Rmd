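---
title: "Non-target chemometric authentication of table olive origin: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-target chemometric authentication of table olive origin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oliveauth)
```

## The problem and the model

Protected-designation-of-origin (PDO) table olives command a premium that
invites mislabeling: Kalamata-type olives grown outside Messinia are sold as
Greek PDO product. Untargeted LC-HRMS fingerprinting addresses this without a
predefined analyte list: every aligned (m/z, retention-time) feature across a
sample set becomes a variable, and a supervised multivariate model separates
geographical origins and exposes the features that drive the separation —
candidate authenticity markers.

The statistical core is PLS-DA: partial least squares regression of a one-hot
class dummy matrix $Y$ on the scaled intensity matrix $X$. We fit it by
NIPALS (PLS2 variant): each latent variable finds a weight vector $w_a$
maximizing the covariance between the $X$ score $t_a = X w_a$ and the $Y$
block, after which both blocks are deflated by the rank-one reconstruction
$t_a p_a^\top$ (and $t_a c_a^\top$). Prediction projects a new sample onto
the weights, and the class is the argmax of the predicted dummy values;
assigned probabilities are their softmax (a clipped-and-renormalized
alternative is available via `predict(..., prob = "clip")`, since the
literature reports "class probabilities" without a formula).

Marker influence is measured by the variable importance in projection,

$$\mathrm{VIP}_j = \sqrt{p \; \frac{\sum_a \mathrm{SSY}_a \,(w_{aj}/\lVert w_a\rVert)^2}{\sum_a \mathrm{SSY}_a}},$$

with $\mathrm{SSY}_a$ the reduction in the $Y$ sum of squares attributable to
component $a$ and $p$ the feature count, so the squared VIPs average exactly
to 1. Features with VIP strictly above 0.83 — a conventional cutoff slightly
below the "greater than 1" folklore, keeping moderately influential features
— are reported as markers. Pairwise class contrasts use OPLS-DA: for each
pair of classes one orthogonal component (orthogonal signal correction) is
removed before a single predictive component is fitted, concentrating the
discriminative variance in one direction; a marker elevated in one class
scores high in both pairs containing that class and low in the third.

## Pipeline order and the tunable parameters

The stages run in a fixed order: curation, scaling, sample division,
training, validation, marker selection, annotation, suspect classification.

**Curation.** Features whose mean intensity across biological samples is
below 3x their mean across procedural blanks are discarded (a transparent
fold rule; the default 3 is the usual blank-subtraction convention).
Near-duplicate features — alignment artifacts — are grouped by single linkage
at 5 mDa and 0.1 min and each group keeps its most intense member; retained
intensities are never altered. Both operations are idempotent.

**Scaling.** Nine pretreatments are implemented (Pareto, mean centering,
autoscaling, range, vast, level, a generalized-log transform, mean-centered
log2, and PQN followed by Pareto). Pareto — centering then division by the
square root of the per-feature standard deviation — is the workflow default:
it damps the dominance of high-abundance features without inflating noise
features the way full autoscaling does. PQN estimates one dilution factor per
sample as the median quotient against a reference spectrum, here the
per-feature median of the pooled-QC rows. The generalized-log method uses
$g(x) = \log((x + \sqrt{x^2 + \lambda^2})/2)$ with $\lambda$ the median
non-zero training intensity; it is a variance-stabilizing transform in the
glog family, not a full arsinh model fit, and is documented as such.
All parameters (means, deviations, ranges, the PQN reference, $\lambda$) are
estimated on training rows only and applied unchanged to test and suspect
rows — the leakage guard is asserted in the test suite by poisoning test rows
with sentinels and checking the fitted parameters are bit-identical.

A composite score ranks the methods when the choice is left open
(`scaling = "auto"`):
$0.15\,R^2X + 0.15\,R^2Y + 0.20\,Q^2 + 0.15\,(1-\mathrm{RMSEE}) +
0.30\,(1-\mathrm{RMSEP}) + 0.01\,\mathrm{acc}_{tr} + 0.02\,\mathrm{acc}_{te}
+ 0.02\,\mathrm{acc}_{cv}$ — prediction error carries the largest weight.
On the synthetic data the log-family transforms tend to win this ranking
because the generator's noise is exactly multiplicative log-normal; on real
peak tables the ordering is an empirical question, which is why the ranking
is recomputed rather than hard-coded.

**Division.** The Kennard-Stone max-min algorithm selects a space-filling
training set on Euclidean distances: seed with the two mutually farthest
samples, then repeatedly add the sample maximizing its minimum distance to
the chosen set. Ties break to the lowest row index, making the split
deterministic. The 65-sample design divides 51/14. Distances are computed on
the Pareto-scaled sample matrix; the model's own scaling parameters are then
re-fitted on the chosen training rows alone. (The literature also describes
an alternating farthest-pair variant that yields near 50/50 splits; it is
available as `variant = "alternating"` but contradicts a 51/14 design, so
max-min is the default.)

**Model size.** The latent-variable count is chosen by stratified 5-fold
cross-validation of the misclassification error (smallest count attaining the
minimum; `k = n` gives leave-one-out). The study-scale configuration uses 3
latent variables.

**Validation.** $R^2X$ is the fraction of X variance captured by the score
reconstruction; $R^2Y$ the dummy-response fit; $Q^2 = 1 - \mathrm{PRESS}/SS$
under k-fold CV; RMSEE/RMSEP are root-mean-square dummy residuals on
training/test (the "mean error" under the root is read as mean *squared*
error — the standard meaning of the acronyms). ROC curves sweep each class's
softmax probability one-vs-rest over the unique scores extended by infinite
endpoints; the trapezoid AUC equals the Mann-Whitney statistic, which the
tests assert against an independent rank-based oracle. The permutation test
refits model and CV under 20 uniformly random relabelings; the p-value uses
the add-one estimator $(1 + \#\{Q^2_{perm} \ge Q^2_{obs}\})/(n_{perm}+1)$,
which cannot report 0 from 20 permutations. Outlier diagnostics use
Hotelling's $T^2 = \sum_a t_a^2/\mathrm{var}(t_a)$ with the 95% limit
$A(n-1)/(n-A)\,F_{0.95}(A, n-A)$, and the squared reconstruction residual
$Q$ with the Jackson-Mudholkar limit from the residual eigenvalues; a sample
must exceed both limits to be flagged.

**Annotation.** Identification proceeds down a confidence ladder. Candidate
formulas are matched on the deprotonated ion, $[M-H]^- = M - 1.00727646$ Da
(the proton mass, not the hydrogen atom mass — the 0.5 mDa electron-mass
difference matters at 4 decimal places). Mass error is reported as
theoretical minus observed, in mDa and ppm. Theoretical isotope patterns come
from full polynomial expansion over a vendored IUPAC isotope table (binary
exponentiation of the per-element convolution, peaks aggregated within
1 mDa); the fit score is $1000(1 - \cos)$ over abundance vectors aligned at
5 mDa, with scores below 100 accepted — a cosine-based analogue of vendor
"mSigma" values, comparable in threshold but not in absolute value, since the
vendor formula is proprietary. MS/MS similarity is the cosine of
square-root-intensity-weighted vectors after greedy highest-intensity-first
peak matching at 0.01 Da. Candidate search enforces a strict 5 mDa window and
drops candidates whose predicted retention time is off by 1.8 min or more.
Confidence levels: 1 (reference standard), 2a (library MS/MS cosine >= 0.7,
or >= 3 matched fragments when the library spectrum lacks intensities), 2b
(library evidence that cannot separate isomers), 3 (in-silico/literature
evidence only), 4 (unequivocal formula: exact mass + isotope fit < 100), 5
(exact mass only).

**Targeted figures of merit.** Standard-addition calibration normalizes the
blank-subtracted analyte area by the internal-standard area and fits ordinary
least squares; $\mathrm{LOD} = 3.3\,S_a/b$ and $\mathrm{LOQ} = 10\,S_a/b$
from the intercept standard error and slope of the low-range (0.02–1 mg/kg)
curve, so LOQ/LOD is exactly 10/3.3. The matrix effect is the signed slope
ratio $100(b_{matrix}/b_{solvent} - 1)$ (suppression negative); the
area-ratio alternative is available behind a flag. Precision is the percent
RSD of replicates, pooling both days for the inter-day figure.

## What the synthetic generator emulates — and what it does not

The generator reproduces the study geometry: 20/24/21 samples in three
classes, ~2000 features, 6 pooled-QC rows built as the mean of all sample
rows plus measurement noise, 4 procedural blanks carrying a contaminant
subset of features, 8 injected near-duplicate features (within 3 mDa and
0.05 min of their source), and an 11-sample suspect set drawn from the Greek
class with an extra per-feature harvest-year factor shared across the set.
Intensities follow
$x_{ij} = \beta_j \cdot e_{ij} \cdot d_i \cdot \varepsilon_{ij}$: a
log-normal baseline $\beta_j$ (meanlog 10, sdlog 1 — a typical 2–3 decade
LC-MS abundance spread), a class effect $e_{ij}$ equal to the marker fold
change (default 5) when feature $j$ is a marker of sample $i$'s class and 1
otherwise, a per-sample dilution $d_i$ (log-normal, sdlog 0.2), and
multiplicative noise at 10% CV. The study does not report within-class
variances or marker effect sizes, so these defaults were chosen once as
plausible for processed food extracts and are deliberately strong enough
that the classes separate — the published model also classified perfectly.

Synthetic m/z values sit on a 10 mDa grid with at most ±2 mDa jitter, which
guarantees that only the injected duplicates can fall inside the merge
tolerance; duplicate sources are additionally chosen isolated in (m/z, rt)
so single-linkage merging collapses exactly the injected pairs for any seed.

What passing tests on this generator demonstrate: the pipeline's arithmetic,
its determinism, the no-leakage contract, and its ability to recover known
markers under a realistic noise model. What they do not demonstrate:
performance under retention-time drift, batch effects, censored/missing
intensities, correlated features (adducts, isotopologues, in-source
fragments), or class overlap — real peak tables have all of these, and the
perfect error rates on synthetic data must not be read as a claim about real
olives.

## Numerical choices and degenerate inputs

- Sample standard deviations use the $n-1$ denominator throughout.
- 0/0 situations in autoscale/vast/level (constant or zero-mean columns) map
  to 0: constant columns carry no class information and this keeps matrices
  finite.
- The log2 transform uses $\log_2(x+1)$ to admit zeros; missing values are
  stored as 0 and treated as true zeros.
- NIPALS converges at $10^{-10}$ relative score change, at most 500
  iterations per component; fully deflated blocks truncate the model rather
  than fitting noise components.
- Argmax class assignment breaks ties to the first class in sorted class
  order; Kennard-Stone ties break to the lowest sample index; duplicate
  merging breaks intensity ties by ascending m/z.
- PQN requires a positive overlap between each sample and the reference and
  refuses all-zero references.
- CV folds are stratified with a fixed seed whenever every class has at
  least `k` members; permutation replicates fall back to unstratified folds
  when a relabeling starves a class.

## Problem sizes used by the packaged analyses

The numbered scripts under `analysis/` and the acceptance script run the
full 65-sample, 2000-feature configuration (a fit takes well under a second;
the 20-permutation test refits the model and its 5-fold CV 126 times and
completes in seconds). Unit tests exercise a reduced 24-sample, 150-feature
bundle where study scale is not the point, and the study-scale configuration
where it is.

## Known limitations

- One orthogonal component in OPLS-DA (more are rarely identifiable in
  two-class contrasts of this size); no kernel or sparse PLS variants.
- The isotope-fit score shares only its acceptance threshold with vendor
  mSigma values, not its scale.
- The scaling comparison reports the composite score on whatever data it is
  given; it does not reproduce any particular published ranking, which
  depends on the real data's noise structure.
- In-source fragments are annotated via an explicit flag, not detected
  automatically.
- Retention-time prediction is consumed as user input (`predicted_rt` in the
  candidate list), never modelled.
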