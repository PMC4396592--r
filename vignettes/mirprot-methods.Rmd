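---
title: "Methods: integrated miRNA-mRNA-protein association analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated miRNA-mRNA-protein association analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirprot)
```

## The model and its assumptions

The starting point is a mass-balance argument: protein influx is
proportional to the transcript level and protein outflux proportional to the
protein level, `P'(t) = aE − bP` with translation rate `a > 0` and
degradation rate `b > 0`. If mRNA expression is approximately constant over
the interval in which protein levels fixate, the solution is
`P(t) = (a/b)E + C·exp(−bt)`, so at steady state the protein level is
proportional to the mRNA level with constant `a/b`
(`kinetics_params()`, `simulate_kinetics()`, `integrate_kinetics()`).
Allowing that ratio to depend multiplicatively on miRNA expression yields
the power-law model

\[ P = C \cdot M_1^{\beta_1} \cdots M_m^{\beta_m} \cdot E^{\gamma}, \]

linear on the log scale. `beta = −1, gamma = 1` is the textbook case of a
protein proportional to its mRNA and inversely proportional to a repressing
miRNA; other exponent combinations absorb other functional relationships,
which is the point — the model measures *association*, direct or indirect,
not mechanism.

Assumptions worth keeping in mind: (i) the relationship is log-linear over
the observed expression range; (ii) expression snapshots are near steady
state; (iii) the error is additive and Gaussian on the log scale; (iv) in
the univariate screen, the miRNAs not in the current model act as noise —
the screen is a marginal analysis, and the multivariate refit exists
precisely because miRNAs co-vary.

## Standardization

Before fitting, every feature is mapped across samples to
`X* = (X − min)/(max − min) + δ₀` with `δ₀ = 0.1` by default
(`standardize()`), making miRNA, mRNA and protein values share the range
`[δ₀, 1 + δ₀]` and rendering them strictly positive, hence
log-transformable. Standardization is applied to linear-scale values,
per feature. Two numerical consequences drive the implementation:

* features with `max == min` leave the map undefined and carry no signal;
  they are dropped with a warning rather than imputed;
* the map is affine per feature, so re-standardizing a standardized matrix
  is the identity (asserted to 1e-12 in the tests) and within-feature ranks
  are preserved.

`log_transform()` uses the natural log. The exponents β and γ are invariant
to the log base (a base change rescales both sides of the regression
identically; asserted to 1e-10), so only the intercept α depends on this
choice; it is reported in natural-log units.

## The univariate screen and the conservative FDR estimator

`fit_univariate()` is plain OLS of `logP` on `(1, logM, logE)` with
two-sided t-tests at `n − 3` df. Samples with a missing value in any of the
three vectors are removed pairwise from that one fit — the simplest rule
that maximizes the usable data per fit. Collinear designs and fits with
fewer than 4 usable samples are flagged degenerate and report p = 1 instead
of aborting: at a 105 × 421 = 44,205-fit sweep scale, a single bad pair must
not kill the run, and p = 1 keeps the pair-count invariant intact while
guaranteeing the pair can never be called significant.

`fit_all_pairs()` vectorizes the sweep: for one protein the response and the
mRNA covariate are fixed, so the centered cross-products of all miRNAs can
be computed with matrix products and the per-pair 2×2 normal equations
solved in closed form. The fast path is algebraically identical to the QR
fit and is verified against it (and against an independent normal-equations
oracle) to 1e-10 in the tests; rows with missing values fall back to the
per-pair path.

Significance is called on the pooled miRNA p-values. Under a global null
with independent tests, the expected number of false positives at threshold
`P*` is `N·P*`; dividing by the observed call count `S` gives the most
conservative FDR estimate `N·P*/S`. `choose_threshold()` scans the observed
p-values (any threshold between consecutive order statistics induces the
same call set, so observed values are canonical) and returns the feasible
threshold maximizing `S` — algebraically the Benjamini–Hochberg step-up
rule, which is why the global-null simulation in the acceptance tests holds
the realized false-discovery proportion at the bound. When no threshold
qualifies the result is `S = 0` with `fdr_hat = 0` (an empty call set
contains no false discoveries). The estimator is applied to the miRNA
p-values only; mRNA (γ) p-values are reported but not thresholded, since
the screen's question is about miRNAs and γ is an adjustment.

## The prescreen-constrained Lasso

Per protein, all miRNAs enter one model, with two guards against the
`m ≫ n` regime: coefficients nominally nonsignificant in the univariate
screen (p > 0.01, uncorrected) are constrained to zero
(`prescreen()`), and the remainder is fitted with an L1 penalty whose λ is
chosen by 10-fold cross-validation (`fit_multivariate()`, backed by
glmnet). Nonzero coefficients are the multivariate "significant effects".
Design choices the upstream description leaves open, and how this package
resolves them:

* **γ is unpenalized** (as is the intercept): the mRNA term is an in-*cis*
  adjustment, not a candidate predictor; penalizing it would let the miRNA
  coefficients absorb part of the cis effect. `penalize_gamma = TRUE`
  exposes the alternative.
* **λ at minimum mean CV error** (`lambda_rule = "min"`); the one-SE
  convention is available as `"1se"`.
* **Folds**: k = 10, assignment drawn deterministically from `cv_seed`; the
  same inputs and seed give bit-identical fits.
* **Numerics**: predictors are standardized inside the solver and
  coefficients back-transformed; convergence threshold 1e-7 on the CV path
  and 1e-12 for the fixed-λ limit checks (λ = 0 must match the unpenalized
  normal-equations solution to 1e-6, λ → ∞ the mRNA-only OLS to 1e-8).

An empty allowed set degrades to OLS of `logP` on `logE` — the protein
simply has no detected miRNA component.

## Interactome clustering

The coefficient table B (proteins × miRNAs) is clustered two ways with
Pearson-correlation distance `1 − cor` and complete linkage
(`correlation_distance()`, `hierarchical_cluster()`), on all cells, not just
significant ones — coordinated blocks are visible in the coefficients
themselves. Zero-variance rows get distance 1 to everything (the
uncorrelated convention) with a warning. Flat clusters come from cutting
each tree at a fixed k (`extract_clusters()`); recursive
dendrogram-partitioning heuristics are deliberately out of scope, and
published cluster counts obtained with them are treated as data-dependent
observations. When no k is configured, `suggest_k()` maximizes the mean
silhouette width over k = 2..k_max — chosen over a gap statistic because it
needs only the distance matrix, which is the native object of this pipeline.
Network export (`export_network()`) emits SIF lines `mirna pos|neg protein`
for significant cells, optionally filtered at a |β| threshold (0.15 was the
published choice for cross-cohort concurrence).

## Scores, prediction and screen consistency

The patient score `score(i, p) = Σ_j β̂_ij · logM(j, p)` uses the
multivariate coefficients and the **log-standardized** miRNA expression —
the representation the coefficients were fitted on; using raw expression
would mix scales. Patients are clustered on score columns with Euclidean
distance and complete linkage; association between cluster labels and a
clinical factor is tested by chi-square, with Fisher's exact test when
expected counts fall below 5 in a small table (no test is prescribed
upstream).

Cross-cohort prediction applies a fitted model's coefficients to another
cohort's matrices (standardized with the same δ₀ pipeline, which is what
makes scales comparable across platforms):
`α̂ + γ̂·logE_B + Σ β̂_j·logM_B(j)`, dropping (and counting) miRNAs absent
from the target cohort, and scoring with Pearson r and a two-sided
t-approximation p-value, significance at p < 0.05 per cohort.

Overexpression-screen validation standardizes each protein's measurements
across the whole perturbation screen (`screen_zscore()`), and an association
is validated iff it is significant in the cohort, `|z| ≥ 1.96`, and the
screen effect's sign matches the fitted coefficient's
(`screen_consistency()`). The numeric 1.96 is used (and configurable); the
"±2 SD" phrasing sometimes attached to it is treated as a gloss on the
same normal quantile.

## What the simulator emulates — and what it does not

`simulate_cohort()` draws miRNA and mRNA levels from positive laws —
log-normal(0, 1) on the log scale by default, because the fitted model is
linear there and no marginal distribution is claimed for real data — and
generates protein *exactly* from the power-law model with Gaussian log-scale
noise (`noise_sd`, default 0.25, a moderate residual scatter relative to
unit-variance log-covariates). Optional subtype structure is injected as
additive offsets on the log-miRNA scale only; protein inherits the blocks
through the model, which is the simplest mechanism that reproduces
subtype-aligned patient clusters in the score heatmap. Default dimensions
mirror the reference cohort: 283 samples, 105 protein/mRNA pairs, 421
miRNAs. A single integer seed drives all randomness through deterministic
substreams; identical seeds give bit-identical cohorts.

The simulator does **not** emulate array measurement error, probe effects,
normalization artifacts, missingness patterns, miRNA–miRNA co-expression
beyond subtype blocks, or any deviation from the power-law form. A green
test therefore establishes that the estimators recover the model's own
truth under realistic dimensions and noise — it cannot establish that real
cohorts follow the model, nor reproduce published cohort-specific counts
(3,687 significant calls, 47 screen-validated pairs, and so on), which
depend on data this package does not ship.

## Numerical choices and degenerate inputs

* Runge–Kutta integration of the kinetics caps `b·dt` at 0.02, keeping the
  global error far below the 1e-6 agreement tolerance with the closed form.
* The fast univariate path declares a pair degenerate when the centered
  design's determinant falls below 1e-12 of its scale; noise-free designs
  (residual sum of squares exactly 0) report p = 0 for nonzero estimates.
* FDR threshold ties: among thresholds achieving the maximal S, the
  smallest is returned (canonical; all induce the same call set).
* `estimate_fdr()` with `S = 0` reports `fdr_hat = +Inf` (undefined ratio);
  `choose_threshold()` reports 0 for its empty result, see above.
* hclust's deterministic tie handling supplies the merge-tie rule; the tree
  is verified against a naive O(n³) agglomerative oracle.

## Known limitations

Associations are not causal claims; the screen's marginal β conflates
direct targeting, indirect regulation, reverse causation and shared
upstream drivers — the target-prediction overlap (`putative_direct()`,
≥ 2 of 3 algorithms by default) is the only directness filter provided. The
conservative FDR estimator assumes independent tests; correlated miRNAs
make it more conservative, not less. Lasso coefficients are reported
without inference (no p-values on selected effects, by design). The
prescreen can exclude miRNAs whose effect only appears conditionally on
others; that trade-off is inherited from the modeling approach itself.
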