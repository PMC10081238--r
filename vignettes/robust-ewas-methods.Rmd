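---
title: "Robust E/TWAS: model, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust E/TWAS: model, simulation design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The statistical problem

An E/TWAS tests each of many quantitative markers for association with one
outcome. Standard multiple-testing corrections control false discoveries
from sampling error but not those from data artefacts. The hazardous case
is a *bivariate* outlier: one individual whose outcome and marker values
are both extreme. A concordant pair (same sign) contributes a large product
term to the marker-outcome covariance and can produce an arbitrarily small
p-value for a null marker. *Univariate* outliers — an extreme value in
either variable but not both — instead add pure variance and mostly
*attenuate* real signal. Because a small p is exactly what pushes a feature
into the reported top list, artefact-driven findings concentrate among the
top hits.

## The robust procedure

For each feature the package:

1. partitions the n samples into k equal, non-overlapping folds
   (`partition_folds()`);
2. fits the linear model per fold (`fit_marker_association()`), giving fold
   T statistics with small residual degrees of freedom
   (fold size minus the number of coefficients);
3. maps each T to a signed Z with the exact t-tail transform
   (`t_to_signed_z()`) and combines them as
   `Z_meta = sum(z_i) / sqrt(k)` (`stouffer_combine()`);
4. adjusts the two-sided normal p-values of `Z_meta` across features
   (`adjust_pvalues()`).

An artefact only contaminates the fold that contains it. If the
contamination shifts that fold's Z by Δ, `Z_meta` moves by exactly
`Δ/sqrt(k)` — the dilution that drives the method's robustness, and an
identity asserted numerically in the test suite for k in {2, 5, 10, 20}.

Key identity: at k = 1 the procedure *is* the full-sample analysis on the Z
scale (`|Δp| < 1e-12` in the tests), so the robust method is a strict
generalization of conventional testing.

### Parameters that matter

| parameter | default | meaning / rationale |
|---|---|---|
| `k` | user choice | folds; dilution is `1/sqrt(k)`, per-fold df shrink as `n/k` |
| fold weights | all 1 | folds are built equal-sized (±1), so `sqrt(n_i)` weighting coincides up to rounding; a `weights` argument exists for uneven folds |
| stratification | on for binary outcomes | an all-control fold makes the per-fold test undefined |
| minimum fold size | covariates + 3 | residual df ≥ 1 with margin |
| `model_orientation` | `marker_as_response` | conventional EWAS formulation `marker ~ outcome + covariates`; without covariates both orientations give the identical correlation t (asserted in tests) |
| `adjust` | `bonferroni` | `bh` and `none` available |

Covariates are **refit within each fold**. The apparently cheaper
alternative — residualize covariates once on the whole sample, then test
residuals per fold while spreading the df loss — couples the folds through
the shared residualization and deflates the per-fold p-values; it is
deliberately not implemented, as is a log-transformation workaround whose
results no longer transfer to the untransformed data. The cost of the
per-fold refit is a df loss of (covariates + 2) in *every* fold, which is
the main source of the method's small power loss.

### Why the exact t-to-Z mapping

Per-fold df are small: at n = 250 and k = 10, each fold has 25 samples and
23 df without covariates. At t = 3, df = 23, the normal approximation
z ≈ t overstates |z| by ~0.3; summing k such errors inflates `Z_meta` and
breaks calibration. The mapping is computed on the log-probability scale
(`pt(..., log.p = TRUE)` → `qnorm(..., log.p = TRUE)`) so it remains exact
far into the tails (|t| of 30+ at small df), and it preserves the
two-sided p to < 1e-12 by construction.

## Comparators

*Full-sample analysis* is the k = 1 special case reported on the native t
scale.

*Split-half replication* randomly halves the sample (stratified, sizes ±1),
tests two-sided in the discovery half at `alpha_discovery`, and — only for
features passing — tests one-sided in the replication half in the
discovery direction at `alpha_replication`. Two type-I summaries exist and
both are reported: the **conditional** replication rate among discoveries
(the rate on the per-test alpha scale) and the **joint**
discovery-and-replication rate (nominally `alpha_d * alpha_r`; the power
metric). Neither is privileged in figures produced by
`plot.ewas_sim_result()`; the conditional rate is drawn as the reference
line. Worth knowing: under a bivariate outlier the conditional rate is a
mixture of a clean-replication branch (rejecting at exactly alpha) and a
rarely-reached contaminated-replication branch, so it stays near alpha
(~0.06 at 6 SD) even while the full-sample rate explodes (~0.52). The sense
in which splitting is *most* sensitive to the outlier is per-stage: the
outlier sits in a half-sized sample where it is diluted half as much, so
the stage containing it rejects more often than the full-sample test does.

## Diagnostics

*Genomic inflation lambda*: observed median of the 1-df chi-square
association statistics divided by the null median `qchisq(0.5, 1)`
(≈ 0.4549364). P-values are mapped through the upper tail; an exact zero is
mapped to the largest finite quantile with a warning. Lambda ≈ 1 says the
*bulk* of tests is calibrated — it is insensitive to a handful of
artefact-driven tails, which is why the outlier-sensitivity refit exists.

*MAD outlier flags*: observation i is flagged when
`|r_i − median(r)| / (1.4826 · MAD(r)) > 3`, i.e. a robust z-score above 3.
The 1.4826 normal-consistency constant (R's `mad()`) makes the threshold
comparable to "3 standard deviations" under normality; the raw-MAD reading
of "MAD > 3" would make the rule scale-dependent. Zero MAD returns
all-unflagged with a warning rather than dividing by zero.

*Outlier-sensitivity refit* (`outlier_sensitivity()`): fit, flag on the
fitted model's residuals, refit without flagged samples, report
`p_ratio = p_trimmed / p_full`. A finding is called outlier-driven when
`p_ratio > 100`, i.e. the evidence weakens at least 100-fold on removal —
the directional reading under which removal of influential artefacts
*weakens* a spurious signal. The ratio and its direction are part of the
output so the interpretation can be audited. Per-site post-hoc removal is a
diagnostic here, never an automatic filter: it is unsystematic across sites
(different individuals drive different sites), which is the motivation for
the robust procedure itself.

This audit trail is also how the method behaves on real methylation data:
on a published case/control HumanMethylation450 reanalysis the regular
analysis gave λ ≈ 1.13 with a handful of Bonferroni-significant sites,
several of which lost > 100-fold significance after MAD trimming, while the
5-fold robust analysis gave a comparable λ and dropped most of the
outlier-flagged sites from its suggestive list. Reproducing that external
dataset requires the accession plus its upstream QC pipeline and is
deliberately outside this package's tests; the package's own evidence is
the simulation study below.

## The simulation study

`run_type1_study()` / `run_power_study()` draw `(y, x)` standard bivariate
normal with correlation `rho` (`generate_pair()`: `x = rho*y +
sqrt(1-rho^2)*e`), inject outliers, and apply every configured method,
counting rejections at `alpha`. Defaults encode the study conditions this
package was built to reproduce:

* n = 250 samples, 10,000 replicates per scenario;
* type-I: `rho = 0`, `alpha = 0.05`; power: `rho = 0.3`, `alpha = 0.001`;
* five univariate outliers or one bivariate outlier per replicate;
* fold grid {2, 5, 10, 20, 25}, bracketing the k ≥ 10 regime where the
  univariate-outlier calibration is exact at n = 250.

Outliers **replace** values (n stays 250) with a point `magnitude`
population SDs from the mean, random sign. The magnitude is not part of the
stated study conditions anywhere we could anchor it; the package default is
**6 SD** — far enough to dominate a fold-level fit at n/k ≈ 25, yet
plausible for an array artefact — and magnitude-dependent conclusions are
checked across {4, 6, 8} SD in the acceptance tests. Univariate outliers
alternate between marker and outcome starting with the marker (so five
outliers split 3 marker / 2 outcome); the split and starting variable are
configurable. Bivariate outliers are concordant by default because only
concordant pairs manufacture association signal. Power is studied without
bivariate outliers: on a truly associated marker a bivariate outlier can
push detection either way depending on its orientation to the trend.

Every reported rate is an exact count over `n_sims` with Monte-Carlo
standard error `sqrt(r(1-r)/n_used)`; results are bit-reproducible given
`(config, seed)`. Fold assignments draw per-replicate seeds from the master
stream but execute in their own substream (`partition_folds()` restores the
caller's RNG state), so adding a method to a configuration does not perturb
another method's folds.

Problem sizes used by the test suite: the calibration, ordering and power
checks run the full 10,000-replicate design at n = 250 (the study
conditions themselves); distributional checks (p-value uniformity under the
null) use 10,000 features at n = 250 in one vectorized pass; the
Monte-Carlo cross-checks of conditional/joint split-half rates use 5,000
replicates at n = 100, sized so their binomial tolerance bands are decisive.

## What the synthetic generator does and does not emulate

`generate_fixture_ewas()` produces a complete EWAS-shaped dataset — shared
outcome, conditionally independent Gaussian markers with a known set of
truly associated features, optional confounding covariates loading on both
sides, optional injected outliers — with a truth table for every feature.
It deliberately does **not** emulate beta-value heteroscedasticity, probe
cross-reactivity, batch structure, or correlated marker blocks. Passing
tests on these fixtures therefore demonstrate the statistical behaviour of
the procedure (calibration, dilution, orderings), not robustness to
array-specific noise; on real arrays the usual upstream QC and
normalization remain necessary, and covariate sets (cell composition,
batch) must be supplied by the analyst.

## Numerical and design notes

* Association fits: without covariates the closed-form simple-regression
  t (= correlation t) is used; with covariates a QR fit with rank check.
  Both orientations and the closed form are verified against `lm()` in the
  tests.
* Degenerate inputs raise classed errors (`robustewas_degenerate_predictor`,
  `robustewas_collinearity`, `robustewas_insufficient_sample`,
  `robustewas_invalid_fold_count`, ...) annotated with feature and fold
  context when raised inside the k-fold engine.
* Remainder handling when k does not divide n: the first `n %% k` folds
  take one extra sample. Stratified assignment gives each stratum's
  remainder to the currently smallest folds with random tie-breaks, which
  keeps overall fold sizes within 1 of each other.
* Ties and p = 1: `stouffer_combine(c(1, -1))` gives exactly z = 0,
  p = 1; `adjust_pvalues()` caps at 1.
* The suggestive-significance reporting threshold in the CLI defaults to
  1e-5, the customary E/TWAS "suggestive" line.

## Known limitations

* Linear association only; logistic/GLM, mixed models, and
  surrogate-variable estimation are out of scope.
* Equal-weight Stouffer combination assumes near-equal fold sizes; the
  `weights` argument exists but heterogeneous-study meta-analysis
  (random effects) is not implemented.
* The split-half comparator implements a single 50/50 split; multi-stage
  replication designs are not modelled.
* The simulation treats one marker at a time; correlated nulls across
  markers (and hence dependence of the multiple-testing correction) are
  not simulated.
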