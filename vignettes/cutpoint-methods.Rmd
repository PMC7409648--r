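---
title: "Methods: cut-point selection and honest inference for survival biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cut-point selection and honest inference for survival biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survcutpoint)
```

## The scientific setting

In AML, patients who reach a measurable-residual-disease-negative complete
remission still have very heterogeneous outcomes.  One candidate
post-treatment prognostic marker is the *degree of platelet recovery*:
the difference `dplt = plt_peak - plt_pre` (10⁹/L) between the platelet
peak after marrow recovery from the remission-inducing course and the
count on the day before initial treatment.  The analytic questions the
package answers are generic to any continuous biomarker and censored
outcome pair:

1. at which threshold does dichotomizing the marker best separate
   progression-free (PFS) or overall survival (OS)?
2. is that separation real, given that the threshold was chosen to
   maximize it?
3. does the dichotomized marker survive adjustment for standard clinical
   covariates?

## The scan (maximally selected log-rank)

`scan_cutpoints()` enumerates candidate thresholds and evaluates the
two-group log-rank statistic at each.  Conventions, chosen once:

* **Candidates are observed marker values**, not midpoints, so a reported
  cut-point is always a value in the data's own units.  A candidate is
  admissible when the split leaves both groups with at least
  `max(1, ceiling(min_group_frac * n))` patients.
* **`min_group_frac` defaults to 0.10.**  Clinically meaningful splits are
  often lopsided (20/80); 0.10 admits those while excluding the extreme
  tails where the log-rank variance degenerates and spurious maxima
  concentrate.
* **"High" means strictly greater than the cut-point**, so the patient
  defining an observed-value cut-point falls in the low group.  This is
  the convention of the maximally-selected-statistics literature; it is
  configurable in `dichotomize(strict = )`.
* **Direction of association** is read off the sign of `O - E` for the
  high group (`direct` = fewer events than expected = better outcome), not
  from a hazard-ratio fit: it is always defined when any events exist and
  costs nothing.
* **Ties in the maximum break to the smallest candidate**, a deterministic
  rule that favors the larger high group.
* **The optimization endpoint defaults to PFS.**  Progression is the
  outcome most directly tied to remission quality; the package reuses a
  PFS-derived cut-point for OS in `run_full_analysis()` (per-endpoint
  scanning remains available by calling the scan directly).

Because `argmax chi-square = argmin p` at one degree of freedom, scanning
by chi-square and scanning by minimal p are the same search; the package
asserts this equivalence in its tests.

## Why the naive p-value is wrong, and the honest test

The minimal p over a scan is the minimum of many correlated tests; treating
it as a single test's p-value inflates type-I error several-fold (the
package's calibration study measures the inflation rather than assuming
it).  `cv_cutpoint_test()` implements the two-fold cross-validated repair
in the style of Faraggi and Simon:

1. split the cohort uniformly at random into halves A and B (odd n: A
   receives the extra patient — an arbitrary but fixed convention);
2. scan A for its optimal cutoff, scan B for its own;
3. label B's patients above/below with A's cutoff and A's patients with
   B's cutoff — no label ever depends on a cutoff fitted to data
   containing that patient;
4. test above vs below with a log-rank test stratified by half
   (contributions to `O - E` and `V` accumulate within each half and are
   summed before squaring).

Conditional on the two cutoffs the labels are data-independent under the
null, so the stratified statistic keeps its χ²₁ reference distribution.
The classical procedure uses a *single* random split, and so does the
package's default; the split seed is a required, recorded argument, and
`cv_sensitivity()` exposes the split-to-split variability across seeds as
a clearly flagged extension.  The same seed is reused for both endpoints
by default so PFS and OS are judged on the same partition.  A fold in
which no admissible candidate or no event exists aborts the test with an
error carrying the seed, letting callers resample or report.

## Survival machinery

`km_estimate()`, `logrank_test()` and `stratified_logrank()` are
implemented in the package (vectorized risk-set tabulation) rather than
delegated, for two reasons: the scan evaluates the statistic thousands of
times inside simulation loops, and the scan entries, the unstratified test
and the stratified test must agree *exactly*, which is guaranteed by
routing all of them through one engine (the unstratified test is the
constant-stratum case of the stratified one).  The test suite cross-checks
the implementation against `survival::survfit()` / `survival::survdiff()`
and against hand tabulations.

Numerical conventions:

* censored records tied with an event time stay in that time's risk set
  (censoring after events at equal times);
* event times whose risk set is a singleton contribute zero variance
  (guard against 0/0); a candidate split with no events at all scores
  chi-square 0, p 1;
* for more than two groups the quadratic form uses a pseudo-inverse when
  the variance matrix is numerically singular;
* "two-sided log-rank p" means the upper tail of the χ² reference
  distribution — the conventional reading.  At very small n this
  continuous reference cannot match the discrete permutation distribution
  of the statistic (with four subjects the exact permutation p has only a
  handful of attainable values); the tests therefore validate the
  statistic against exact enumeration and validate the Monte-Carlo
  permutation distribution against that enumeration, while the asymptotic
  p is what the package reports at cohort sizes where it is appropriate.

`survival_rate_at()` reads the step function at a horizon (months) and
flags horizons beyond the observed follow-up instead of extrapolating
silently.

## Cox modelling

`fit_cox()` is built on `survival::coxph()` (Efron tie handling by
default, Breslow switchable for oracle comparisons; convergence at
relative log-likelihood change < 1e-9 within 100 iterations) and reports
per-coefficient hazard ratios with Wald confidence intervals computed as
`exp(estimate ± 1.96·se)` — the fixed multiplier matching clinical
reporting style — and two-sided Wald p-values.  Design encoding follows
the clinical table convention: explicit reference levels, indicator
columns per non-reference level, induction-course count collapsed to
"1" vs "more than 1", and listwise deletion of incomplete rows with a
logged count.  The model is deliberately unpenalized even when events per
coefficient are few — the package's target analyses are reproductions of
conventional clinical workflows — but a warning fires below 10 events per
coefficient.  Brute-force partial-likelihood maximization serves as the
oracle in tests, and the score test at β = 0 for a binary covariate is
checked against the log-rank chi-square, tying the two modules together.

Baseline tables use the Pearson chi-square without continuity correction
and without an automatic exact-test fallback (sparse cells warn instead;
Fisher's test sits behind a flag), and the Mann–Whitney U test for numeric
characteristics — exact enumeration when `n1*n2 <= 400` and tie-free,
otherwise the tie-corrected continuity-corrected normal approximation.
Mean ± SD summaries use the n−1 standard deviation and report both the
Mann–Whitney and the Welch p-value, since clinical reports are often
ambiguous about which was used.

## The synthetic cohort generator

`generate_cohort()` draws cohorts with the statistical structure the
analysis assumes, so every stage is testable without patient data:

| parameter | default | rationale |
|---|---|---|
| `n` | 67 | size of the emulated remission cohort |
| `plt_pre` | log-normal, median 43, sdlog 0.9 | right-skewed counts; at n = 67 the simulated range brackets 3–282 |
| `plt_peak` | log-normal, median 389, sdlog 0.45 | range brackets 122–984 |
| `rho` | 0.2 | log-scale correlation of the two counts; the true joint dependence is unknowable from summary tables, so it is a free, sensitivity-testable parameter |
| `threshold` | 60th percentile of simulated `dplt` | emulates a cut-point in the upper-middle of the marker distribution (52 vs 15 style splits) |
| `hazard_ratio` | 3 | low-vs-high hazard multiplier; 3 matches the magnitude of adjusted effect the package is designed to detect; 1 gives null cohorts |
| `baseline_rate` | ln(2)/24 per month | closed-form calibration (`calibrate_baseline_rate()`): 50% event-free at 2 years in the high group |
| censoring | uniform on 5–90 months | administrative censoring over a realistic follow-up window |
| `post_progression_mean` | 12 months | exponential post-progression survival; places 2-year OS above 2-year PFS as observed clinically |
| covariates | sex 0.5; age U(3, 69); risk 0.18/0.63/0.19; courses 0.64/0.31/0.045; consolidation 0.48/0.36/0.16 | typical AML remission-cohort frequencies |

The marker is always *derived* as `plt_peak - plt_pre`, never sampled, so
its distribution inherits the platelet model; negative values are rare but
legal.  OS is built compositionally as PFS plus post-progression survival,
so `os_time >= pfs_time` holds in simulated data even though the data
model merely warns on violations (observational tables can violate it).
The hazard is a change-point model — constant within each marker group —
because that is exactly the assumption a dichotomized-marker analysis
makes; a linear-in-marker hazard is *not* simulated by default, and
covariates are sampled independently of outcome, so baseline homogeneity
between marker groups holds in expectation.

What the generator does **not** emulate — integer-rounded counts,
marker–covariate confounding, non-exponential baseline hazards, cohort
selection effects — bounds what passing tests show: they validate the
estimators and the inferential logic under the stated model, not the
clinical claim on any real cohort.

## Validation design and problem sizes

The test suite validates each operation against an independent oracle
(hand tabulation, exhaustive permutation, brute-force likelihood search,
closed forms, or a reference implementation) and then validates the
pipeline's statistical behavior by simulation, at sizes chosen to keep
Monte-Carlo error small relative to the bands being checked: 1000 null
cohorts of n = 67 for the selection-bias and calibration studies (binomial
SE ≈ 0.007 at a nominal 0.05), 200 replicates of n = 500 for cut-point
recovery under a hazard ratio of 3, 200 replicates of n = 1000 for Cox
bias and coverage, and 10,000 random permutations against exact
enumeration for the small-sample log-rank distribution.
`scripts/acceptance.R` re-runs the pipeline-level quantities from a single
command-line seed.

## Known limitations

* The cross-validated p-value depends on the random split; the package
  reports the single-split classical answer and surfaces the sensitivity
  explicitly rather than averaging splits.
* No corrected analytic p-values for maximally selected statistics
  (e.g. asymptotic bounds for the maximum over cutoffs) — the
  cross-validation route is the one implemented; the analytic route is
  noted as related work.
* Single-cut-point analysis only; two-cut (three-group) scanning is out
  of scope.
* No Kaplan–Meier confidence bands, no proportional-hazards diagnostics,
  no multiplicity adjustment across baseline characteristics: the package
  reproduces the conventional clinical workflow, which uses none of them.
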