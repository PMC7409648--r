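# survcutpoint

Optimal cut-point selection and cross-validated inference for survival
biomarkers, motivated by platelet-recovery prognostics in acute myeloid
leukemia (AML).

## The problem

Clinicians routinely dichotomize a continuous biomarker — here the degree
of platelet recovery around the first measurable-residual-disease-negative
complete remission, `D_PLT = PLT_peak − PLT_pre` (units 10⁹/L) — into
"high" and "low" groups and compare survival between them.  Choosing the
threshold that *maximizes* the separation (the maximally selected log-rank
statistic, the computation behind pixel-scan tools such as X-tile) makes
the usual log-rank p-value badly anti-conservative: the same data pick the
split and test it.  `survcutpoint` implements both halves of a sound
workflow:

* **the scan** — for every admissible candidate threshold *c* (observed
  marker values leaving both groups at least a configurable fraction of
  the cohort), dichotomize at `marker > c`, compute the two-group log-rank
  statistic

  χ²(c) = (O₁ − E₁)² / V,  V = Σⱼ dⱼ (n₁ⱼ/nⱼ)(1 − n₁ⱼ/nⱼ)(nⱼ − dⱼ)/(nⱼ − 1),

  summed over distinct event times, and select ĉ = argmax χ²(c);

* **the honest test** — a two-fold cross-validated significance test in
  the style of Faraggi & Simon: split the cohort at random into halves A
  and B, find each half's optimal cutoff, label the *other* half's
  patients with it, and test above vs below with a log-rank test
  stratified by half.  No patient's label depends on a cutoff estimated
  from their own data, so the resulting p-value is approximately
  calibrated, where the naive "minimum p" of the scan rejects null
  cohorts several times too often.

Around this core the package provides Kaplan–Meier estimation with
fixed-horizon survival rates, plain and stratified log-rank tests, Cox
proportional-hazards reporting with clinical covariate encodings
(univariate sweep + multivariate model), baseline-table group comparisons
(Pearson χ², Mann–Whitney U), and a synthetic remission-cohort generator
with a threshold hazard model — so the entire pipeline is testable without
patient-level data.

## Worked example

```r
library(survcutpoint)

co <- generate_cohort(cohort_config(seed = 20))   # 67 simulated CR patients
prof <- scan_cutpoints(survival_sample(co$pfs_time, co$pfs_event),
                       co$dplt, marker_name = "dplt")
prof
#> <cutpoint_profile> dplt: 54 candidates over n = 67
#>   optimum: dplt > 515.718 (chi2 = 9.668, p = 0.001875, 17 high / 50 low, direct)

cv_cutpoint_test(co, seed = 3)
#> <crossval_result> dplt on PFS (seed 3)
#>   cutoff A = 525.537, cutoff B = 404.137
#>   stratified log-rank chi2 = 3.6072 (df 1), p = 0.05753
```

The scan's naive minimum p (0.0019) looks overwhelming; the honest
cross-validated p for the same cohort is 0.058 — the difference is exactly
the selection effect the cross-validation corrects.  Downstream, the
dichotomized marker enters a multivariate Cox model with the standard
clinical covariates:

```r
grp <- dichotomize(co$dplt, optimal_cutpoint(prof))
xd <- as.data.frame(co); xd$dplt_group <- grp
fit_cox(encode_design(xd, default_covariate_spec())$x,
        co$pfs_time, co$pfs_event)
#> <cox_fit> n = 67, events = 54, ties = efron
#>   ...
#> 8  dplt_group=low 3.207 1.536-6.698 0.00192
```

i.e. low platelet recovery carries a ~3.2-fold hazard of progression after
adjustment, and the high group's 2-year progression-free survival
(`survival_rate_at(km_estimate(...), 24)`) is 37.0% in this replicate.

A command-line wrapper with `analyze` / `simulate` / `calibrate` / `scan`
verbs is installed at `inst/cli/survcutpoint.R`.

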