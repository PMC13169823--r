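---
title: "Methods: building and validating OCMB triage rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and validating OCMB triage rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocmbtriage)
```

## The clinical problem and the model

Oligoclonal IgM bands (OCMB) in cerebrospinal fluid evidence intrathecal
IgM synthesis, a marker of interest in multiple sclerosis, but their
detection by isoelectric focusing and immunoblotting is laborious and
restricted to specialized laboratories. Two automatable indices are
informative surrogates: the IgM index and the free kappa light chain index,
each the CSF/serum quotient of the analyte divided by the albumin quotient
$Q_{Alb}$,

$$\mathrm{IgMi} = \frac{IgM_{CSF}/IgM_{serum}}{Q_{Alb}}, \qquad
  \mathrm{FKLCi} = \frac{FKLC_{CSF}/FKLC_{serum}}{Q_{Alb}}, \qquad
  Q_{Alb} = \frac{Alb_{CSF}}{Alb_{serum}}.$$

Both are dimensionless, so any consistent concentration unit works; the
package still canonicalizes everything to mg/L at the I/O boundary
(`read_cohort()` converts declared g/L or mg/dL columns) because mixed-unit
tables are a silent failure mode in practice.

The decision problem is *triage*, not diagnosis: flag patients whose index
values make OCMB positivity likely enough that the confirmatory test can be
skipped, and route everyone else to the usual OCMB determination. A flag is
raised when either marker reaches its cutoff,

$$\text{flag} \iff \mathrm{IgMi} \ge c_1 \;\lor\; \mathrm{FKLCi} \ge c_2,$$

with inclusive comparisons throughout. Because a missed flag only means the
patient receives the test they would have received anyway, the rule is
optimized for *confidence in the flag* — specificity and PPV — rather than
sensitivity. The test-sparing benefit is measured by PROM (percentage
reduction of OCMB measurements), the flagged fraction
$(tp + fp)/n$. Two identities tie the metrics together and are asserted as
package invariants:

$$\mathrm{PROM} = \mathrm{sens}\cdot\pi + (1-\mathrm{spec})(1-\pi), \qquad
  \mathrm{PPV} = \frac{\mathrm{sens}\cdot\pi}
  {\mathrm{sens}\cdot\pi + (1-\mathrm{spec})(1-\pi)},$$

with $\pi$ the OCMB prevalence. An OR rule's flagged set contains each
component rule's flagged set, so its sensitivity and PROM can only be at
least the best component's and its specificity at most the worst's
("OR-dominance"); this is also asserted on every evaluation.

## Fitting procedure

`ocmb_triage()` runs five stages.

1. **Panel derivation.** Indices are computed per patient; samples missing
   any of the six concentrations are dropped with a message (complete-pair
   analysis, no imputation). $Q_{Alb} > 0.05$ warns but does not exclude —
   no plausibility-based exclusion rule is applied.
2. **ROC analysis.** Each marker's empirical ROC curve sweeps the inclusive
   rule `score >= t` over all unique values plus an `Inf` sentinel. The AUC
   is the Mann–Whitney statistic (mid-ranks, so ties count one half), whose
   trapezoidal-area equivalence is a tested invariant. Confidence intervals
   use DeLong's structural-components variance on the plain probability
   scale, clipped to $[0,1]$ — no logit transform, matching common ROC
   tooling defaults — and the two correlated AUCs are compared with the
   paired DeLong test.
3. **Cutoff selection.** Per marker, among operating points with
   specificity *strictly* above `min_specificity` (default 0.85), the
   threshold with maximal sensitivity wins; ties break toward higher
   specificity, then the higher threshold. The winner is snapped *up* to
   the next multiple of a clinical grid (defaults 0.05 for IgMi, 25 for
   FKLCi) — rounding up only shrinks the flagged set, so the specificity
   constraint survives snapping, which is re-verified anyway. Snapping
   reproduces the round cutoffs clinicians actually quote; pass
   `snap_* = NULL` for raw thresholds.
4. **Rule grid.** The default candidate set per marker is the selected
   cutoff and one grid step tighter, giving four OR models (labeled A–D)
   plus the four single-marker rules for reference. Metrics carry exact
   Clopper–Pearson 95 % intervals (beta-quantile closed form) — the
   conservative convention for small diagnostic cohorts; Wilson intervals
   are available via `ci_method = "wilson"`. PROM is reported without an
   interval.
5. **Selection.** The optimal OR rule maximizes specificity, then PPV, then
   PROM, with a deterministic name tie-break. This lexicographic criterion
   formalizes the preference for a trustworthy flag over raw test sparing;
   it is deliberately a plain, swappable ranking — `select_optimal()`
   accepts any table with those columns, including externally published
   metric tables.

## The synthetic-cohort generator

No patient-level data ship with the package, so `simulate_cohort()`
generates cohorts with the statistical structure the analysis assumes.
Index distributions in real cohorts are right-skewed and non-normal with
higher medians in OCMB-positive patients; the generator therefore models
$(\log \mathrm{IgMi}, \log \mathrm{FKLCi})$ as bivariate normal with shared
within-class covariance, correlation $\rho$, and a pure location shift
$\delta$ for the positive class. This is the simplest structure consistent
with those features that still has a closed-form AUC,
$\Phi(\delta/\sqrt{\sigma_+^2+\sigma_-^2})$ (`binormal_auc()`), making exact
calibration possible: `calibrate_delta()` inverts it, and the default
shifts are calibrated to marker AUCs of 0.71 (IgMi) and 0.64 (FKLCi).
$Q_{Alb}$ and the three serum concentrations are independent log-normals,
and CSF concentrations are back-computed (`backfill_concentrations()`) so
that the derived indices reproduce the drawn ones exactly — a round-trip
tested to 1e-9 relative tolerance.

Defaults (all overridable in `cohort_params()`): cohort size 97 with OCMB
prevalence 54/97 and the AUC targets above, which anchor the generator to a
reported clinical cohort; the rest are field-plausible conventions chosen
once — unit log-sd for both indices, $\rho = 0.5$ (a moderate correlation;
reports note significance but rarely a coefficient), OCMB-negative medians
IgMi 0.08 and FKLCi 60 (sitting below typical decision cutoffs), $Q_{Alb}$
median 0.005 (log-sd 0.3), serum medians 42 000 / 1 000 / 15 mg/L for
albumin, IgM and FKLC (log-sd 0.25), and a disease-activity flag with
probability 81/97. Class assignment is Bernoulli by default so the positive
count is properly random; `fixed_counts = TRUE` reproduces an exact split.

What the generator does *not* emulate: assay measurement error and
detection limits, the dependence of IgM synthesis on disease activity or
subtype (CIS vs RRMS), heavy tails beyond log-normality, and any
$Q_{Alb}$–index dependence. Passing tests therefore demonstrate the
*methods* are correct and calibrated under a realistic generating model,
not that a particular published cohort's cutoffs transfer to new
laboratories.

## Numerical choices and edge cases

- **Percentages** in reports round half away from zero (55.67 → 56), the
  convention that matches clinical tables; raw fractions are always kept in
  machine-readable output. Medians/IQRs use type-7 (linear interpolation)
  quantiles.
- **Degenerate DeLong variance** (all scores tied, or perfect separation)
  yields `se = 0` with a warning and a `degenerate` flag rather than an
  error; the paired test returns $p = 1$ when both the AUC difference and
  its variance vanish.
- **Zero denominators** (e.g. PPV when nothing is flagged) are reported as
  `NA` with the metric named in the report's `undefined` field.
- **No feasible cutoff** (no operating point strictly exceeds the
  specificity floor) is an error naming the constraint — the caller must
  relax the floor, not receive a silently invalid rule.
- **Grid snapping** uses `ceiling(t/g - 1e-9) * g` so that thresholds
  already on the grid are not pushed a step further by floating-point
  noise. Without a grid, the second candidate cutoff is 1.5× the first.
- `simulate_cohort()` restores the caller's RNG state, so seeded pipelines
  compose deterministically; identical configuration and seed give
  byte-identical pipeline artifacts (a tested contract).

## Validation strategy and problem sizes

The test suite checks every operation against an independent route: the
rank-based AUC against an explicit pairwise-counting oracle (dozens of
random small cohorts with ties); constrained cutoff selection against
brute-force enumeration of all operating points; DeLong variances and
paired p-values against the pROC implementation; Clopper–Pearson bounds
against `binom.test`; the closed-form binormal AUC against numerical
quadrature. Distributional claims use Monte Carlo at sizes chosen to make
the sampling error a small fraction of the tolerance: marginal and
correlation recovery at $n = 10^5$; prevalence over 2 000 seeded cohorts;
AUC calibration over 300 cohorts (tolerance 0.02); DeLong interval
coverage and null rejection over 2 000 replicates at the 54/43 class split;
binomial coverage over 10 000 draws at $n = 43$. The acceptance script
averages 10 000 replicates per marker for the calibration check, where the
Monte Carlo standard error of the mean AUC is about 0.0005 — well inside
the two-decimal reporting precision.

## Known limitations

- The lexicographic selection criterion is one reasonable formalization of
  "prefer specificity and PPV"; cost-weighted or utility-based selection is
  out of scope but pluggable through `select_optimal()`'s table interface.
- Cutoffs are selected and evaluated on the same cohort; no internal
  cross-validation or optimism correction is provided, so reported metrics
  are apparent performance. For transfer to a new laboratory the rule
  should be re-fitted or externally validated.
- PROM carries no confidence interval by design (none is conventionally
  reported for it).
- Only two markers and OR combination are supported; richer model classes
  (logistic regression, more markers) are deliberately out of scope.
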