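---
title: "Multi-marker genetic risk scores for incident CHD: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-marker genetic risk scores for incident CHD: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grsCHD)
```

## The problem

Weighted multi-locus genetic risk scores (GRS) summarise a person's burden
of common coronary-artery-disease risk alleles as

$$\mathrm{GRS} = \sum_{i=1}^{n} \beta_i \cdot \mathrm{SNP}_i + 0.131 \cdot H,$$

where $\mathrm{SNP}_i \in \{0,1,2\}$ counts copies of variant $i$'s effect
allele, $\beta_i$ is the published per-allele log-hazard weight, and $H$
indicates carriage of the four-SNP *ALOX5AP* haplotype B
(rs10507391-A, rs93155050-A, rs17222842-G, rs17216473-A), scored as one
unit with its own weight 0.131. Two score compositions are supported:
a 12-marker score (8 variants chosen for independence from classical risk
factors, plus the haplotype) and a 51-marker score (47 variants plus the
haplotype). The package evaluates what such scores add to the Framingham
Risk Score (FRS) for predicting incident coronary heart disease (CHD) in
cohorts of African, Latino and East-Asian ancestry: per-stratum Cox model
suites, fixed-effects meta-analysis across strata, discrimination,
calibration, reclassification, and a screening number-needed-to-treat
(NNT) calculus.

## Score construction

Dosages are accepted as hard genotype calls (`GT`) or imputed dosages
(`DS`); imputed values are converted to best-guess genotypes by rounding
to the nearest integer, with halves rounded away from zero. Variants are
matched to weights by rsid, and dosages are re-oriented onto the effect
allele (`d -> 2 - d` when the counted allele is the other allele).
Palindromic A/T and C/G variants cannot be strand-resolved without a
frequency hint and are rejected in strict mode. Variants whose imputation
$r^2$ is below 0.85 are excluded from scoring at read time and logged.

Missing genotypes are never silently zeroed. If more than 10% of an
individual's scored variants are missing, the score is `NA`; otherwise a
missing dosage is imputed as twice the effect-allele frequency of the
non-missing samples at that variant, which keeps scores on a common scale
without renormalising the weight sum.

Because unphased data cannot confirm that the four haplotype alleles sit
in *cis*, the haplotype term defaults to **presence** (1 if every member
carries at least one effect allele) and offers `min_dosage` (the minimum
oriented dosage, an upper bound on the copy number) as a documented
approximation; a homozygous carrier contributes 0.131 under presence and
0.262 under `min_dosage`.

Scores are standardised (mean 0, SD 1, denominator $n-1$) and cut into
tertiles *within ancestry group* (type-7 quantiles at 1/3 and 2/3; values
tied with a cut point go to the lower tertile), so "per SD" and "tertile
3 vs 1" always refer to a person's own ancestry distribution.

## Framingham 10-year risk

Baseline 10-year CHD risk uses the sex-specific *categorical* Wilson
equation: age (linear, plus a quadratic term in women) and coefficients
for total-cholesterol, HDL-C and blood-pressure categories (the higher of
the SBP and DBP category governs), diabetes and current smoking, mapped
through $p = 1 - S_0(10)^{\exp(L - \bar L)}$. The coefficients ship as a
checksummed CSV (`inst/extdata/wilson_frs_coefficients.csv`) and a user
file with the same layout can be substituted. Observed blood pressure is
used as measured; treatment flags enter only the fully adjusted Cox tier.
Risks map to four categories with left-closed boundaries — [0, 0.10) low,
[0.10, 0.15) intermediate-low, [0.15, 0.20) intermediate-high,
[0.20, 1] high — so 10% is intermediate-low and 15% intermediate-high,
exactly.

## Survival evaluation

**Cox suites.** Eight models cross the score form (per SD; tertiles with
the lowest tertile as referent) with nested covariate tiers: (a) ancestry
PCs only (6 by default), (b) + the individual FRS components, (c) + family
history, (d) + education, BMI, treatment flags and alcohol. Ties use the
Efron approximation — the natural choice for EHR-scale data with shared
event dates. Monotone likelihood (separation) for the score is reported
distinctly from non-convergence.

**Proportional hazards** are checked by adding a score-by-time
interaction (`tt()` term); its Wald p-value is flagged below 0.10.

**Discrimination** is Harrell's C (censoring-aware comparable pairs, risk
ties counted 0.5, computed via `survival::concordance`); the p-value for a
difference in C between nested models is a paired bootstrap over subjects,
since no analytic test is implied by the reporting format.

**10-year horizon.** Follow-up averages ~8.7 years, so all 10-year
quantities are extrapolated: the Kaplan-Meier (or baseline-hazard) curve
is extended beyond the last observed time under a constant hazard equal to
the average cumulative-hazard increment over the final observed year. This
rule is the package's own choice; any smooth tail assumption would do, and
the extrapolated segment is never more than ~1.3 years at the defaults.

**Calibration** uses a Hosmer-Lemeshow statistic over deciles of predicted
risk with Kaplan-Meier observed events per bin,
$\sum_b (O_b - E_b)^2 / (E_b(1 - E_b/n_b))$ on `bins - 1` degrees of
freedom (9 with the default 10 bins). Empty bins arising from tied risks
are merged with a neighbour and the realised bin count reported.

**Age-adjusted rates** per score tertile come from Poisson regression
with a log person-time offset, predicted at the cohort mean age.

## Reclassification metrics

The 4x4 reclassification table counts subjects by (baseline category,
updated category); each cell's expected 10-year events are its size times
the cell's own KM event probability, following the expected-events
convention for censored data. The categorical NRI is
$P(\mathrm{up}\mid\mathrm{event}) - P(\mathrm{down}\mid\mathrm{event})$
plus the reverse contrast for non-events, with event and non-event masses
taken from those KM-expected events. The IDI is the change in
discrimination slope, with subject-level fractional event weights: 1 for
observed events by year 10, 0 for subjects followed event-free past 10,
and the conditional KM event probability for subjects censored earlier.
On censoring-free data both metrics reduce exactly to their
direct-counting definitions, which the test suite exploits.

Confidence intervals are percentile bootstrap (default B = 1000),
recomputing the metric end-to-end — including every KM step — on each
resample, so the intervals reflect KM uncertainty.

**Intermediate-risk NRI bias correction.** An NRI computed on the subset
at intermediate *baseline* risk is biased upward: subjects near a
category boundary move under any refit, and events sit nearer the upper
boundary. The correction implemented here estimates that null movement by
refitting the base model on bootstrap resamples (default 100), scoring the
original cohort, recomputing the subset NRI against these null updates,
and subtracting the average, component-wise. The published description of
this correction is a citation, not a formula; this resampling null is the
package's stated interpretation, and single-draw corrected values retain
the considerable sampling noise of the KM-based NRI itself (SD ~0.1 when
the intermediate subset holds only a few dozen events).

## Meta-analysis

Per-ancestry hazard ratios are pooled on the log scale by inverse-variance
fixed effects (the strata come from a single source population), with
$se = (\ln \mathrm{UCL} - \ln \mathrm{LCL}) / (2 \times 1.959964)$
reconstructed from printed CIs; Cochran's Q, its p-value and $I^2$
quantify heterogeneity. The package uses $z = 1.959964$ internally and
rounds only at report time; reconstruction from 2-decimal published CIs
reproduces the published combined rows to print precision, which the
acceptance checks verify.

## Screening utility

For one stratum, the one-stage arm treats all subjects at intermediate
baseline risk (A subjects, B KM-expected 10-year events among them); each
two-stage arm treats only subjects a score up-reclassifies out of the
intermediate categories. Assuming statins prevent 24% of events
(configurable), the published arithmetic is followed literally and in
order: C = B x 0.24 rounded half-up to 1 decimal, then NNT D = A / C
rounded to the nearest integer, then efficiency = one-stage D / arm D to
1 decimal. Some published one-stage NNT cells are not reproducible from
their printed A and B under any standard rounding (they were evidently
computed from unrounded internal totals); the package reports its computed
values rather than matching those cells.

## The synthetic-cohort generator

Real individual-level data are not deposited, so every stage is exercised
on synthetic cohorts with the structure the analyses assume:

* **Genotypes**: independent Hardy-Weinberg dosages
  $\mathrm{Binomial}(2, f)$; default frequencies are deterministic,
  evenly spaced over [0.1, 0.9]. The four haplotype members are drawn
  jointly: each of a person's two haplotypes is haplotype B with
  probability 0.15 (a typical *ALOX5AP* haplotype-B frequency), else a
  background haplotype whose per-member allele frequencies preserve the
  marginals (defaults 0.35/0.30/0.45/0.40).
* **Covariates**: per-ancestry truncated normals / Bernoullis matching the
  published baseline tables of the emulated multi-ethnic cohort (e.g. AFR
  SBP 128.9 +/- 15.6 mmHg, EA current smoking 3.0%); six standard-normal
  PCs. Covariates are independent given ancestry because only marginals
  are published; a correlation hook is deliberately out of scope.
* **Outcomes**: Weibull baseline (shape 1.2) times
  $\exp(\beta_{GRS} z + \mathbf{x}'\boldsymbol\gamma)$ with centred
  covariates, inverse-transform sampling, exponential dropout
  (0.0074/year) and administrative censoring at 9 years — jointly tuned
  to a mean follow-up near 8.7 years. The Weibull scale is calibrated
  numerically so ~4% of subjects have an event by year 9, matching the
  emulated cohort's 450/11,242. The default GRS effect is log(1.15) per
  SD, the pooled per-SD estimate.

Defaults reproduce the emulated study's shape: n = 11,242 split
2,089/4,349/4,804 across AFR/LAT/EA. What the generator does **not**
emulate: linkage disequilibrium beyond the single haplotype block,
PC-genotype coupling (admixture), covariate correlations, and
ancestry-specific allele frequencies. Passing tests therefore demonstrate
correctness of the statistical machinery under the assumed model, not
robustness to real-data violations of it.

A subtlety worth knowing: the PC-only Cox tier (Model 1a) estimates a
*marginal* score effect. Because the generator's hazard also depends on
risk factors (independent of the score), non-collapsibility of the Cox
model attenuates the marginal per-SD hazard ratio slightly below the
conditional generating value (about 1% at the defaults) — visible in
large parameter-recovery runs, and expected behaviour, not a defect.

## Numerical choices

* Tertile cuts: type-7 interpolated quantiles, ties to the lower bin.
* Half-up rounding (`roundHalfUp`) in the screening table, matching the
  published arithmetic; everywhere else values are rounded only at
  report time.
* Best-guess dosage: nearest integer, halves away from zero, clamped to
  [0, 2].
* Degenerate inputs are defined errors, not NaN: zero within-group score
  variance, all-equal scores, empty weight tables, zero expected events
  in the NRI, NNT at zero events prevented, KM horizons beyond data with
  extrapolation disabled.
* Bootstrap replicates that fail (e.g. an empty category after resampling)
  are dropped; more than 20% failures aborts with diagnostics.
* All simulation entry points are deterministic given the configuration
  seed; derived seeds stay below $2^{31}$.

## Problem sizes in the test suite

The suite checks operating characteristics at sizes chosen to keep Monte
Carlo error well inside the asserted tolerances: oracle equivalences on
15-20-subject fixtures (exhaustive enumeration), null CI coverage on 200
replicates of n = 1,500, parameter recovery on 20 cohorts of n = 20,000,
and reclassification nulls on 200 resampling replicates of an n = 4,000
cohort. The pipeline smoke tests run n = 2,400 with reduced bootstrap
depth.

## Limitations

The shipped 51-variant weight table is a synthetic stand-in (the real
supplement's weights are not redistributable here): rsids and weights are
invented except the four haplotype members and the four variants excluded
for imputation quality. Analyses of real cohorts should supply the actual
published weight table in the same TSV layout. The Paynter-Cook-style
correction is an interpretation (see above); continuous NRI,
competing-risks models, time-varying effects beyond the PH diagnostic,
random-effects meta-analysis and the Pooled Cohort Equations are
deliberately out of scope.
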