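---
title: "Monthly opioid-misuse indicators and segmented interrupted time-series analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monthly opioid-misuse indicators and segmented interrupted time-series analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opioidits)
```

## The problem

Health-system interventions against prescription-opioid misuse — drug
monitoring systems, reporting mandates, reimbursement rules — are rolled
out at a known calendar date, not randomized. The standard
quasi-experimental tool for evaluating them from routinely collected
claims is the interrupted time series (ITS): an outcome is aggregated
monthly over several years, and a segmented regression asks whether the
intervention month brought an immediate jump in the outcome's *level*
and/or a bend in its *trend*, against the counterfactual of the
pre-intervention line continuing undisturbed.

`opioidits` implements that pipeline end to end for outpatient pharmacy
claims: cohort selection from patient and prescription tables, four
monthly misuse indicators, and a two-interruption segmented regression
with autocorrelation-aware inference. Because national claims extracts
are not redistributable, the package also includes a synthetic claims
generator whose monthly indicator prevalences follow a configurable
segmented linear model, so the entire pipeline is testable — and its
statistical properties measurable — without any restricted data. The
reference configuration throughout is a 60-month window (January 2016 –
December 2020) with a narcotics-monitoring-system rollout opening month
29 (May 2018) and a second interruption for the COVID-19 outbreak
opening month 50 (February 2020).

## The model

For month $t = 1, \dots, n$ the outcome $Y_t$ (a monthly percentage) is

$$Y_t = \beta_0 + \beta_1\,t + \beta_2\,I_1(t) + \beta_3\,s_1(t)
      + \beta_4\,I_2(t) + \beta_5\,s_2(t) + \varepsilon_t,$$

where $I_k(t)$ is the level indicator of interruption $k$ (0 before its
month $m_k$, 1 from $m_k$ on) and $s_k(t)$ is the post-interruption
clock (0 before $m_k$, $t - (m_k - 1)$ afterwards, so it equals 1 in the
interruption month itself). $\beta_0$ is the baseline level, $\beta_1$
the baseline monthly trend, $\beta_2$/$\beta_4$ the immediate level
changes and $\beta_3$/$\beta_5$ the trend changes. The slope after the
first interruption is $\beta_1 + \beta_3$ and after the second
$\beta_1 + \beta_3 + \beta_5$ (`post_slope()`). Omitting $m_2$ gives
the one-interruption variant of the same model — a configuration switch
(`build_design(n, m1)`), not a separate code path.

Errors are either independent Gaussian or a stationary first-order
autoregression $\varepsilon_t = \rho\,\varepsilon_{t-1} + u_t$. The
estimator is chosen by the data: `fit_its()` first fits ordinary least
squares, tests the residuals for serial correlation with the
Durbin-Watson statistic, and refits by exact AR(1) maximum likelihood
when the test rejects at `alpha` (default 0.05). The OLS Durbin-Watson
statistic is carried on the returned fit either way, since reports
conventionally print one D-W value per outcome.

### Numerical choices

* **Durbin-Watson p-value.** The statistic
  $d = \sum (e_t - e_{t-1})^2 / \sum e_t^2$ has a design-dependent null
  distribution. When the design matrix is available, the p-value uses a
  normal approximation matched to the *exact* null moments of $d$
  (the classical trace formulas $E[d] = \mathrm{tr}(AM)/(n-p)$ and the
  corresponding variance); this matters for ITS designs, whose trend
  columns shift the null mean of $d$ visibly away from 2. With only a
  residual vector, the cruder $d \sim N(2, 4/n)$ limit is used, and a
  permutation bootstrap is available as `method = "bootstrap"`. At the
  60-month reference design the moment-matched test keeps the OLS
  branch in about 98% of independent-noise simulations and switches to
  AR(1)-ML in over 99% of simulations with $\rho = 0.7$.
* **AR(1) maximum likelihood.** The exact stationary Gaussian
  likelihood is profiled: for fixed $\rho$ the GLS coefficients and
  error variance have closed forms (via the Prais-Winsten transform for
  gapless series, or the Cholesky factor of the general
  $\rho^{|t_i-t_j|}$ correlation matrix when months have been dropped),
  leaving a one-dimensional profile maximized over
  $\rho \in [-0.99, 0.99]$ by golden-section search (tolerance 1e-8).
  Coefficient standard errors come from the GLS information matrix at
  $\hat\rho$, with large-sample normal p-values; OLS p-values use the
  exact $t$ reference on $n - p$ degrees of freedom. The fit matches
  `nlme::gls(..., correlation = corAR1(), method = "ML")` to 1e-6 in
  coefficients, $\rho$ and log-likelihood in the package's tests.
* **Missing months** are deleted listwise with a warning; remaining
  rows keep their true calendar $t$, so trends and the AR(1) covariance
  stay on the calendar clock rather than being re-indexed.
* **Degenerate designs.** Rank deficiency is reported with the names of
  the collinear columns (e.g. an interruption placed at month 2 makes
  the post-clock an affine function of time). A warning — not an error
  — is raised when fewer than 12 months precede or follow the first
  interruption, the usual adequacy rule for the evaluated intervention;
  the second interruption is treated as a control covariate and may
  open a shorter closing segment, as the reference configuration's
  11-month final segment does.

## The indicators

All four indicators share one monthly denominator: patients with at
least one outpatient opioid fill *starting* in that month. Fills are
dispensing events in claims, so a fill spanning a month boundary counts
its patient in the start month only — but it still contributes to dose
and overlap arithmetic in the month it spills into, for patients
independently present there.

* **High-dose treatment.** A fill supplies
  `units_per_day x unit_strength_mg x mme_factor` morphine milligram
  equivalents (MME) per day over its closed covered range
  `[start_date, start_date + days_supplied - 1]`; a patient's daily
  dose is the sum over fills active that day. A patient is high-dose in
  a month when the *maximum* daily dose over the month reaches 100
  MME/day (threshold inclusive). The maximum is the stricter, common
  monitoring convention; a mean-over-covered-days mode is available by
  configuration. Conversion factors live in an editable catalog
  (`default_opioid_catalog()`) covering the nine study molecules, with
  morphine fixed at 1; for the two transdermal patches the unit
  strength is read as a delivery rate (µg/h) with rate-to-MME factors.
* **Multiple providers.** At least 2 distinct prescriber identifiers
  among the month's fills, deliberately ignoring institutional
  affiliation — two prescribers in one hospital count.
* **Prescription overlap.** Per patient, days covered by ≥ 2 fills
  divided by days covered by ≥ 1 fill, clipped to the month and pooled
  across all catalog opioids. The monthly value is the mean of these
  ratios × 100 (the definitional form). Published period summaries
  often present a patient *count* instead, so an any-overlap proportion
  mode is always emitted alongside (`overlap_any_*`); the two
  presentations disagree by construction and neither is asserted as
  canonical.
* **Naloxone use.** Opioid users of the month with at least one
  naloxone record (the reserved drug code `NALOXONE`, which never
  enters MME or overlap arithmetic) in the same month, as an overdose
  proxy.

Values are kept at full precision in the series; reporting rounds
half-up to 2 decimals (`proportion_pct()`), the convention of published
result tables. A month with no opioid users yields flagged missing
values and a warning, and downstream fits drop it listwise.

Cohort selection retains adult (≥ 20 years) outpatients carrying at
least one musculoskeletal/connective-tissue diagnosis (ICD-10 chapter
M) and no cancer diagnosis (C00–C97) at any time in the window — the
conservative reading, since claims do not reliably date diagnosis
onset. Age uses completed years at the calendar year of the first
in-window opioid fill, because claims carry birth year only. Diagnosis
matching is by code prefix on dot-free codes, robust to the varying
specificity of claims coding.

## The synthetic generator

The generator has two deliberately different tiers.

The **series tier** (`simulate_series()`) draws the monthly percentage
directly: the segmented mean plus stationary Gaussian AR(1) noise with
marginal standard deviation `noise_sd`. This is the tier for estimator
tests, where the Gaussian-AR(1) error model must hold *exactly* so that
deviations indicate implementation error, not model misfit.

The **record tier** (`simulate_claims()`) emits claims rows. Each month
it creates `patients_per_month` cohort patients and plants the four
behaviours with independent Bernoulli draws at the month's expected
prevalence: a high-dose patient's baseline fill is replaced by one at
≥ 120 MME/day (all other fills stay ≤ 40 MME/day, so even two
concurrent ordinary fills cannot cross 100); an overlapping patient
receives an exact duplicate of their baseline fill; a multi-provider
patient receives a day-disjoint second fill from a different
prescriber; a naloxone patient one naloxone record. Planted numerators
are returned as a truth table, and the indicator module recovers them
*exactly* — this equality, not approximate agreement, is what the tests
assert. Noise at this tier is binomial, not Gaussian: with monthly
cohorts of a few hundred patients and prevalences near 1%, the monthly
percentage has standard deviation
$100\sqrt{p(1-p)/n_{\text{month}}}$ — documented because estimator
benchmarks should use the series tier, while pipeline benchmarks use
the record tier.

Defaults are the study conditions: 60 months, interruptions at 29 and
50, generating coefficients at the published Table-2 magnitudes for all
four indicators, demographic mix at the published cohort totals (60.9%
female; age groups 12.5/33.1/34.6/19.8%; 9.1% MedAid-or-PVI; morbidity
26.1/46.6/26.1/1.2%), and `patients_per_month = 890`, the monthly
cohort size implied by the published pre-intervention period total
(24,924 patients / 28 months). Residual standard deviations are not
published; the defaults (0.20–0.30 percentage points, AR(1)
$\rho = 0.2$) were chosen once to resemble the scatter of the published
monthly series and are documented as arbitrary. Expected monthly
proportions are validated to stay within [0, 100] at construction,
before any sampling.

What the record tier does **not** emulate: real prescribing
epidemiology (drug-level market shares, dose titration, refill
persistence), within-patient correlation across months (each monthly
cohort is independent, patient identifiers are month-scoped), or
correlation between the four behaviours (independent draws). Passing
tests therefore demonstrate that the pipeline's arithmetic and
inference are correct under the stated statistical structure — not that
the indicators are clinically valid in any particular health system.

## What the test suite measures

Simulation sizes were chosen to balance Monte-Carlo resolution against
a default test run of about a minute: 500 replicates for
autocorrelation recovery at $n = 200$ (mean $\hat\rho$ within 0.05 of
0.5); 1,000 replicates for 95% CI coverage of all six coefficients at
the 60-month reference design (each within [90%, 99%]); 200
record-level replicates for end-to-end sign recovery of an injected
level change equal to 3 binomial standard deviations (≥ 95% correct
sign); and randomized fill sets (up to 10 fills × 60 days) checked
against a brute-force per-day coverage oracle for the overlap ratio.
Unbiasedness of series-tier recovery is asserted as a maximum
standardized bias below 3 across the 6 coefficients × 2 noise settings,
a family-wise-consistent bound: with twelve separate 2-standard-error
checks, an exactly unbiased estimator would spuriously fail about half
the time.

## Known limitations

* AR(1) is the only error structure; no seasonal terms, ARMA
  extensions, or heteroscedasticity-robust (Newey-West) alternatives.
  Residual ACF/PACF diagnostics (`residual_diagnostics()`) are provided
  for judging whether AR(1) suffices.
* The maximum-likelihood $\hat\rho$ carries the usual small-sample
  negative bias, larger with more regressors (about −0.03 at $n = 200$
  with four columns, matched by `nlme::gls`); inference on $\beta$ uses
  large-sample normal p-values under the AR(1) path.
* Interruption months are user-supplied; there is no change-point
  detection.
* The monthly-denominator convention (start-month membership) is one of
  several defensible readings of claims aggregation; it is configurable
  only by preprocessing the fills table.
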