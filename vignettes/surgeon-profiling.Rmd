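---
title: "Profiling surgeons with risk-adjusted Wilson funnel plots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling surgeons with risk-adjusted Wilson funnel plots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funnelprof)
library(dplyr)
```

## The problem

Orthopaedic quality registers increasingly feed outcome data back to
individual surgeons. Comparing surgeons naively on raw complication
proportions is unfair twice over: surgeons differ enormously in annual
volume (so low-volume surgeons' proportions are noisy), and they differ in
case mix (so surgeons operating sicker patients look worse). `funnelprof`
implements the standard register answer to both problems for binary
outcomes after primary total hip arthroplasty (THA): adverse events within
90 days of surgery (`ae90`) and reoperations of the same hip within 2 years
(`reop2y`), both consumed as precomputed binary flags.

## The funnel model

For one analysis stratum (a calendar year, or the pooled period), let
$p̄$ be the overall event proportion, and let surgeon $j$ have $n_j$
surgeries with $O_j$ observed events. Surgeon $j$'s observed proportion
$O_j/n_j$ is plotted against $n_j$ inside control limits centred on $p̄$.
The upper limit at denominator $n$ is the upper bound of the Wilson score
interval,

$$u(n) = \frac{p̄ + z^2/2n + z\sqrt{p̄(1-p̄)/n + z^2/4n^2}}{1 + z^2/n},$$

with $z$ the standard-normal quantile. The Wilson interval is obtained by
inverting the score test and is well behaved at small $n$ and small $p̄$ —
exactly the regime of low-volume surgeons and rare outcomes — which is why
it is preferred here over the normal approximation. A surgeon is *outside*
the funnel when the proportion strictly exceeds the upper limit; a value
exactly on the limit is inside. Two limits are drawn by convention: 95% and
99.8%, interpreted as two-sided conventions, i.e. $z = \Phi^{-1}(0.975)$
and $\Phi^{-1}(0.999)$ (`one_sided = TRUE` switches to one-sided tail
quantiles; only the two-sided convention is asserted in tests). Flagging
uses the upper limit only: the concern is poor performance, not unusually
good results. Flags nest by construction — anyone outside the 99.8% limit
is outside the 95% limit.

### The inversion variant

`funnel_config(method = "inversion")` offers the alternative reading of
"Wilson limits": the smallest observed proportion whose *lower* Wilson
bound exceeds $p̄$. By the score-test duality this has the closed form
$p̄ + z\sqrt{p̄(1-p̄)/n}$. The two readings agree at rate $O(1/n)$, but the
constant is not 1: the exact leading gap is $z^2(1-2p̄)/2n$, about $1.9/n$
at the 95% level and $4.8/n$ at 99.8% for small $p̄$. The test suite
asserts the correct bound ($z^2/n$) together with exactness of the
inversion (the lower Wilson bound evaluated at the limit returns $p̄$). The
Wilson-slot method is the default; neither is asserted to be the uniquely
correct reading.

## Risk adjustment and indirect standardization

Case mix is removed by indirect standardization. A logistic model of the
outcome on patient risk factors is fitted within the stratum
(`fit_risk_model()`, maximum likelihood via IRLS). Each surgeon's expected
event count is the sum of fitted probabilities over their patients,
$E_j = \sum_i \hat p_i$, and the standardized proportion is

$$\tilde p_j = \frac{O_j}{E_j}\, p̄ .$$

Because a logistic MLE with an intercept satisfies its score equations,
$\sum_j E_j = \sum_j O_j$ on the fitting stratum — a conservation identity
the tests check to $10^{-6}$ — and an intercept-only model reduces
standardization to the identity on observed proportions. Standardized
proportions may exceed 1 for extreme $O/E$; they are analysed as-is and
clipped only in plots.

Predictor sets follow register practice: all five recorded risk factors
(age, sex, ASA class, BMI, diagnosis) for 90-day adverse events; sex, ASA
and BMI for 2-year reoperation. Encodings (our choice; only the predictor
lists are given by register practice): age and BMI linear; sex as a male
indicator (reference female, the majority); ASA categorical with reference
I and grades III and IV merged — grade IV appears a handful of times per
year, so a separate level is a separation hazard; diagnosis as a
secondary-osteoarthritis indicator. Models are fitted per analysis stratum,
matching the stratum-specific $p̄$; fitting one pooled model and predicting
into years is *not* done, since it would break the conservation identity
within years.

Degenerate fits are errors, not silent results: a constant outcome raises a
degenerate-fit error, and (quasi-)complete separation is detected (divergent
coefficient plus fitted probabilities pinned at 0/1) and named. For
separation-prone small strata `fit_risk_model(firth = TRUE)` provides
Firth's Jeffreys-prior penalized fit, which keeps estimates finite; it is
never switched on silently.

## Inclusion rules

Three filters, each logged in the cohort's provenance and each idempotent:

* **Simultaneous bilateral collapse** — a patient receiving both hips on
  one day counts as one surgery. The two sides (linked by a
  `bilateral_group` token) are replaced by the first-listed record with
  each outcome the logical OR of the pair: an event on either hip is an
  event for the single exposure. OR is our choice — first-side-only and
  worst-side are defensible too, and nothing in register practice fixes
  it — chosen because the outcome definition ("any adverse event / any
  reoperation after the exposure") is naturally event-on-either-hip. Pairs
  naming two different surgeons are rejected rather than attributed
  arbitrarily. Staged (different-day) bilaterals are separate surgeries.
* **Complete-case filtering** — records missing any model covariate are
  dropped per outcome before fitting. This composes
  (`filter(A ∪ B) = filter(filter(A), B)`) and its removal counts
  reconcile exactly in the provenance log.
* **Annual volume threshold** — the sub-analysis restricted to
  higher-volume surgeons supports both readings found in register reports:
  strictly more than the threshold (`strict = TRUE`, the default) and
  at-least (`strict = FALSE`). Both are first-class because the two
  readings genuinely coexist in practice; neither is asserted as canonical.
  The pooled stratum is never volume-filtered — the threshold is an annual
  rule, and the pooled funnel is meant to show every surgeon.

The surgeons-at-risk denominators reported alongside annual count tables
are counted after complete-case filtering and before any volume filter, so
the count table's header matches the population actually classified in the
unrestricted analysis.

## The synthetic registry generator

Register data of this kind are person-identifiable and not shareable, so
the package carries its own generator (`generate_cohort()`) with known
ground truth. Its defaults emulate a six-year regional THA register:

| parameter | default | unit / meaning |
|---|---|---|
| `n_surgeons` | 208 | surgeons |
| `years` | 2011–2016 | calendar years |
| `volume_mean`, `volume_sd` | 27, 17 | surgeries/surgeon/year |
| `female_prop` | 0.59 | proportion |
| `age_mean`, `age_sd` | 69, 11 | years |
| `bmi_mean`, `bmi_sd` | 28, 5 | kg/m² |
| `asa_probs` | 0.25, 0.60, 0.145, 0.005 | ASA I–IV |
| `secondary_oa_prop` | 0.05 | proportion |
| `trainee_prop` | 0.09 | proportion |
| `miss_bmi`, `miss_asa` | 0.06, 0.025 | MCAR missingness |
| `target_rate_ae90` | 0.062 | marginal proportion |
| `target_rate_reop2y` | 0.018 | marginal proportion |
| `bilateral_prop` | 0.0045 | simultaneous-pair fraction |

Mean and SD of volume, the covariate marginals, missingness levels and the
two event rates reflect published register summaries; `age_sd = 11` and
`bmi_sd = 5` are our choices (the sources print means and ranges only) and
are ordinary values for THA populations. Volumes are rounded,
zero-truncated draws from a lognormal moment-matched to mean 27 / SD 17 —
registry volumes are right-skewed, and the lognormal leaves roughly 8% of
surgeon-years at 10 or fewer surgeries, so volume-threshold paths are
genuinely exercised.

Outcomes are Bernoulli draws from a logistic mechanism: record linear
predictor $x^\top\beta$ (true coefficients of realistic magnitude, with the
ASA III and IV coefficients equal so the merged analysis encoding is
correctly specified), an optional per-surgeon effect
$u_j \sim N(0, \sigma_u^2)$, and an intercept calibrated by monotone
root-finding (`calibrate_intercept()`, achieved rate within $10^{-8}$) so
the marginal rate hits its target exactly in expectation. With
$\sigma_u = 0$ (the default) every surgeon shares one conditional event
model — the in-control null that funnel false-flag rates are calibrated
against. Missingness is applied after outcome generation, so the
data-generating truth always uses complete covariates.

### Case-mix confounding

`case_mix_confounding = TRUE` gives each surgeon a latent severity score
$s_j \sim N(0, 1.5)$ that shifts their patients' ASA cumulative logits by
$-s_j$, BMI by $+2 s_j$ kg/m² and age by $+4 s_j$ years, while the
conditional outcome model stays common to all surgeons. The strength was
chosen from a variance analysis: it puts the between-surgeon spread of true
case-mix event risk near 0.4 on the logit scale — comparable to the spread
between referral and routine practices — which is the smallest order that
remains visible against binomial noise at annual volumes near 27 (at
volume 27 and rate 6.2% the surgeon-level logit noise SD is ≈ 0.8; a
case-mix spread an order smaller would be statistically invisible, and
standardization would have nothing to remove). Under this switch, observed
funnel flags are partly case-mix artefacts and indirect standardization
removes them on average; the simulation tests assert the direction of that
reduction, not a count.

### What the generator does not emulate

Covariates are drawn independently of each other (real age/ASA/BMI are
correlated); missingness is MCAR while real register missingness is
plausibly informative (concentrated in particular hospitals); there is no
hospital-level clustering beyond surgeon assignment, no time trend, and no
within-patient correlation for staged bilaterals. Passing tests therefore
demonstrate the statistical machinery under a faithful *marginal*
emulation, not the registry's joint distribution.

## Numerical choices

* Logistic fits: IRLS (`stats::glm`) with convergence tolerance $10^{-10}$
  and up to 100 iterations; Firth fits use Newton steps on the penalized
  score with step-halving, tolerance $10^{-8}$.
* Intercept calibration: `uniroot` on the mean-probability equation,
  tolerance $10^{-12}$, verified to $10^{-8}$ in the achieved rate.
* Ties at the control limit: inside (strict inequality for "above").
* Wilson corner cases: $p̄ = 0$ gives $z^2/(n+z^2)$; $p̄ = 1$ collapses to 1.
* No over-dispersion inflation of limits is applied, matching the practice
  this package models; with many surgeons and genuine extra-binomial
  variation the limits would flag more than the nominal fraction.
* Truncated-normal draws use quantile inversion (no rejection loops), so
  generated cohorts are bit-identical for a given seed and config across
  platforms with identical RNG (R's default Mersenne–Twister / inversion).

## Simulation sizes used in the test suite

The packaged simulation checks run at: 500 in-control replicates of the
208-surgeon single-year cohort for null false-flag calibration (nominal
upper-tail mass 2.5% and 0.1%; binomial discreteness at small $n$ makes the
Wilson limit conservative, so observed rates sit well below); 200
replicates of $n = 10{,}000$ for coefficient recovery (slope bias bound
0.02 on the logit scale — the intercept is excluded from the bias bound
because its sampling SE with uncentered age/BMI leaves Monte-Carlo noise of
≈ 0.03 at 200 replicates — and empirical 95% CI coverage in
$[0.92, 0.975]$); and 200 confounded replicates for the
observed-to-standardized flag reduction. These sizes give Monte-Carlo
standard errors an order below each asserted margin.

## Known limitations

Surgeon identity is treated as fixed labels (no blinding or linkage);
outcome windows (90 days, 2 years) are assumed already applied upstream, so
late-period cohorts with shorter follow-up are the caller's responsibility;
multiplicity across surgeons is not adjusted (none of the register feedback
systems this models does); and the standardized proportion's sampling
variance differs from the observed proportion's at the same $n$ (it scales
with $1/E_j$ rather than $1/n_j$), so plotting both against the same Wilson
limits — as register practice does — is a pragmatic convention rather than
an exact calibration for the standardized dots.
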