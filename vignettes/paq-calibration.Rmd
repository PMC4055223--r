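---
title: "Calibrating the PAQ against accelerometry: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating the PAQ against accelerometry: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paqcal)
```

## The measurement problem

The Physical Activity Questionnaire (PAQ-C for children, PAQ-A for
adolescents) is a 7-day recall instrument whose items are scored on an
ordinal 1–5 scale and averaged into a summary score. The score ranks
children by activity reasonably well but has no physical units, so it cannot
be compared against public-health guidelines expressed in minutes of
moderate-to-vigorous physical activity (MVPA). Regression calibration
resolves this by modelling a criterion measure — here, accelerometer-derived
percent of wear time in MVPA — as a linear function of the PAQ score and
demographics, then using the fitted equation to convert questionnaire output
onto the criterion scale.

`paqcal` implements the full workflow: accelerometer screening, PAQ scoring,
a 70/30 calibration/validation split, the OLS fit with its diagnostics,
conversion of predictions to weekly minutes, and agreement evaluation. A
synthetic-data module generates cohorts with the same statistical structure,
which is what the test suite and the acceptance script run on.

## The calibration model

For participant $i$,

$$\%MVPA_i = \beta_0 + \beta_1\,\mathrm{sex}_i + \beta_2\,\mathrm{age}_i +
\beta_3\,\mathrm{PAQ}_i + \varepsilon_i,\qquad
\varepsilon_i \sim N(0, \sigma^2),$$

with sex coded 1 = male / 2 = female (the published convention; note the
intercept therefore absorbs one sex unit relative to 0/1 coding), age in
whole years over 8–14, and PAQ rounded to one decimal place before entering
the model — `fit_calibration()` and `predict_pct_mvpa()` both apply that
rounding so fitted and published equations are used identically. The
reference coefficient set shipped in `inst/extdata/reference_coefficients.csv`
is $\beta = (14.56, -0.98, -0.84, 1.01)$ with residual RMSE
$\hat\sigma = 2.54$ percentage points.

Model assumptions worth stating: linearity of %MVPA in the PAQ score,
homoscedastic Gaussian residuals (checked by the Breusch–Pagan test), and
predictors measured without error — the last is knowingly false for a recall
instrument, so the equation is a *calibration* mapping, not a structural
model, and is only claimed to produce group-level estimates.

Diagnostics follow the standard definitions: $R^2 = 1 - SSE/SST$ (plain, not
adjusted), RMSE $= \sqrt{SSE/(n-4)}$ (the square root of the mean-square
residual of the regression ANOVA), Gaussian AIC
$= n\log(SSE/n) + 2k$ with $k = 5$ (four coefficients plus the variance;
only model-to-model differences on the same data are meaningful),
$VIF_j = 1/(1-R_j^2)$ from auxiliary regressions, and a
Lagrange-multiplier heteroscedasticity test in the studentized (Koenker)
form $LM = nR^2_{aux}$.

The Breusch–Pagan test is implemented in two variants because the auxiliary
design is a genuine free choice. `variant = "bp"` regresses squared
residuals on the three predictors (3 df). `variant = "white"` (the default)
adds squares and pairwise products and then drops every term that is aliased
with a column already kept, testing rank column by column. With binary-coded
sex, sex² is an affine function of sex, so the White design has 8 df for
this model — the df the published test reports — which is why `white` is the
default.

## Accelerometer screening rules

All parameters sit in `paq_config()`; defaults follow the study protocol.

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| day window | 08:00–21:00, half-open | clock time | 780 min of plausible awake time; avoids diluting %MVPA with sleep |
| non-wear bout | ≥ 90 | min | long enough not to misread seated classroom time as removal |
| allowance | ≤ 2 consecutive min at 1–100 | min, cpm | brief low-count noise inside a removal |
| valid day | ≥ 546 wear min (70% × 780), inclusive | min | see note below |
| valid week | ≥ 4 valid days, ≥ 3 weekdays, ≥ 1 weekend day | days | both day types must inform the weekly mean |
| MVPA floor | 4 | METs | standard youth moderate-intensity threshold |
| weekly base | 5,460 | min | 13 awake hours × 7 days |
| guideline | 420 | min/week | 60 min/day recommendation |

Two conventions deserve comment.

**The 70% valid-day threshold.** 70% of the 780-minute window is 546 minutes
(9.1 h), while protocol descriptions sometimes round this to "9.0 hours"
(540 min). The package takes 546, inclusive, as the exact reading of the 70%
rule and exposes `valid_day_minutes` so either convention can be run.

**Combining weekday and weekend %MVPA.** Strata are summarised separately
(means over valid days within stratum); the combined weekly outcome defaults
to the calendar-weighted mean $(5\,\text{wd} + 2\,\text{we})/7$, since that
is the quantity a full week of wear would produce. An unweighted mean over
valid days (`combine = "unweighted"`) is provided because published
protocols rarely state which rule they used; with equal stratum means the
two coincide.

**Minute aggregation.** The non-wear rule is stated in counts per minute, so
epoch pairs aligned to clock minutes are summed before the scan; an unpaired
edge epoch is dropped from the minute series (no minute value can be formed
for it) but still participates in epoch-level MVPA classification, where its
minute defaults to worn. Maximal candidate runs must start and end on
zero-count minutes; an interruption longer than the allowance, or any minute
above 100 cpm, terminates the candidate, and each maximal run is flagged
non-wear iff its total span reaches 90 minutes.

**Cut points.** The per-age counts-per-minute threshold inverts the
Freedson-age MET equation
$METs = 2.757 + 0.0015\,cpm - 0.08957\,age - 0.000038\,cpm\cdot age$
at the 4-MET floor, rounds to the nearest whole count, and halves it for
30-s epochs (age 10 → 1910 cpm → 955 counts/epoch). The equation is not
monotone-decreasing in age over 8–14 (it increases, reflecting the MET cost
model), which is why the package treats it as configuration: a user-supplied
`cutpoint_table` (age → cpm) overrides it verbatim.

## PAQ scoring

The summary score is the mean of the checklist item score (itself the mean
of the activity-checklist ratings, variable length) and the timed items: PE,
recess (PAQ-C only), lunch, after school, evening, weekend, and two weekly
pattern items — 9 scored items for PAQ-C, 8 for PAQ-A. A "sick last week"
item is ignored if present. Missing required items are a hard error naming
the item; no pro-rating is applied, because no imputation rule is part of
standard scoring. Scores are stored at full precision; the one-decimal
rounding is applied only where the score enters the calibration equation.

## Validation statistics

Predictions for the hold-out set are floored at 0 (the linear equation can
go negative for older, low-PAQ girls) and converted to weekly minutes via
the 5,460-minute base. The observed accelerometer outcome uses the same
%-based conversion by default so both instruments share one time base; a
raw-minutes mode (`mvpa_min_daily_mean × 7`) is provided, and the two agree
exactly at full window wear.

Agreement reporting combines the conventional choices that make the
published intervals internally consistent: limits of agreement use the fixed
1.96 normal multiplier on the SD of differences (n − 1 denominator), while
the 95% CI of the mean bias uses the $t_{n-1}$ quantile on the standard
error; the paired $t$ is mean bias over its standard error. Guideline
classification thresholds both instruments at 420 min/week and computes the
AUC by the rank (Mann–Whitney) statistic with ties counting one half — a
trapezoid-free formulation that is invariant under strictly monotone
transforms of the predictions. With all observations in one guideline class
the AUC is undefined and flagged rather than extrapolated.

## What the synthetic generator emulates

`generate_cohort()` draws integer ages uniformly over 8–14 (an explicit
weight table can skew younger, as school samples usually are), sex at 51%
male, season with a slight spring excess, and true PAQ scores from a normal
truncated to [1, 5] with age-group means 3.2 (ages 8–11) and 2.8 (12–14) and
SD 0.7 — younger children reporting more activity, matching the age gradient
such samples show. True weekly %MVPA is the calibration equation evaluated
at the drawn covariates plus $N(0, 2.54^2)$ noise, floored at 0 because a
percentage cannot be negative. That floor is the one place the generative
model deviates from the fitted one: it truncates roughly 1–2% of draws
(old/low-PAQ profiles) and biases naive moment recovery by about 1–2%,
which is why recovery tests are stated against replicate SDs, and why
sample moments are compared against the *truncated* distribution's
closed-form moments rather than the untruncated parameters.

`generate_epoch_trace()` renders a 7-day, midnight-to-midnight 30-s epoch
series per participant: zeros outside the day window (sleep), scheduled
all-zero non-wear blocks (one per day with probability 0.2, 90–150 min,
giving a mean wear time near 755 min/day), contiguous MVPA bouts of 2–10
minutes placed uniformly at random within wear segments (capacity-aware, so
a bout never overflows a segment), and light activity everywhere else with
per-minute counts in (100, cutpoint − 2] — above the allowance ceiling so
wear is unambiguous, and strictly below the epoch threshold so no light
epoch classifies as MVPA. Daily MVPA targets equal the participant's weekly
value by default (`day_sd_pct = 0`); day-to-day variability is exposed as a
parameter rather than asserted, since no empirical value for it is
established. Bout totals are rounded to the nearest epoch, so screening
recovers the generated %MVPA to well within half a percentage point.

`generate_paq_items()` produces integer 1–5 responses whose mean tracks the
true score; the per-item Gaussian perturbation is scaled by the distance of
the true score from the scale boundaries, so a participant at exactly 1 or 5
answers uniformly at the extreme regardless of the noise level. The
within-0.5 recovery of the summary score is therefore exact for small item
noise and holds for ~99% of draws at noise SD 0.5.

What the generator does **not** emulate: biomechanically realistic count
distributions (counts are uniform draws within the class-defining ranges),
spurious wear artefacts, seasonal activity differences (the season label is
carried but has no effect), reactivity or recall bias in the questionnaire,
and correlation between wear compliance and activity level. Passing
round-trip tests therefore demonstrates the correctness of the screening and
fitting machinery under the stated generating assumptions — not the field
validity of the calibration itself, which can only come from real paired
data.

## Numerical choices and degenerate inputs

- OLS is delegated to `stats::lm`; the test suite holds it to the
  normal-equations solution at 1e-10 and checks residual orthogonality.
- Collinear designs abort naming the aliased predictor; constant predictors
  abort before fitting; VIF of a perfectly explained predictor reports
  `Inf` with a warning rather than a misleading large number.
- The White auxiliary design drops aliased columns by testing whether each
  candidate column increases the QR rank of the design built so far —
  deterministic, order-stable, and exact for affine aliasing like sex².
- Epoch validation is strict (non-negative integer counts, constant 30-s
  spacing within a day) and errors name the offending file line. A
  vendor-style preamble can be skipped explicitly, never silently.
- Zero-wear days carry `NA` %MVPA; invalid weeks carry `NA` combined %MVPA
  and are excluded (with a logged reason) before modelling.
- Splits guarantee non-empty calibration and validation sets and refuse
  samples under 10; stratified splits hold the fraction within each stratum
  to ±1 participant.
- Bland–Altman statistics refuse fewer than 3 pairs; constant differences
  yield zero-width limits and an undefined paired $t$ (NaN), not an error.

## Problem sizes used by the tests

The acceptance-level checks use the study's own scale where that is cheap:
200 replicate cohorts of n = 103 for coefficient and RMSE recovery (about a
minute), 1,000 random day traces for the non-wear oracle comparison, and
1,000 homoscedastic replicates for the Breusch–Pagan size check. Cohort
moment checks run at n = 4,000, and full trace round-trips at 6 participants
× 7 days, which keeps the whole suite around two minutes without changing
any generating parameter.

## Known limitations

- The age-specific cut points are a configurable default, not a claim about
  which exact cut-point table any particular study used; results are
  sensitive to that choice.
- The calibration is cross-sectional and sample-specific: coefficients fitted
  on one cohort transfer to others only as far as the demographics overlap
  (here, ages 8–14).
- Individual-level prediction intervals are wide by construction (limits of
  agreement of hundreds of weekly minutes); the tool is for group-level
  estimation.
- Only uniaxial count data at 30-s epochs are supported; raw-acceleration
  formats, vector-magnitude processing and non-wear imputation are out of
  scope.
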