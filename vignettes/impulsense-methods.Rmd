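---
title: "Passive-sensing features and impulsivity prediction: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Passive-sensing features and impulsivity prediction: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(impulsense)
```

## The problem

Impulsivity — the disposition to act on short-term temptation at long-term
cost — is usually measured with questionnaires (BIS-15, UPPS) administered
once, or with lab tasks. Smartphones passively record behavioural traces
that plausibly carry the same signal: how often a phone is checked, when
calls happen, how battery charging is managed. `impulsense` implements a
complete analysis chain for this kind of study: ingest and clean durative
sensor event logs (calls, battery charging, screen unlock sessions), reduce
them to a compact behavioural feature set, and relate those features to
trait questionnaires (between-person analysis) and to daily self-reports and
mobile cognitive tasks (within-person, day-level analysis). A synthetic
cohort generator with known ground truth makes every stage testable without
access to participant data.

## Sensor streams and cleaning

Each sensor yields durative events `(start, duration)`. Two cleaning rules
are applied before any feature is computed:

* **Battery:** charging events strictly shorter than 10 s are removed.
  Cable jiggle and OS glitches produce ~1 s charging blips; a 10 s event
  survives. On the generator's default contamination this removes roughly
  16–17% of raw battery events.
* **Screen:** unlock sessions strictly longer than 2 h are removed, on the
  rationale that they reflect unrelated continuous use such as navigation;
  a session of exactly 2 h survives. This removes roughly 0.4% of events.

The strict reading of "shorter than"/"longer than" is deliberate and both
thresholds are arguments to `filter_battery()`/`filter_screen()`. Filtering
is idempotent, never reorders events, and reports the removed fraction.

## The 15 features

For each sensor, five statistics are computed over a time window (the whole
observation span for trait-level analysis; the 24 h preceding each morning
assessment for daily analysis):

| statistic | definition | units |
|---|---|---|
| `Use`  | total in-window event time / window length | h per h |
| `Freq` | events starting in the window / window length | 1/h |
| `Mean` | mean duration of events starting in the window | h |
| `SD`   | SD of those durations | h |
| `Ent`  | Shannon entropy of event starts over 24 hour-of-day bins | nats |

Three conventions matter and are applied consistently:

* **Windows are half-open** `[start, end)`; an event belongs to a window
  when its start lies inside. For `Use` only, durations straddling a window
  edge are clipped to the window, because `Use` measures occupancy; `Mean`
  and `SD` use the full durations of in-window events, because they
  describe the events themselves.
* **Entropy uses natural logarithms** and event *starts* only, binned by
  hour of day in the participant's local timezone. The maximum is
  `log(24) ≈ 3.178`; typical cohort values around 2.5–2.9 sit just below
  it, consistent with phone activity spread over most waking hours. A
  base-2 entropy would place the same behaviour implausibly far below its
  maximum of 4.585, which is why nats are the default (the base is an
  argument).
* **Missingness is explicit:** `Use` and `Freq` are genuinely 0 for an
  event-free window, while `Mean`, `SD` and `Ent` are `NA` there because
  their defining event set is empty.

## Trait pipeline

`run_trait_battery()` relates the 15 whole-study features to nine trait
scores (BIS-15 total + 3 subscales, UPPS total + 4 subscales):

1. **Correlations** (`correlate_traits()`): pairwise Pearson r with
   two-sided p values over complete cases.
2. **Sparse explanatory model**: features are standardized across the
   sample, the response centered, and the Lasso is fit at a single fixed
   penalty (0.05 on the `(1/2n)‖y − Xβ‖² + λ‖β‖₁` scale). Features with
   nonzero coefficients are refit by OLS (`ols_refit()`), reported with the
   conventional F statistic on `(k, n − k − 1)` degrees of freedom and
   adjusted R².
3. **Out-of-sample validation** (`loso_svr()`): leave-one-subject-out
   linear support vector regression (C = 1, ε = 0.1 — unremarkable defaults
   for standardized predictors, both configurable), with standardization
   statistics and (by default) Lasso re-selection learned inside each
   training fold. Performance is the MAE and the Pearson correlation
   between held-out predictions and true scores.

**Inference caveat.** The p values of the OLS refit are naive
post-selection values. With n = 26 and a weak penalty, selection feeds the
F test its own favourite features: on null synthetic cohorts the nominal
5% model-level F test fires about 30% of the time. The package reports
these p values (they mirror common practice and the explanatory summary)
but the calibrated discovery test is the LOSO stage: on null cohorts the
rate of positive, significant LOSO correlations is close to the nominal 5%.
This is also how the acceptance suite evaluates false-positive control.

## Daily state pipeline

`run_state_battery()` treats each of 23 daily outcomes (five present-moment
semantic differentials in the morning and evening, five previous-day
differentials, two affect scores, six task metrics) the same way:

* **Gaussian GEE with exchangeable working correlation** (`fit_gee()`),
  clustered by participant. No GEE package is assumed: the estimator is
  the standard one — GLS coefficient updates under the working correlation,
  a moment estimator of the exchangeable correlation from Pearson-residual
  cross-products, and a robust sandwich covariance. With an independence
  working structure the point estimates coincide with pooled OLS (tested),
  and with one observation per cluster the fit degenerates to ordinary
  regression. The estimated working correlation is reported as the
  "within-group correlation"; model fit is summarised by the in-sample
  Pearson r between marginal fitted values and observations.
* **Median-split classification**: outcomes are binarized at the pooled
  median (strictly-greater → 1, so label prevalence never exceeds 1/2,
  and labels are invariant to monotone transforms), then a logistic
  regression is trained leave-one-subject-out and scored per held-out
  individual (`loso_classify()`).

**In-sample r caveat.** The reported r is an in-sample quantity. With 15
covariates and 26 clusters, coefficient noise — amplified by the large
between-person spread of the features — produces a null distribution of r
with a standard deviation around 0.15–0.25 for high-ICC outcomes. An
outcome with no true feature link can therefore test "significant" by this
statistic in a single cohort. The test suite's end-to-end check asserts the
expected dissociation (linked outcomes significant, deliberately unlinked
impulsivity items null) and is allowed to flag this known fragility rather
than hide it; across seeds the unlinked items are markedly less significant
than the linked ones, but not reliably above p = .05.

## Mobile task simulators

Three mobile cognitive tasks are generated and performed by parameterised
agents (`agent_params()`), providing day-level behavioural metrics with
known generative structure.

* **Go/no-go** (`generate_gng_session()`, `simulate_gng()`): 75 trials of
  fixation (250 ms), blank (250 ms), a horizontal or vertical cue at one of
  six stimulus-onset asynchronies (100–750 ms), then a go or no-go target
  for up to 500 ms, and a 250 ms intertrial interval. Cues are uniform;
  the target matches its cue with probability 0.70 (horizontal signals go).
  The agent misses go targets at its omission rate, responds to no-go
  targets at its commission rate, and draws latencies from a normal
  distribution truncated to (0, 500] ms. Task summaries in this literature
  sometimes label commission as "go" errors and omission as "no-go"
  errors — the
  reverse of convention; the simulator uses the conventional definitions
  and offers a label-swap flag rather than asserting either reading.
* **Delay discounting** (`run_mdd()`): five adaptive choices between an
  immediate amount and a fixed delayed reward, following the standard
  adjusting-amount staircase — start at half the delayed amount, then move
  away from each choice with steps halving each trial (A/4, A/8, A/16,
  A/32). The agent values delay hyperbolically, `A/(1 + k·delay)`, with
  optional logistic choice noise. The staircase's indifference estimate
  provably converges to within one final step of the hyperbolic present
  value and is monotone in k. The *present bias* (fraction of immediate
  choices) is only coarsely monotone in k: it counts immediate choices
  along a binary-search path, and the path re-orders around cell
  boundaries (e.g. with A = 20, delay = 30: k = 0.027 yields 0.6 but the
  larger k = 0.042 yields 0.4). This is a property of any adaptive
  staircase, not of the implementation.
* **Balloon risk task** (`simulate_bart()`): 15 balloons, explosion point
  uniform on `{1..10}`, reward 4.13 per surviving pump; the agent aims for
  a noisy target pump count. The defaults were chosen so a typical agent
  produces mean pumps near 3.9 and mean per-trial gains near 10.3, with
  mean truncated latencies near 424 ms for the go/no-go agent; the uniform
  explosion model gives the closed-form expected gain
  `pay · n · (1 − n/max_pumps)` for a fixed policy of n pumps, which the
  test suite checks by simulation.

## The synthetic cohort generator

`generate_bundle()` produces a complete study: 26 participants × 21 days by
default, with traits, raw streams, cleaned streams, daily features, and
daily outcomes. Its structure:

* **Traits** are multivariate normal across seven subscales (exchangeable
  correlation 0.3), clipped to the 1–4 instrument range, with instrument
  totals as subscale means — which reproduces the reference total-score
  moments without extra parameters.
* **Event streams** are inhomogeneous Poisson processes. Each participant
  gets an event rate and a duration scale (lognormal across participants),
  a circadian hourly profile, and day-to-day lognormal jitter of both rate
  and duration scale. Durations are lognormal within person. Spurious
  events (sub-10 s battery blips, >2 h screen sessions) are added so that
  the cleaning filters operate at realistic removal fractions.
* **Entropy control.** Rather than tuning a concentration parameter until
  entropies look right, each participant receives an occurrence-entropy
  *target* (normal across participants), and their hourly profile is
  solved directly — a mixture of the uniform distribution and a peaked
  circadian template, with the mixing weight found by bisection (entropy
  is strictly decreasing in the weight). Because the observed plug-in
  entropy of N events is biased low by roughly `(24−1)/(2N)`
  (Miller–Madow), the solver targets the intended *observed* entropy plus
  that allowance.
* **Calibration targets.** Default rates, duration scales, and entropy
  moments are set so cohort feature means land on the package's calibration
  surface (battery usage 0.30 h/h, call frequency 0.38/h, screen frequency
  1.97/h, screen entropy 2.89, …). One arithmetic fact forces a choice: a
  usage target of 0.30 h/h is inconsistent with a 0.20/h frequency target
  times a ~2 h mean-duration target unless frequency and duration are
  negatively correlated across participants. For screen checking the
  generator keeps the reference duration moments and solves a strongly
  negative log-scale residual correlation (frequent checkers have shorter
  sessions — also what makes screen *usage* the cleanest single carrier of
  a planted usage effect). For battery and call it instead rescales the
  duration targets to be product-consistent (e.g. battery mean duration
  1.50 h), because the forced anticorrelation there would turn battery
  usage into a low-noise shadow of battery frequency and destabilise the
  planted multivariate signature.
* **Planted trait links.** Sensation seeking shifts battery log-rate (+),
  screen log-rate and log-duration (+, jointly loading screen usage),
  call entropy targets (−), and battery entropy targets (+0.48 — the
  correlation-analysis anchor). Motor impulsivity loads screen entropy,
  urgency loads call entropy negatively, and nonplanning/perseverance load
  the screen duration scale. Link magnitudes for the sensation trio were
  chosen so that the three-feature signature (battery frequency +, screen
  usage +, call entropy −) is identifiable by the Lasso→OLS pipeline in at
  least ~90% of 26-participant cohorts; this places the synthetic
  sensation model at the strong end (adjusted R² ≈ 0.7) of what a cohort of this size could exhibit. Identifiability, not effect-size mimicry, is the
  design goal, since all three features proxy a single latent trait and
  weaker links make the multivariate signs unrecoverable at n = 26.
* **Daily outcomes** are participant random intercept + a scaled link to
  that day's standardized features + noise, clipped to the instrument
  range, with per-outcome feature-variance shares and intraclass
  correlations from the package's per-outcome calibration table. The
  present-moment and previous-day "intentional–impulsive" items carry *no*
  feature link by default, so a correctly behaving pipeline must report
  them as null. Task
  metrics run the simulators with agent parameters derived from traits
  (discount rate increasing in trait impulsivity) plus a day-level feature
  link (strongest for the discounting task).
* **Seed policy.** A master seed spawns per-participant substreams for
  traits, person-level parameters, events, and outcome noise, so enlarging
  the cohort never perturbs existing participants. Bundles are
  bit-reproducible under a fixed seed.

## What the synthetic cohort does and does not show

Passing tests on synthetic cohorts demonstrate that the pipelines recover
what the generator plants, control false positives at the stated rates,
and never leak held-out data. They do not demonstrate that real phone
behaviour carries these signals. Known divergences from real data:

* Participant random intercepts of the daily outcomes are independent of
  the features; only day-level links are planted. Real cohorts show
  between-person alignment too, so median-split accuracies reported
  for real cohorts of this design (0.7–0.9 for EMA items) can exceed what
  this generator produces
  (~0.5–0.6, except the strongly day-linked present bias at ~0.85).
* No weekday/weekend or seasonal structure; circadian shape is shared
  across sensors up to the entropy target.
* EMA responses are continuous clipped Gaussians, not integer scale points.

## Problem sizes and runtime choices

The test suite exercises the full study geometry (26 participants, 21
days). Stochastic properties use 100 synthetic cohorts for sign recovery,
25 null cohorts (225 trait models) for false-positive control, and 200
replicates for GEE coverage — sizes at which the binomial error of each
check is a few percent and the whole suite runs in about a minute.

## Numerical notes

* The exchangeable working correlation is clamped to the invertible range
  `(-1/(max cluster size - 1), 1)`; iteration stops on a relative
  coefficient change below 1e-10.
* The Lasso is solved by `glmnet` at a single fixed λ with a 1e-12
  convergence threshold and no internal standardization (the pipeline owns
  standardization); a one-column design uses the closed-form soft
  threshold, and the test suite verifies active sets against an
  independent proximal-gradient solver plus explicit KKT subgradient
  checks.
* Degenerate inputs error early and descriptively: zero-length windows,
  constant outcomes at the median split, rank-deficient refit designs
  (naming the collinear columns), and selections larger than `n - 2` are
  capped to the largest-coefficient features with a warning.
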