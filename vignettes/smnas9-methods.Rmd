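---
title: "Deriving abbreviated-scale decision rules for neonatal opioid withdrawal titration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving abbreviated-scale decision rules for neonatal opioid withdrawal titration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smnas9)
```

## The problem

Infants with neonatal opioid withdrawal syndrome (NOWS) are monitored with
ordinal severity instruments scored every 3–4 hours, and pharmacologic
treatment (morphine or buprenorphine) is titrated by protocolized rules on
score-derived metrics. The full MOTHER NAS scale (MNAS) scores 19 elements
(summed range 0–43); its abbreviated nested version, sMNAS-9, scores 9 of
those elements (range 0–19) and halves the scoring burden. Replacing the
full scale inside an existing titration algorithm requires short-scale
cutoffs that reproduce the full-scale decisions: this package implements
that derivation — optimal cutpoint selection by Youden-index maximization
over empirical ROC curves, with a depth-1 classification-tree (decision
stump) cross-check — together with everything around it: instrument
encoding, longitudinal rolling metrics, the titration rule engine,
infant-level train/test evaluation with bootstrap confidence intervals, and
a synthetic cohort generator so the whole chain is testable without patient
data.

## Instrument encoding

The shipped definition (`load_instrument()`) encodes each scored element as
an ordered list of severity levels with strictly increasing point values,
plus membership flags for the full and short scales; the short scale is
constrained to be a subset of the full scale. Nine further elements
(myoclonic jerks, watery stools, ...) are recorded as present/absent but
never summed.

The published rendering of the instrument table is typographically
ambiguous about one or two per-item maxima. The printed summed-score ranges
— 0–43 for the full scale over 19 items, 0–19 for the short scale over 9
items — are unambiguous, so we treat them as authoritative and reconcile
the encoding against them: the Moro reflex levels are encoded as 2 and 3
points (the parent Finnegan instrument's values for hyperactive and
markedly hyperactive), which is the unique assignment that reaches a
full-scale maximum of exactly 43; and the nine items carrying short-scale
points (crying, sleep, undisturbed tremors, muscle tone, fever, tachypnea,
poor feeding, vomiting, loose stools) sum to exactly 19.
`validate_instrument()` recomputes both maxima and flags any departure.

Scoring is strict about missingness: every scored item must appear in a
record, with 0 as the explicit "assessed, sign absent" marker. A missing
item is an error, not an implicit zero — all elements are assessed at every
scoring time, so silent zero-filling would mask data-entry problems.

## Longitudinal metrics

For each scoring time `t` of each infant, `build_metrics_table()` computes,
separately on both scales:

* the 24-hour average: the mean of all scores in the half-open window
  `(t − 24, t]`. The window includes the current score — the current
  assessment must be able to influence the current decision. Whether the
  original analysis included it is not documented; the window width is a
  parameter.
* the sum of 3 consecutive scores: the current score plus the two prior;
  undefined (`NA`) until three scores exist, and rules based on it cannot
  fire on undefined values (fail-safe toward no dose change).
* dose timers: time since the most recent dose increase and decrease, and
  flags for "≥ 48 h since last increase" and "≥ 24 h since last decrease"
  (inclusive at the boundary, reading "had passed" inclusively; the
  thresholds are parameters). Initiation and rescue doses count as
  increases — any escalation restarts the stability clock that gates
  weaning; this classification is configurable. Before any dose event both
  timers run from the infant's first score, which defines time zero.

Time is real-valued hours relative to each infant's first score; there is
no calendar or timezone handling, and no imputation of missed scoring
times. All rolling computations use cumulative sums but are tested for
exact agreement against naive per-query recomputation on randomized
series.

## The titration rule engine

A rule set (`load_ruleset()`) binds a drug, a scale, dose parameters, the
six indicator thresholds, and a priority-ordered list of guarded rules.
The six indicators, in their full-scale form, are: (i) 24-h average < 8,
(ii) 24-h average ≤ 8, (iii) sum of 3 < 18, (iv) sum of 3 ≥ 24, (v) sum of
3 ≥ 28, (vi) single score ≥ 12. The short-scale counterparts shipped as
defaults are < 4.6, ≤ 4.6, ≤ 10, ≥ 14, ≥ 16 and ≥ 7 — note the
deliberate comparator flip on (iii) (strict on the full scale, non-strict
on the short), preserved exactly as the derived rule pairs report it; its
rationale is not documented and we do not re-derive it.

At each scoring observation, every rule's condition, timer guards and dose
bounds are evaluated and the highest-priority satisfied rule fires — at
most one per step. The default priority order is discontinue > decrease >
large increase > increase > rescue > initiate: weaning decisions dominate
once stability criteria are met. The shipped rule sets use indicator (vi)
for initiation and rescue, (iv)/(v) for escalation, (i) for weaning (gated
by both stability flags) and (iii) for discontinuation (gated additionally
by a prior decrease and a dose floor). Which of (i) versus (ii), and where
(iii) enters, is genuinely open in the source algorithms' figures; both
remain configuration, and indicator (ii) is exposed for rule sets that
prefer the non-strict weaning boundary.

The dose magnitudes in the shipped rule sets — starting dose, step sizes,
rescue size, discontinuation floor — are placeholder configuration values
for simulation. They are not legible from the published algorithm figures
and we deliberately do not invent clinical numbers: every analysis in this
package depends on the sequence of actions, not on dose units.

## Cutoff derivation

For each full-scale indicator, the binary response labels (full-scale
condition holds / does not) are paired with the same-form short-scale
metric as predictor (24-h average with 24-h average, sum of 3 with sum of
3, single score with single score), pooled across infants in the training
set. The empirical ROC is evaluated at every distinct observed predictor
value (plus an infinite sentinel); the reported cutoff maximizes the Youden
index `J = sensitivity + specificity − 1`, with ties broken by the smallest
maximizing cutoff — deterministic, and favouring sensitivity for
≥-type treatment rules. Orientation is inherited from the full-scale
comparator (≥-type indicators are predicted by `short ≥ c`, </≤-type by
`short ≤ c`), not re-estimated. Rounding — one decimal for 24-h-average
cutoffs, nearest integer for sums and single scores — is applied only
after optimization.

The derivation literature describes both a CART step and Youden
maximization; the two coincide on a single threshold. We treat Youden
maximization as authoritative for the reported cutoff and provide the
depth-1 Gini-impurity stump (`stump_cutoff()`, exhaustive over midpoints of
adjacent distinct values) as a cross-check reported alongside; whether the
original analysis used Gini or another impurity is not stated, and both
quantities are reported rather than reconciled.

## Evaluation

Infants — never observations — are split into training and test sets by
independent Bernoulli(0.5) assignment under a fixed seed. Cutoffs are
derived on training rows only; the derived short-scale rules are then
applied to test rows and scored against the full-scale rules with
sensitivity and specificity. Disjointness of derivation and evaluation
infants is asserted on every run.

Confidence intervals are percentile bootstrap (bounded quantities in
[0, 1]; no normal approximation), default 2000 resamples at the 95% level,
with the seed a required argument. The default resampling unit is the
observation, stratified by the reference label, mirroring common
ROC-bootstrap practice; an infant-level clustered bootstrap is provided
because observations within an infant are autocorrelated and the
observation bootstrap understates that dependence. Which variant the
original analysis used is not documented; neither is claimed as it.

## The synthetic cohort generator

No public data accompany the source cohort, so the generator is a
first-class module. It emulates the *structure* of a monitored cohort:

* scoring times with uniform 3–4 h gaps (the documented cadence), the first
  score defining time zero; timestamps are rounded to 0.001 h so CSV
  round-trips are lossless;
* a latent severity process per infant: a rise–plateau–decay mean curve
  (baseline 2, peak 16 on the full-score axis at 72 h, shape 2 — values
  chosen once as a clinically plausible acute course) with first-order
  autoregressive noise (ρ = 0.7, marginal SD 4), floored at zero, and
  reduced by the current dose when treatment feedback is on (12 full-scale
  points per unit dose, making treatment visibly suppress scores at the
  placeholder doses);
* item-level emission by per-item ordered thresholds on latent severity
  plus independent per-item jitter (SD 3): higher severity awards higher
  ordinal levels, every emitted level is legal, and both summed scales are
  monotone functions of one latent process, so full and short scores are
  strongly positively correlated by construction. Item difficulties are
  spread across the severity axis in alphabetical item order so full-only
  and short-scale items interleave;
* dose events generated by running the titration engine over the
  accumulating scores, in feedback with severity. The default 480 h
  follow-up is long enough for a complete
  initiate–escalate–wean–discontinue course under the shipped rule sets.

The generator reproduces none of the real cohort's score distributions,
treatment durations or demographics, and has no pharmacokinetics; passing
tests demonstrate the correctness and internal consistency of the
*procedure*, not clinical performance on real data. The published test-set
sensitivities and specificities cannot be reproduced without the original
cohort, and this package does not attempt to.

A second mode plants ground truth: full-scale scores are generated as an
integer-discretized latent trajectory over 0–43 and short scores are set
through the deterministic map `floor(full/2) + 1` — a construction of this
package interpolating the two published calibration pairs (full 8 ↔ short
5, full 12 ↔ short 7). Under this map the single-score indicators have
exactly known short-scale counterparts, so cutoff recovery is exactly
checkable; mapped short values may exceed the real short scale's maximum
of 19 because they are calibration devices, not instrument scores. A noise
rate ε perturbs each short score by ±1 with probability ε. For the
avg24/sum3 indicators the map does not commute exactly with averaging, so
"planted truth" for recovery testing is defined as the cutoffs derived
from the same cohort at ε = 0; recovery at ε = 0.05 is required to land
within one step of the reported cutoff grid (0.1 for 24-h averages, 1 for
sums and single scores).

## Numerical choices and problem sizes

* Exactness of the rolling metrics relies on integer-valued scores:
  cumulative sums of integers below 2^53 are exact, so the optimized and
  naive computations agree bit-for-bit.
* Youden ties take the smallest maximizing cutoff; stump ties take the
  first (lowest) maximizing midpoint.
* Degenerate inputs raise structured errors: single-class labels
  ("degenerate ROC"), empty metrics tables, queries at non-observation
  times, stepping a discontinued episode.
* The test suite exercises the oracles at 1000 randomized series for the
  rolling metrics and 100 random instances (n ≤ 500) for the cutpoint
  optimizer; parameter recovery runs on a ~2000-observation planted
  cohort; bootstrap coverage uses 500 replicate experiments of n = 5000 at
  1000 resamples each. These sizes keep the full suite in the minutes
  range on one core while leaving the Monte Carlo error well inside the
  asserted bands.

## Known limitations

* The shipped dose magnitudes are placeholders; traces are meaningful as
  action sequences only.
* The observation-level bootstrap ignores within-infant autocorrelation
  (use `unit = "infant"` for the clustered variant).
* The planted map is a package construction; only the two published
  calibration pairs anchor it.
* No multi-split trees, no cross-validated pruning, no pharmacologic dose
  modelling, no calendar-time handling, and no attempt to reproduce other
  groups' abbreviated Finnegan variants.
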