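# smnas9

Clinical decision rules for neonatal opioid withdrawal syndrome (NOWS) are
written on the full 19-element MOTHER NAS scale (MNAS, summed score 0–43),
scored every 3–4 hours: dose-titration algorithms initiate, escalate, wean
and discontinue morphine or buprenorphine based on single scores, 24-hour
average scores, and sums of three consecutive scores. The abbreviated
9-element scale (sMNAS-9, summed score 0–19) halves the scoring burden —
but dropping it into an existing algorithm requires short-scale cutoffs
that reproduce the full-scale decisions.

`smnas9` implements that derivation and everything needed to exercise it
end to end, for biostatisticians and quality-improvement teams working
with abbreviated withdrawal instruments:

* **Instrument encoding** — the nested MNAS / sMNAS-9 definition with
  per-item ordered severity levels, validated against the printed summed
  ranges (43 / 19); strict missing-vs-absent scoring semantics.
* **Longitudinal metrics** — rolling 24-h averages (half-open window
  `(t−24, t]`), sums of 3 consecutive scores, and the dose timers and
  stability flags (≥ 48 h since last increase, ≥ 24 h since last decrease)
  that gate weaning.
* **Titration engine** — configurable guarded rule sets over the six
  indicator conditions; four shipped variants (morphine/buprenorphine ×
  full/short scale). Dose magnitudes are placeholder configuration, not
  clinical numbers.
* **Cutoff derivation** — for each full-scale indicator, the short-scale
  cutoff maximizing the Youden index
  `J = sensitivity + specificity − 1` over the empirical ROC of the
  same-form short-scale metric, smallest-maximizer tie-break, with a
  depth-1 Gini decision stump as cross-check.
* **Evaluation** — infant-level Bernoulli(0.5) train/test splits with an
  always-on leakage assertion, sensitivity/specificity on the test set,
  percentile bootstrap 95% CIs (stratified observation bootstrap by
  default, infant-clustered optionally).
* **Synthetic cohorts** — an item-level generator (autocorrelated latent
  severity, treatment feedback through the engine) and a planted-mapping
  mode whose short scores follow `floor(full/2) + 1`, the integer map
  interpolating the published calibration pairs (full 8 ↔ short 5,
  full 12 ↔ short 7), giving exactly known ground truth.

## Worked example

Recover the published single-score calibration from first principles —
enumerate every attainable full score once, map through the planted
calibration map, and ask for the short-scale rule matching
"full score ≥ 12":

```r
library(smnas9)
full <- 0:43
youden_optimal_cutoff(as.integer(full >= 12), planted_short_map(full),
                      orientation = "ge", round_digits = 0)
#> Youden-optimal rule: predictor >= 7 (J = 1.000, sens 1.000, spec 1.000; 32 pos / 12 neg)
```

The full pipeline on a synthetic cohort — simulate, compute metrics,
derive cutoffs on the training infants, evaluate on the held-out infants:

```r
cfg     <- cohort_config(n_infants = 20, seed = 42)
coh     <- generate_cohort(cfg, ruleset = load_ruleset("morphine_full"))
scores  <- coh$scores[c("infant_id", "timestamp_h", "full_score", "short_score")]
metrics <- build_metrics_table(scores, coh$doses)
split   <- split_infants(unique(metrics$infant_id), p = 0.5, seed = 42)
cuts    <- derive_all(metrics, split = split)
cuts[c("indicator", "short_metric", "direction", "cutoff", "youden")]
#>   indicator short_metric direction cutoff youden
#> 1         i  avg24_short        <=    2.1  0.949
#> 2        ii  avg24_short        <=    2.1  0.947
#> 3       iii   sum3_short        <=    4.0  0.880
#> 4        iv   sum3_short        >=    7.0  0.935
#> 5         v   sum3_short        >=    7.0  0.938
#> 6        vi  short_score        >=    3.0  0.844

evaluate_rules_on_test(metrics, split, cuts, n_boot = 2000, seed = 42)[
  c("indicator", "short_rule", "sensitivity", "specificity")]
#>   indicator         short_rule sensitivity specificity
#> 1         i avg24_short <= 2.1       0.944       0.971
#> 2        ii avg24_short <= 2.1       0.942       0.970
#> 3       iii    sum3_short <= 4       0.912       0.942
#> 4        iv    sum3_short >= 7       0.934       0.956
#> 5         v    sum3_short >= 7       0.966       0.948
#> 6        vi   short_score >= 3       0.929       0.912
```

Each row pairs one full-scale rule with its derived short-scale rule and
reports how faithfully the short rule reproduces the full rule's decisions
on infants never used for derivation. The cutoffs above are properties of
the *synthetic* severity distribution; on real cohort data the same
procedure yields the deployed short-scale thresholds (shipped as the
default short-scale rule sets: 4.6, 4.6, 10, 14, 16, 7).

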