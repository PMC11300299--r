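# Independent brute-force oracles and small fixture builders.
# The oracles deliberately use plain loops / direct definitions, not the
# package's cumulative-sum or vectorised code paths.

naive_avg24 <- function(timestamps, scores, t, window = 24) {
  acc <- c()
  for (i in seq_along(timestamps)) {
    if (timestamps[i] > t - window && timestamps[i] <= t) {
      acc <- c(acc, scores[i])
    }
  }
  mean(acc)
}

naive_sum3 <- function(timestamps, scores, t, k = 3) {
  idx <- c()
  for (i in seq_along(timestamps)) if (timestamps[i] <= t) idx <- c(idx, i)
  if (length(idx) < k) return(NA_real_)
  tail_idx <- idx[(length(idx) - k + 1):length(idx)]
  s <- 0
  for (i in tail_idx) s <- s + scores[i]
  s
}

# exhaustive Youden search: nested loops over candidates and observations
naive_youden <- function(labels, predictor, orientation) {
  cand <- c(sort(unique(predictor)), Inf)
  best_j <- -Inf; best_c <- NA; best_sens <- NA; best_spec <- NA
  for (cc in cand) {
    tp <- 0; fn <- 0; tn <- 0; fp <- 0
    for (i in seq_along(labels)) {
      pos_call <- if (orientation == "ge") predictor[i] >= cc else predictor[i] <= cc
      if (labels[i] == 1) {
        if (pos_call) tp <- tp + 1 else fn <- fn + 1
      } else {
        if (pos_call) fp <- fp + 1 else tn <- tn + 1
      }
    }
    sens <- tp / (tp + fn); spec <- tn / (tn + fp)
    j <- sens + spec - 1
    if (j > best_j) {  # strict: keeps the smallest maximising cutoff
      best_j <- j; best_c <- cc; best_sens <- sens; best_spec <- spec
    }
  }
  list(cutoff = best_c, youden = best_j,
       sensitivity = best_sens, specificity = best_spec)
}

# one infant's random scoring series with realistic-ish irregular gaps
random_series <- function(n, max_score = 43) {
  times <- cumsum(c(0, runif(n - 1, 0.5, 12)))
  scores <- sample(0:max_score, n, replace = TRUE)
  list(timestamps = times, scores = scores)
}

# deterministic piecewise score trajectory for engine tests:
# high severity then low, scored every `gap` hours
forced_trajectory <- function(high_full, low_full, n_high, n_low, gap = 3.5,
                              id = "infA") {
  n <- n_high + n_low
  full <- c(rep(high_full, n_high), rep(low_full, n_low))
  data.frame(infant_id = id,
             timestamp_h = (seq_len(n) - 1) * gap,
             full_score = full,
             short_score = planted_short_map(full))
}

# small planted-mapping cohort plus its metrics table
planted_metrics <- function(n_infants, seed, epsilon = 0) {
  cfg <- cohort_config(n_infants = n_infants, seed = seed,
                       mode = "planted_mapping", epsilon = epsilon)
  build_metrics_table(generate_planted_mapping_cohort(cfg))
}
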