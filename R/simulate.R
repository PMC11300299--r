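#' Configuration for a synthetic withdrawal cohort
#'
#' Collects and validates the generator parameters. The generator emulates
#' the structure of a monitored cohort — scoring every 3-4 h, autocorrelated
#' within-infant severity, item-level points on two nested scales, dose
#' events produced in feedback with severity — without attempting to match
#' any real cohort's distributions.
#'
#' @param n_infants Number of infants (>= 1).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param interval_min_h,interval_max_h Uniform bounds of the gap between
#'   consecutive scorings, in hours (default 3-4, the scoring cadence).
#' @param followup_h Follow-up duration per infant in hours (default 480,
#'   i.e. 20 days, long enough for a full initiate-escalate-wean-discontinue
#'   course under the shipped rule sets).
#' @param baseline,peak Latent-severity mean curve: resting level and peak
#'   height on the full-scale score axis (defaults 2 and 16).
#' @param t_peak_h Time of peak severity in hours (default 72).
#' @param shape Sharpness of the rise-plateau-decay mean curve (default 2).
#' @param ar_rho First-order autocorrelation of the severity noise
#'   (default 0.7).
#' @param noise_sd Marginal standard deviation of the severity noise
#'   (default 4).
#' @param treat_effect Severity reduction per unit dose (default 12; with
#'   the placeholder morphine doses this makes treatment visibly suppress
#'   scores).
#' @param jitter_sd Independent per-item jitter standard deviation for item
#'   emission (default 3).
#' @param mode `"item_level"` (full generator) or `"planted_mapping"`.
#' @param epsilon Noise rate for the planted-mapping mode: each short score
#'   is perturbed by +/-1 with this probability (0 <= epsilon < 0.5).
#' @return List of class `smnas_cohort_config`.
#' @export
cohort_config <- function(n_infants = 50, seed = 1,
                          interval_min_h = 3, interval_max_h = 4,
                          followup_h = 480,
                          baseline = 2, peak = 16, t_peak_h = 72, shape = 2,
                          ar_rho = 0.7, noise_sd = 4,
                          treat_effect = 12, jitter_sd = 3,
                          mode = c("item_level", "planted_mapping"),
                          epsilon = 0) {
  mode <- match.arg(mode)
  stopifnot(n_infants >= 1, interval_min_h <= interval_max_h,
            interval_min_h > 0, followup_h > 0,
            epsilon >= 0, epsilon < 0.5,
            ar_rho >= 0, ar_rho < 1, noise_sd >= 0, peak >= baseline)
  structure(list(n_infants = as.integer(n_infants), seed = as.integer(seed),
                 interval_min_h = interval_min_h,
                 interval_max_h = interval_max_h,
                 followup_h = followup_h, baseline = baseline, peak = peak,
                 t_peak_h = t_peak_h, shape = shape, ar_rho = ar_rho,
                 noise_sd = noise_sd, treat_effect = treat_effect,
                 jitter_sd = jitter_sd, mode = mode, epsilon = epsilon),
            class = "smnas_cohort_config")
}

# rise-plateau-decay mean severity curve on the full-score axis
severity_mean <- function(t, config) {
  x <- t / config$t_peak_h
  config$baseline +
    (config$peak - config$baseline) * (x * exp(1 - x))^config$shape
}

# scoring times with uniform gaps; first score defines time zero;
# rounded to the nearest 0.001 h so CSV round-trips are lossless
scoring_times <- function(config) {
  gaps <- numeric(0)
  t <- 0
  repeat {
    g <- stats::runif(1, config$interval_min_h, config$interval_max_h)
    if (t + g > config$followup_h) break
    gaps <- c(gaps, g)
    t <- t + g
  }
  round(cumsum(c(0, gaps)), 3)
}

# per-item emission thresholds on the latent full-score axis: item j's
# level k is awarded once latent + jitter exceeds base_j + (k-1) * step_j;
# difficulties are assigned in alphabetical item order so full-only and
# short-scale items interleave across the severity axis
item_emission_params <- function(instr, latent_ref) {
  items <- Filter(function(it) it$in_full, instr$items)
  n <- length(items)
  nms <- vapply(items, `[[`, character(1), "name")
  bases <- numeric(n)
  bases[order(nms)] <- seq(0.15, 0.85, length.out = n) * latent_ref
  lapply(seq_len(n), function(j) {
    it <- items[[j]]
    k <- nrow(it$levels)
    list(name = it$name, points = it$levels$points,
         thresholds = bases[[j]] + (seq_len(k) - 1L) * 0.25 * latent_ref / k)
  })
}

emit_items <- function(latent, emission, jitter_sd) {
  pts <- numeric(length(emission))
  names(pts) <- vapply(emission, `[[`, character(1), "name")
  for (j in seq_along(emission)) {
    e <- emission[[j]]
    u <- latent + stats::rnorm(1, 0, jitter_sd)
    lvl <- sum(u >= e$thresholds)
    pts[[j]] <- if (lvl == 0L) 0 else e$points[[lvl]]
  }
  pts
}

#' Generate a synthetic item-level cohort
#'
#' Per infant: scoring times with uniform 3-4 h gaps; a latent severity
#' process following a rise-plateau-decay mean curve plus first-order
#' autoregressive noise, reduced by the current dose when treatment feedback
#' is enabled; item points drawn by thresholding the latent severity per
#' item (higher severity awards higher ordinal levels), so full and short
#' summed scores are positively correlated by construction; and dose events
#' produced by running the titration engine over the accumulating scores.
#' Fully reproducible from the config seed.
#'
#' @param config An [cohort_config()] with `mode = "item_level"`.
#' @param instrument Instrument definition (default the shipped MNAS/sMNAS-9).
#' @param ruleset An `smnas_ruleset` for treatment feedback, or `NULL` for
#'   an untreated (observation-only) cohort.
#' @return List with `scores` (item-level score sheet including `full_score`
#'   and `short_score`), `doses` (dose-event table; zero rows when
#'   `ruleset` is `NULL`) and `latent` (the latent severity per observation,
#'   for generator diagnostics).
#' @export
generate_cohort <- function(config, instrument = load_instrument(),
                            ruleset = NULL) {
  stopifnot(inherits(config, "smnas_cohort_config"))
  if (config$mode != "item_level") {
    stop_smnas("generate_cohort requires mode = 'item_level'",
               class = "smnas_bad_input")
  }
  emission <- item_emission_params(instrument,
                                   latent_ref = config$peak + 2 * config$noise_sd)
  with_seed(config$seed, {
    score_parts <- list(); dose_parts <- list(); latent_parts <- list()
    for (i in seq_len(config$n_infants)) {
      id <- sprintf("inf%04d", i)
      times <- scoring_times(config)
      n <- length(times)
      innov_sd <- config$noise_sd * sqrt(1 - config$ar_rho^2)
      e <- stats::rnorm(1, 0, config$noise_sd)
      state <- if (!is.null(ruleset)) new_engine_state(ruleset, times[[1L]])
      scale <- if (!is.null(ruleset)) ruleset$scale
      score_col <- if (!is.null(ruleset)) paste0(scale, "_score")
      hist_t <- numeric(0); hist_s <- numeric(0)
      rows <- vector("list", n); latent_v <- numeric(n)
      events <- list()
      for (k in seq_len(n)) {
        t <- times[[k]]
        if (k > 1L) e <- config$ar_rho * e + stats::rnorm(1, 0, innov_sd)
        dose <- if (!is.null(ruleset)) state$dose else 0
        latent <- max(0, severity_mean(t, config) -
                        config$treat_effect * dose + e)
        latent_v[[k]] <- latent
        pts <- emit_items(latent, emission, config$jitter_sd)
        sc <- score_record(instrument, pts)
        rows[[k]] <- c(list(infant_id = id, timestamp_h = t), as.list(pts),
                       list(full_score = sc$full_score,
                            short_score = sc$short_score))
        if (!is.null(ruleset) && !state$discontinued) {
          hist_t <- c(hist_t, t)
          hist_s <- c(hist_s, if (scale == "full") sc$full_score else sc$short_score)
          mrow <- engine_metrics_row(id, t, hist_t, hist_s, state, scale)
          res <- step(state, mrow, ruleset)
          state <- res$state
          if (!is.null(res$event)) events[[length(events) + 1L]] <- res$event
        }
      }
      score_parts[[i]] <- do.call(rbind, lapply(rows, function(r)
        as.data.frame(r, check.names = FALSE)))
      latent_parts[[i]] <- data.frame(infant_id = id, timestamp_h = times,
                                      latent = latent_v)
      if (length(events) > 0L) {
        dose_parts[[length(dose_parts) + 1L]] <- do.call(rbind, events)
      }
    }
    scores <- do.call(rbind, score_parts)
    rownames(scores) <- NULL
    doses <- if (length(dose_parts) > 0L) do.call(rbind, dose_parts) else
      data.frame(infant_id = character(0), timestamp_h = numeric(0),
                 drug = character(0), action = character(0),
                 dose = numeric(0), rule = character(0))
    rownames(doses) <- NULL
    latent <- do.call(rbind, latent_parts)
    rownames(latent) <- NULL
    list(scores = scores, doses = doses, latent = latent)
  })
}

#' Generate a planted-mapping cohort with known ground-truth cutoffs
#'
#' Produces full-scale score trajectories (an autocorrelated latent process
#' discretised to the 0-43 range) and sets each short score through the
#' deterministic integer map `floor(full / 2) + 1`. This map is a
#' construction of this package: it interpolates the two published
#' calibration pairs (full 8 maps to short 5, full 12 to short 7), so the
#' single-score indicators have known matching short-scale cutoffs by
#' construction, and noise-free cutoff recovery is exactly checkable. With
#' `epsilon > 0` each short score is independently perturbed by +/-1 with
#' probability `epsilon` (floored at 0).
#'
#' Note the mapped short scores are a synthetic construction on the full
#' 0-43 domain and may exceed the real instrument's short-scale maximum of
#' 19; they are calibration devices, not instrument scores.
#'
#' @param config An [cohort_config()] with `mode = "planted_mapping"`.
#' @return Data frame of score records: `infant_id`, `timestamp_h`,
#'   `full_score`, `short_score`.
#' @export
generate_planted_mapping_cohort <- function(config) {
  stopifnot(inherits(config, "smnas_cohort_config"))
  if (config$mode != "planted_mapping") {
    stop_smnas("generate_planted_mapping_cohort requires mode = 'planted_mapping'",
               class = "smnas_bad_input")
  }
  with_seed(config$seed, {
    parts <- lapply(seq_len(config$n_infants), function(i) {
      id <- sprintf("inf%04d", i)
      times <- scoring_times(config)
      n <- length(times)
      innov_sd <- config$noise_sd * sqrt(1 - config$ar_rho^2)
      e <- stats::rnorm(1, 0, config$noise_sd)
      full <- integer(n)
      for (k in seq_len(n)) {
        if (k > 1L) e <- config$ar_rho * e + stats::rnorm(1, 0, innov_sd)
        lat <- severity_mean(times[[k]], config) + e
        full[[k]] <- as.integer(min(43, max(0, round(lat))))
      }
      short <- planted_short_map(full)
      if (config$epsilon > 0) {
        flip <- stats::runif(n) < config$epsilon
        short[flip] <- pmax(0L, short[flip] +
                              sample(c(-1L, 1L), sum(flip), replace = TRUE))
      }
      data.frame(infant_id = id, timestamp_h = times,
                 full_score = full, short_score = short)
    })
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out
  })
}

#' The planted full-to-short calibration map
#'
#' `floor(full / 2) + 1`: the integer map interpolating the two published
#' calibration pairs (8 to 5, 12 to 7). A construction of this package for
#' recovery testing, not an instrument property.
#'
#' @param full Integer vector of full-scale scores.
#' @return Integer vector of mapped short-scale scores.
#' @export
planted_short_map <- function(full) {
  as.integer(floor(full / 2) + 1)
}

#' Write a cohort to CSV fixtures
#'
#' Serialises score and dose tables to the CSV dialects consumed by the
#' other modules; [read_score_sheet()] / [read_dose_events()] on the written
#' files reproduce the tables exactly.
#'
#' @param scores Score table.
#' @param doses Dose-event table, or `NULL`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(scores, doses = NULL, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(scores = file.path(dir, "scores.csv"))
  write_score_sheet(scores, paths[["scores"]])
  if (!is.null(doses)) {
    paths[["doses"]] <- file.path(dir, "doses.csv")
    write_dose_events(doses, paths[["doses"]])
  }
  invisible(paths)
}
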