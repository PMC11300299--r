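#' Default indicator thresholds for a scale
#'
#' The six indicator conditions used by the titration algorithms, on either
#' the full 19-item scale or the abbreviated 9-item scale. On the full scale
#' these are: (i) 24-h average < 8, (ii) 24-h average <= 8, (iii) sum of 3
#' consecutive scores < 18, (iv) sum of 3 >= 24, (v) sum of 3 >= 28, (vi)
#' single score >= 12. The short-scale defaults are the derived optimal
#' cutoffs: (i) < 4.6, (ii) <= 4.6, (iii) <= 10, (iv) >= 14, (v) >= 16,
#' (vi) >= 7. Note the deliberate comparator asymmetry of indicator (iii)
#' across scales (strict `<` on the full scale, non-strict `<=` on the
#' short), preserved from the derived rule pairs.
#'
#' @param scale `"full"` or `"short"`.
#' @return Data frame with columns `name` (i--vi), `metric` (`avg24`, `sum3`
#'   or `single_score`), `comparator`, `threshold`.
#' @export
default_indicator_thresholds <- function(scale = c("full", "short")) {
  scale <- match.arg(scale)
  if (scale == "full") {
    data.frame(
      name = c("i", "ii", "iii", "iv", "v", "vi"),
      metric = c("avg24", "avg24", "sum3", "sum3", "sum3", "single_score"),
      comparator = c("<", "<=", "<", ">=", ">=", ">="),
      threshold = c(8, 8, 18, 24, 28, 12))
  } else {
    data.frame(
      name = c("i", "ii", "iii", "iv", "v", "vi"),
      metric = c("avg24", "avg24", "sum3", "sum3", "sum3", "single_score"),
      comparator = c("<", "<=", "<=", ">=", ">=", ">="),
      threshold = c(4.6, 4.6, 10, 14, 16, 7))
  }
}

apply_comparator <- function(x, comparator, threshold) {
  switch(comparator,
         "<"  = x < threshold,
         "<=" = x <= threshold,
         ">=" = x >= threshold,
         ">"  = x > threshold,
         stop_smnas("unknown comparator '%s'", comparator,
                    class = "smnas_bad_input"))
}

#' Evaluate the six indicator conditions on one metrics row
#'
#' @param row A single metrics row (list or one-row data frame) carrying
#'   `avg24_<scale>`, `sum3_<scale>` and `<scale>_score`.
#' @param scale `"full"` or `"short"`.
#' @param thresholds Indicator table as from [default_indicator_thresholds()].
#' @return Named logical vector (`i` .. `vi`). Indicators based on the sum of
#'   3 consecutive scores are `FALSE` while that sum is still undefined
#'   (fewer than 3 scores observed); the attribute `sum3_missing` flags this.
#' @export
evaluate_indicators <- function(row, scale = c("full", "short"),
                                thresholds = default_indicator_thresholds(scale)) {
  scale <- match.arg(scale)
  vals <- list(
    avg24 = row[[paste0("avg24_", scale)]],
    sum3 = row[[paste0("sum3_", scale)]],
    single_score = row[[paste0(scale, "_score")]])
  out <- logical(nrow(thresholds))
  names(out) <- thresholds$name
  sum3_missing <- is.na(vals$sum3)
  for (j in seq_len(nrow(thresholds))) {
    v <- vals[[thresholds$metric[[j]]]]
    out[[j]] <- if (is.null(v) || is.na(v)) FALSE
    else apply_comparator(v, thresholds$comparator[[j]], thresholds$threshold[[j]])
  }
  attr(out, "sum3_missing") <- sum3_missing
  out
}

#' Load a titration rule set
#'
#' Reads a rule-set configuration (JSON): the drug, the scoring scale it
#' listens to, dose parameters, the six indicator thresholds and a
#' priority-ordered list of guarded rules. Four rule sets are shipped:
#' `"morphine_full"`, `"morphine_short"`, `"buprenorphine_full"`,
#' `"buprenorphine_short"`. The shipped dose magnitudes (starting dose, step
#' sizes, rescue size, discontinuation floor) are placeholder configuration
#' values for simulation, not clinically validated numbers; the indicator
#' thresholds are the scale's decision-rule cutoffs.
#'
#' @param name_or_path Name of a shipped rule set or path to a JSON file.
#' @return An object of class `smnas_ruleset`.
#' @export
load_ruleset <- function(name_or_path) {
  shipped <- c("morphine_full", "morphine_short",
               "buprenorphine_full", "buprenorphine_short")
  path <- if (name_or_path %in% shipped) {
    system.file("extdata", "rulesets", paste0(name_or_path, ".json"),
                package = "smnas9", mustWork = TRUE)
  } else name_or_path
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  thr <- do.call(rbind, lapply(raw$thresholds, function(x) {
    data.frame(name = x$name, metric = x$metric,
               comparator = x$comparator, threshold = as.numeric(x$threshold))
  }))
  rules <- lapply(raw$rules, function(r) {
    cond <- if (!is.null(r$indicator)) {
      i <- match(r$indicator, thr$name)
      if (is.na(i)) stop_smnas("rule '%s' references unknown indicator '%s'",
                               r$name, r$indicator, class = "smnas_bad_ruleset")
      list(metric = thr$metric[[i]], comparator = thr$comparator[[i]],
           threshold = thr$threshold[[i]])
    } else {
      list(metric = r$condition$metric, comparator = r$condition$comparator,
           threshold = as.numeric(r$condition$threshold))
    }
    list(name = r$name, condition = cond,
         guards = vapply(r$guards %||% list(), as.character, character(1)),
         action = r$action,
         dose_delta = r$dose_delta,
         priority = as.integer(r$priority),
         dose_at_most = if (is.null(r$dose_at_most)) NULL else as.numeric(r$dose_at_most))
  })
  rs <- structure(
    list(name = raw$name, drug = raw$drug, scale = raw$scale,
         dose_units = raw$dose_units,
         start_dose = as.numeric(raw$start_dose),
         max_dose = as.numeric(raw$max_dose),
         thresholds = thr, rules = rules),
    class = "smnas_ruleset")
  validate_ruleset(rs)
  rs
}

validate_ruleset <- function(rs) {
  stopifnot(rs$scale %in% c("full", "short"))
  prio <- vapply(rs$rules, `[[`, integer(1), "priority")
  if (anyDuplicated(prio)) {
    stop_smnas("rule priorities must be unique", class = "smnas_bad_ruleset")
  }
  actions <- vapply(rs$rules, `[[`, character(1), "action")
  for (need in c("initiate", "increase", "decrease", "discontinue")) {
    if (!need %in% actions) {
      stop_smnas("rule set lacks a '%s' rule", need, class = "smnas_bad_ruleset")
    }
  }
  if (rs$start_dose < 0 || rs$max_dose < rs$start_dose) {
    stop_smnas("dose parameters inconsistent", class = "smnas_bad_ruleset")
  }
  invisible(rs)
}

#' @export
print.smnas_ruleset <- function(x, ...) {
  cat(sprintf("<smnas_ruleset> %s: %s, %s scale, %d rules, start %g max %g %s\n",
              x$name, x$drug, x$scale, length(x$rules),
              x$start_dose, x$max_dose, x$dose_units))
  invisible(x)
}

new_engine_state <- function(ruleset, t_first_score) {
  list(treating = FALSE, discontinued = FALSE, dose = 0,
       t0 = t_first_score, t_last_increase = NA_real_,
       t_last_decrease = NA_real_, had_first_decrease = FALSE,
       ruleset = ruleset)
}

guard_holds <- function(guard, state, row) {
  switch(guard,
         "not_yet_treating" = !state$treating && !state$discontinued,
         "treating" = state$treating,
         "48h_since_increase" = isTRUE(row$flag_48h_since_increase),
         "24h_since_decrease" = isTRUE(row$flag_24h_since_decrease),
         "had_first_decrease" = isTRUE(row$had_first_decrease),
         stop_smnas("unknown guard '%s'", guard, class = "smnas_bad_ruleset"))
}

rule_applies <- function(rule, state, row, scale) {
  vals <- list(avg24 = row[[paste0("avg24_", scale)]],
               sum3 = row[[paste0("sum3_", scale)]],
               single_score = row[[paste0(scale, "_score")]])
  v <- vals[[rule$condition$metric]]
  if (is.null(v) || is.na(v)) return(FALSE)  # fail-safe: no dose change
  if (!apply_comparator(v, rule$condition$comparator, rule$condition$threshold))
    return(FALSE)
  for (g in rule$guards) if (!guard_holds(g, state, row)) return(FALSE)
  if (!is.null(rule$dose_at_most) && state$dose > rule$dose_at_most)
    return(FALSE)
  TRUE
}

apply_dose_delta <- function(dose, delta, max_dose) {
  if (is.null(delta)) return(dose)
  v <- as.numeric(delta$value)
  new <- switch(delta$kind %||% "absolute",
                absolute = dose + v,
                relative = dose * (1 + v),
                set = v,
                stop_smnas("unknown dose_delta kind", class = "smnas_bad_ruleset"))
  min(max(new, 0), max_dose)
}

#' Advance the titration state machine by one scoring observation
#'
#' Evaluates every rule of the rule set against the current metrics row and
#' treatment state; the highest-priority rule whose condition, timer guards
#' and dose bounds all hold fires (at most one rule per step). Doses are
#' clipped to `[0, max_dose]`.
#'
#' @param state Engine state as produced by [run_episode()] internally, or a
#'   fresh state for the infant's first score.
#' @param row One metrics row (see [build_metrics_table()]).
#' @param ruleset An `smnas_ruleset`.
#' @return A list with `event` (a one-row dose-event data frame, or `NULL`
#'   for a no-op), `fired` (rule name or `NA`) and the updated `state`.
#' @export
step <- function(state, row, ruleset) {
  if (isTRUE(state$discontinued)) {
    stop_smnas("step after discontinue", class = "smnas_bad_state")
  }
  applicable <- Filter(function(r) rule_applies(r, state, row, ruleset$scale),
                       ruleset$rules)
  if (length(applicable) == 0L) {
    return(list(event = NULL, fired = NA_character_, state = state))
  }
  prio <- vapply(applicable, `[[`, integer(1), "priority")
  rule <- applicable[[which.max(prio)]]
  t <- row$timestamp_h
  state <- switch(
    rule$action,
    initiate = {
      state$treating <- TRUE
      state$dose <- min(ruleset$start_dose, ruleset$max_dose)
      state$t_last_increase <- t
      state
    },
    increase = ,
    rescue = {
      state$dose <- apply_dose_delta(state$dose, rule$dose_delta, ruleset$max_dose)
      state$t_last_increase <- t
      state
    },
    decrease = {
      state$dose <- apply_dose_delta(state$dose, rule$dose_delta, ruleset$max_dose)
      state$t_last_decrease <- t
      state$had_first_decrease <- TRUE
      state
    },
    discontinue = {
      state$dose <- 0
      state$treating <- FALSE
      state$discontinued <- TRUE
      state
    },
    stop_smnas("unknown action '%s'", rule$action, class = "smnas_bad_ruleset"))
  event <- data.frame(infant_id = row$infant_id %||% NA_character_,
                      timestamp_h = t, drug = ruleset$drug,
                      action = rule$action, dose = state$dose,
                      rule = rule$name)
  list(event = event, fired = rule$name, state = state)
}

# metrics for the engine's scale at time t, from accumulated history
engine_metrics_row <- function(infant_id, t, times, scores, state, scale) {
  row <- list(infant_id = infant_id, timestamp_h = t)
  row[[paste0(scale, "_score")]] <- scores[[length(scores)]]
  row[[paste0("avg24_", scale)]] <- average_24h(times, scores, t)
  row[[paste0("sum3_", scale)]] <- sum_last3(times, scores, t)
  t_inc <- if (is.na(state$t_last_increase)) state$t0 else state$t_last_increase
  t_dec <- if (is.na(state$t_last_decrease)) state$t0 else state$t_last_decrease
  row$flag_48h_since_increase <- (t - t_inc) >= 48
  row$flag_24h_since_decrease <- (t - t_dec) >= 24
  row$had_first_decrease <- state$had_first_decrease
  row
}

#' Run a titration algorithm over one infant's score series
#'
#' Iterates [step()] over the infant's scores in chronological order, feeding
#' every emitted dose event back into the timer state, and stops at
#' discontinuation or when the scores end. The run is deterministic given its
#' inputs.
#'
#' @param scores Data frame of one infant's score records (`infant_id`,
#'   `timestamp_h`, `full_score`, `short_score`), in or sortable to
#'   chronological order.
#' @param ruleset An `smnas_ruleset`.
#' @return An episode trace of class `smnas_trace`: a data frame with one row
#'   per fired rule (`infant_id`, `timestamp_h`, `drug`, `action`, `dose`
#'   after the action, `rule`). Usable directly as a dose-event table.
#' @export
run_episode <- function(scores, ruleset) {
  check_cols(scores, c("infant_id", "timestamp_h", "full_score", "short_score"),
             "score table")
  if (nrow(scores) == 0L) {
    return(structure(data.frame(infant_id = character(0),
                                timestamp_h = numeric(0), drug = character(0),
                                action = character(0), dose = numeric(0),
                                rule = character(0)),
                     class = c("smnas_trace", "data.frame")))
  }
  if (length(unique(scores$infant_id)) != 1L) {
    stop_smnas("run_episode expects a single infant", class = "smnas_bad_input")
  }
  scores <- scores[order(scores$timestamp_h), , drop = FALSE]
  scale <- ruleset$scale
  score_col <- paste0(scale, "_score")
  state <- new_engine_state(ruleset, scores$timestamp_h[[1L]])
  events <- list()
  times <- numeric(0); vals <- numeric(0)
  for (i in seq_len(nrow(scores))) {
    t <- scores$timestamp_h[[i]]
    times <- c(times, t); vals <- c(vals, scores[[score_col]][[i]])
    row <- engine_metrics_row(scores$infant_id[[i]], t, times, vals, state, scale)
    res <- step(state, row, ruleset)
    state <- res$state
    if (!is.null(res$event)) events[[length(events) + 1L]] <- res$event
    if (state$discontinued) break
  }
  trace <- if (length(events) > 0L) do.call(rbind, events) else
    data.frame(infant_id = character(0), timestamp_h = numeric(0),
               drug = character(0), action = character(0),
               dose = numeric(0), rule = character(0))
  rownames(trace) <- NULL
  structure(trace, class = c("smnas_trace", "data.frame"))
}
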