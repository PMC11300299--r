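#' Rolling 24-hour average score at an observation time
#'
#' Arithmetic mean of all scores whose timestamp lies in the half-open window
#' `(t - window, t]`. The score at `t` itself is included, so the current
#' assessment always influences the current decision.
#'
#' @param timestamps Numeric vector of observation times in hours, sorted
#'   non-decreasing.
#' @param scores Numeric vector of scores, same length.
#' @param t Query time; must equal one of `timestamps`.
#' @param window Window width in hours (default 24).
#' @return The windowed mean as a double.
#' @export
#' @examples
#' average_24h(c(35, 59, 60), c(10, 4, 6), t = 60)  # 5: t = 35 falls outside
average_24h <- function(timestamps, scores, t, window = 24) {
  check_series(timestamps, scores, t)
  keep <- timestamps > t - window & timestamps <= t
  mean(scores[keep])
}

#' Sum of the three most recent consecutive scores
#'
#' Sum of the score at `t` and the two immediately preceding scores. Returns
#' `NA` while fewer than `k` scores have been observed, so early decision
#' points are flagged rather than computed on partial history.
#'
#' @inheritParams average_24h
#' @param k Number of consecutive scores to sum (default 3).
#' @return The sum, or `NA` if fewer than `k` observations exist up to `t`.
#' @export
sum_last3 <- function(timestamps, scores, t, k = 3) {
  check_series(timestamps, scores, t)
  i <- max(which(timestamps <= t))
  if (i < k) return(NA_real_)
  sum(scores[(i - k + 1L):i])
}

check_series <- function(timestamps, scores, t) {
  if (length(timestamps) != length(scores)) {
    stop_smnas("timestamps and scores differ in length",
               class = "smnas_bad_input")
  }
  if (is.unsorted(timestamps)) {
    stop_smnas("timestamps must be non-decreasing", class = "smnas_bad_input")
  }
  if (!any(timestamps == t)) {
    stop_smnas("t = %g is not an observation time", t,
               class = "smnas_bad_input")
  }
  invisible(TRUE)
}

#' Annotate score times with dose timers and stability flags
#'
#' For every scoring time of every infant, computes the time elapsed since
#' the most recent dose increase and decrease, and the corresponding
#' stability flags used by the titration algorithms: whether 48 h have passed
#' since the last increase and whether 24 h have passed since the last
#' decrease (both inclusive at the boundary). Initiation and rescue doses
#' restart the increase clock, since any escalation resets the stability
#' period that gates weaning. Before any qualifying dose event, both timers
#' run from the infant's first score, which defines time zero.
#'
#' @param scores Data frame of score records: `infant_id`, `timestamp_h`, and
#'   score columns; sorted or sortable by time within infant.
#' @param doses Data frame of dose events: `infant_id`, `timestamp_h`,
#'   `drug`, `action`, `dose`. May have zero rows.
#' @param increase_actions,decrease_actions Actions counted as increases /
#'   decreases for the timers.
#' @param flag_increase_h,flag_decrease_h Flag thresholds in hours.
#' @return `scores` (chronologically ordered within infant) with columns
#'   `t_since_increase`, `t_since_decrease`, `flag_48h_since_increase`,
#'   `flag_24h_since_decrease`, `had_first_decrease` appended.
#' @export
annotate_timers <- function(scores, doses = NULL,
                            increase_actions = c("initiate", "increase", "rescue"),
                            decrease_actions = "decrease",
                            flag_increase_h = 48, flag_decrease_h = 24) {
  check_cols(scores, c("infant_id", "timestamp_h"), "score table")
  if (is.null(doses) || nrow(doses) == 0L) {
    doses <- data.frame(infant_id = character(0), timestamp_h = numeric(0),
                        drug = character(0), action = character(0),
                        dose = numeric(0))
  }
  check_cols(doses, c("infant_id", "timestamp_h", "action"), "dose table")
  unknown <- setdiff(unique(doses$infant_id), unique(scores$infant_id))
  if (length(unknown) > 0L) {
    stop_smnas("dose event for unknown infant: %s", unknown[[1L]],
               class = "smnas_bad_input")
  }
  scores <- order_by_infant_time(scores)
  out <- lapply(split(scores, scores$infant_id, drop = TRUE), function(sc) {
    dv <- doses[doses$infant_id == sc$infant_id[[1L]], , drop = FALSE]
    if (nrow(dv) > 0L && is.unsorted(dv$timestamp_h)) {
      stop_smnas("dose timestamps decreasing for infant %s",
                 sc$infant_id[[1L]], class = "smnas_bad_input")
    }
    t0 <- sc$timestamp_h[[1L]]
    inc_t <- dv$timestamp_h[dv$action %in% increase_actions]
    dec_t <- dv$timestamp_h[dv$action %in% decrease_actions]
    last_at <- function(events, t) {
      prior <- events[events <= t]
      if (length(prior) == 0L) t0 else max(prior)
    }
    sc$t_since_increase <- vapply(sc$timestamp_h,
                                  function(t) t - last_at(inc_t, t), numeric(1))
    sc$t_since_decrease <- vapply(sc$timestamp_h,
                                  function(t) t - last_at(dec_t, t), numeric(1))
    sc$flag_48h_since_increase <- sc$t_since_increase >= flag_increase_h
    sc$flag_24h_since_decrease <- sc$t_since_decrease >= flag_decrease_h
    sc$had_first_decrease <- vapply(sc$timestamp_h,
                                    function(t) any(dec_t <= t), logical(1))
    sc
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build the full longitudinal metrics table
#'
#' Combines the rolling 24-h average, the sum of three consecutive scores
#' (each computed separately on the full and short scales) and the dose-timer
#' annotations into one row per score record. Infants are processed
#' independently and rows are returned in chronological order within infant.
#'
#' @param scores Data frame with `infant_id`, `timestamp_h`, `full_score`,
#'   `short_score`.
#' @param doses Dose-event data frame (see [annotate_timers()]), or `NULL`.
#' @param window 24-h window width passed to the rolling average.
#' @param k Run length for the consecutive-score sum.
#' @param ... Further arguments passed to [annotate_timers()].
#' @return A data frame with one `MetricsRow` per score record: the input
#'   columns plus `avg24_full`, `avg24_short`, `sum3_full`, `sum3_short`
#'   (`NA` until `k` scores exist) and the timer columns.
#' @export
build_metrics_table <- function(scores, doses = NULL, window = 24, k = 3, ...) {
  check_cols(scores, c("infant_id", "timestamp_h", "full_score", "short_score"),
             "score table")
  if (nrow(scores) == 0L) {
    ann <- scores
    for (col in c("avg24_full", "avg24_short", "sum3_full", "sum3_short",
                  "t_since_increase", "t_since_decrease")) ann[[col]] <- numeric(0)
    for (col in c("flag_48h_since_increase", "flag_24h_since_decrease",
                  "had_first_decrease")) ann[[col]] <- logical(0)
    return(ann)
  }
  ann <- annotate_timers(scores, doses, ...)
  parts <- lapply(split(ann, ann$infant_id, drop = TRUE), function(sc) {
    sc$avg24_full <- rolling_mean(sc$timestamp_h, sc$full_score, window)
    sc$avg24_short <- rolling_mean(sc$timestamp_h, sc$short_score, window)
    sc$sum3_full <- rolling_sum_k(sc$full_score, k)
    sc$sum3_short <- rolling_sum_k(sc$short_score, k)
    sc
  })
  res <- do.call(rbind, parts)
  rownames(res) <- NULL
  order_by_infant_time(res)
}

# windowed mean over (t - window, t] for every position, via cumulative sums
rolling_mean <- function(timestamps, scores, window) {
  n <- length(scores)
  cs <- cumsum(scores)
  # first index inside the window for each query time
  first <- findInterval(timestamps - window, timestamps,
                        left.open = FALSE) + 1L
  # findInterval with default closure treats ties as inside; window is open
  # on the left, so an observation exactly at t - window must be excluded
  first <- pmax(first, 1L)
  idx <- seq_len(n)
  tot <- cs[idx] - c(0, cs)[first]
  tot / (idx - first + 1L)
}

rolling_sum_k <- function(scores, k) {
  n <- length(scores)
  out <- rep(NA_real_, n)
  if (n >= k) {
    cs <- cumsum(scores)
    idx <- k:n
    out[idx] <- cs[idx] - c(0, cs)[idx - k + 1L]
  }
  out
}
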