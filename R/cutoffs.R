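#' The six full-scale indicator specifications
#'
#' The response indicators whose short-scale counterparts are derived:
#' (i) 24-h average < 8, (ii) 24-h average <= 8, (iii) sum of 3 consecutive
#' scores < 18, (iv) sum of 3 >= 24, (v) sum of 3 >= 28, (vi) single score
#' >= 12. Each pairs with the same-form short-scale metric
#' (avg24 with avg24, sum3 with sum3, single with single), and the
#' short-scale classification rule inherits the comparator's direction:
#' `>=`-type indicators are predicted by `short metric >= c`, `<`/`<=`-type
#' by `short metric <= c`.
#'
#' @return Data frame with columns `name`, `metric`, `comparator`,
#'   `threshold`, `orientation` (`"ge"` or `"le"`), `round_digits` (reported
#'   cutoff precision: 1 decimal for 24-h averages, integer otherwise).
#' @export
indicator_specs <- function() {
  thr <- default_indicator_thresholds("full")
  thr$orientation <- ifelse(thr$comparator %in% c(">=", ">"), "ge", "le")
  thr$round_digits <- ifelse(thr$metric == "avg24", 1L, 0L)
  thr
}

metric_column <- function(metric, scale) {
  switch(metric,
         avg24 = paste0("avg24_", scale),
         sum3 = paste0("sum3_", scale),
         single_score = paste0(scale, "_score"),
         stop_smnas("unknown metric '%s'", metric, class = "smnas_bad_input"))
}

#' Binary response labels for one indicator
#'
#' Labels each metrics row 1 where the full-scale indicator condition holds,
#' 0 otherwise. Rows where the required full-scale metric is undefined (e.g.
#' the sum of 3 before three scores exist) are dropped and counted.
#'
#' @param metrics Metrics table from [build_metrics_table()].
#' @param spec One row of [indicator_specs()] (or a list with `metric`,
#'   `comparator`, `threshold`).
#' @return List with integer vector `labels`, logical `kept` (row mask into
#'   `metrics`), and `n_dropped`.
#' @export
make_labels <- function(metrics, spec) {
  col <- metric_column(spec$metric, "full")
  check_cols(metrics, col, "metrics table")
  v <- metrics[[col]]
  kept <- !is.na(v)
  labels <- as.integer(apply_comparator(v[kept], spec$comparator, spec$threshold))
  list(labels = labels, kept = kept, n_dropped = sum(!kept))
}

#' Empirical ROC points over all candidate cutoffs
#'
#' One (sensitivity, specificity) point per candidate cutoff, with
#' candidates taken as every distinct observed predictor value plus an
#' infinite sentinel (the classify-none rule). Orientation `"ge"` classifies
#' positive where `predictor >= c`; `"le"` where `predictor <= c` (used for
#' the `<`/`<=`-type weaning indicators, where low short-scale metrics
#' predict the full-scale condition).
#'
#' @param labels Binary 0/1 vector.
#' @param predictor Numeric vector, same length.
#' @param orientation `"ge"` or `"le"`.
#' @return Data frame with `cutoff`, `sensitivity`, `specificity`, `youden`,
#'   ordered by cutoff.
#' @export
empirical_roc <- function(labels, predictor, orientation = c("ge", "le")) {
  orientation <- match.arg(orientation)
  stopifnot(length(labels) == length(predictor))
  labels <- as.integer(labels)
  if (anyNA(labels) || anyNA(predictor)) {
    stop_smnas("labels/predictor contain missing values", class = "smnas_bad_input")
  }
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop_smnas("degenerate ROC: only one class present", class = "smnas_degenerate")
  }
  cand <- c(sort(unique(predictor)), Inf)
  pos <- predictor[labels == 1L]
  neg <- predictor[labels == 0L]
  if (orientation == "ge") {
    sens <- vapply(cand, function(c) sum(pos >= c), numeric(1)) / n_pos
    spec <- vapply(cand, function(c) sum(neg < c), numeric(1)) / n_neg
  } else {
    sens <- vapply(cand, function(c) sum(pos <= c), numeric(1)) / n_pos
    spec <- vapply(cand, function(c) sum(neg > c), numeric(1)) / n_neg
  }
  data.frame(cutoff = cand, sensitivity = sens, specificity = spec,
             youden = sens + spec - 1)
}

#' Youden-optimal cutoff for a dichotomised predictor
#'
#' Selects, over the empirical ROC candidates, the cutoff maximising the
#' Youden index (sensitivity + specificity - 1); ties are broken by the
#' smallest maximising cutoff, which is deterministic and favours
#' sensitivity for `>=`-type treatment rules. The reported cutoff is
#' optionally rounded (1 decimal for 24-h-average metrics, nearest integer
#' for sums and single scores); rounding is applied only after optimisation.
#'
#' @inheritParams empirical_roc
#' @param round_digits Digits for the reported cutoff, or `NULL` to skip
#'   rounding.
#' @return List of class `smnas_cutoff`: `cutoff` (reported), `cutoff_raw`,
#'   `orientation`, `youden`, `sensitivity`, `specificity`, `n_pos`, `n_neg`.
#' @export
youden_optimal_cutoff <- function(labels, predictor,
                                  orientation = c("ge", "le"),
                                  round_digits = NULL) {
  orientation <- match.arg(orientation)
  roc <- empirical_roc(labels, predictor, orientation)
  best <- which(roc$youden == max(roc$youden))
  i <- best[[which.min(roc$cutoff[best])]]
  raw <- roc$cutoff[[i]]
  structure(list(
    cutoff = if (is.null(round_digits)) raw else round(raw, round_digits),
    cutoff_raw = raw,
    orientation = orientation,
    youden = roc$youden[[i]],
    sensitivity = roc$sensitivity[[i]],
    specificity = roc$specificity[[i]],
    n_pos = sum(as.integer(labels) == 1L),
    n_neg = sum(as.integer(labels) == 0L)),
    class = "smnas_cutoff")
}

#' @export
print.smnas_cutoff <- function(x, ...) {
  op <- if (x$orientation == "ge") ">=" else "<="
  cat(sprintf("Youden-optimal rule: predictor %s %g (J = %.3f, sens %.3f, spec %.3f; %d pos / %d neg)\n",
              op, x$cutoff, x$youden, x$sensitivity, x$specificity,
              x$n_pos, x$n_neg))
  invisible(x)
}

#' Depth-1 classification-tree split (decision stump)
#'
#' The single binary split minimising weighted Gini impurity, evaluated
#' exhaustively over the midpoints between adjacent distinct predictor
#' values. Serves as a cross-check on the Youden-optimal cutoff: with
#' separable data the two coincide on the same boundary.
#'
#' @inheritParams empirical_roc
#' @return List with `cutoff` (the split point, `NA` when no split reduces
#'   impurity), `gain` (impurity decrease), `informative` (logical).
#' @export
stump_cutoff <- function(labels, predictor) {
  labels <- as.integer(labels)
  n <- length(labels)
  if (sum(labels == 1L) == 0L || sum(labels == 0L) == 0L) {
    stop_smnas("degenerate labels: only one class present",
               class = "smnas_degenerate")
  }
  gini <- function(p) 2 * p * (1 - p)
  root <- gini(mean(labels))
  vals <- sort(unique(predictor))
  if (length(vals) < 2L) {
    return(list(cutoff = NA_real_, gain = 0, informative = FALSE))
  }
  splits <- (vals[-length(vals)] + vals[-1L]) / 2
  gains <- vapply(splits, function(s) {
    left <- predictor <= s
    nl <- sum(left); nr <- n - nl
    root - (nl / n) * gini(mean(labels[left])) -
      (nr / n) * gini(mean(labels[!left]))
  }, numeric(1))
  best <- which.max(gains)
  if (gains[[best]] <= 1e-12) {
    return(list(cutoff = NA_real_, gain = 0, informative = FALSE))
  }
  list(cutoff = splits[[best]], gain = gains[[best]], informative = TRUE)
}

#' Derive short-scale cutoffs for all six indicators
#'
#' For each full-scale indicator, builds the binary response labels from the
#' full-scale metrics, takes the same-form short-scale metric as predictor,
#' and selects the Youden-optimal cutoff (with the decision-stump split
#' reported alongside as a cross-check). Observations are pooled across
#' infants. When a train/test split is supplied, only training-set rows are
#' used and the training infant ids are recorded on the result for the
#' downstream leakage check.
#'
#' @param metrics Metrics table from [build_metrics_table()].
#' @param specs Indicator table, default [indicator_specs()].
#' @param split Optional split assignment from [split_infants()]; when given,
#'   only rows of infants assigned to `"train"` are used.
#' @return Data frame of class `smnas_cutoffs`, one row per indicator:
#'   `indicator`, `full_metric`, `full_comparator`, `full_threshold`,
#'   `short_metric`, `direction` (`>=` or `<=`), `cutoff`, `cutoff_raw`,
#'   `youden`, `sensitivity`, `specificity`, `n_pos`, `n_neg`, `n_dropped`,
#'   `stump_split`. Attribute `train_infants` carries the infant ids used.
#' @export
derive_all <- function(metrics, specs = indicator_specs(), split = NULL) {
  if (!is.null(split)) {
    train_ids <- split$infant_id[split$set == "train"]
    metrics <- metrics[metrics$infant_id %in% train_ids, , drop = FALSE]
  } else {
    train_ids <- unique(metrics$infant_id)
  }
  if (nrow(metrics) == 0L) {
    stop_smnas("empty metrics table: nothing to derive cutoffs from",
               class = "smnas_bad_input")
  }
  rows <- lapply(seq_len(nrow(specs)), function(j) {
    spec <- specs[j, ]
    lab <- make_labels(metrics, spec)
    pred <- metrics[[metric_column(spec$metric, "short")]][lab$kept]
    fit <- youden_optimal_cutoff(lab$labels, pred,
                                 orientation = spec$orientation,
                                 round_digits = spec$round_digits)
    stump <- stump_cutoff(lab$labels, pred)
    data.frame(indicator = spec$name,
               full_metric = spec$metric,
               full_comparator = spec$comparator,
               full_threshold = spec$threshold,
               short_metric = metric_column(spec$metric, "short"),
               direction = if (spec$orientation == "ge") ">=" else "<=",
               cutoff = fit$cutoff, cutoff_raw = fit$cutoff_raw,
               youden = fit$youden, sensitivity = fit$sensitivity,
               specificity = fit$specificity,
               n_pos = fit$n_pos, n_neg = fit$n_neg,
               n_dropped = lab$n_dropped,
               stump_split = stump$cutoff)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "train_infants") <- unique(train_ids)
  class(out) <- c("smnas_cutoffs", "data.frame")
  out
}
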