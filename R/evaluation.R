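#' Randomly split infants into training and test sets
#'
#' Each infant is assigned to the training set independently with
#' probability `p` (default 0.5); the rest form the test set. The assignment
#' is reproducible from the seed and splits by infant, never by observation,
#' so all of an infant's scores land on one side.
#'
#' @param ids Vector of unique infant identifiers.
#' @param p Training-set probability, strictly between 0 and 1.
#' @param seed Integer seed.
#' @return Data frame of class `smnas_split` with columns `infant_id`, `set`
#'   (`"train"`/`"test"`); attribute `seed`.
#' @export
split_infants <- function(ids, p = 0.5, seed) {
  stopifnot(p > 0, p < 1)
  ids <- unique(ids)
  train <- with_seed(seed, stats::runif(length(ids)) < p)
  out <- data.frame(infant_id = ids,
                    set = ifelse(train, "train", "test"))
  attr(out, "seed") <- seed
  class(out) <- c("smnas_split", "data.frame")
  out
}

#' 2x2 confusion counts
#'
#' Counts agreement between the full-scale rule (the reference label) and
#' the short-scale rule (the prediction).
#'
#' @param labels,predictions Equal-length binary 0/1 vectors.
#' @return Named numeric vector `c(tp, fp, tn, fn)`.
#' @export
confusion <- function(labels, predictions) {
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  stopifnot(length(labels) == length(predictions),
            all(labels %in% 0:1), all(predictions %in% 0:1))
  c(tp = sum(labels == 1L & predictions == 1L),
    fp = sum(labels == 0L & predictions == 1L),
    tn = sum(labels == 0L & predictions == 0L),
    fn = sum(labels == 1L & predictions == 0L))
}

#' Sensitivity and specificity from confusion counts
#'
#' @param counts Named vector as from [confusion()].
#' @return List with `sensitivity` = tp/(tp+fn) and
#'   `specificity` = tn/(tn+fp).
#' @export
sens_spec <- function(counts) {
  if (counts[["tp"]] + counts[["fn"]] == 0) {
    stop_smnas("no positives: sensitivity undefined", class = "smnas_degenerate")
  }
  if (counts[["tn"]] + counts[["fp"]] == 0) {
    stop_smnas("no negatives: specificity undefined", class = "smnas_degenerate")
  }
  list(sensitivity = counts[["tp"]] / (counts[["tp"]] + counts[["fn"]]),
       specificity = counts[["tn"]] / (counts[["tn"]] + counts[["fp"]]))
}

#' Bootstrap percentile confidence intervals for sensitivity and specificity
#'
#' Point estimates come from the observed 2x2 table and do not depend on the
#' bootstrap seed; only the intervals do. The default resampling unit is the
#' observation, stratified by the reference label (positives and negatives
#' resampled separately, mirroring common ROC-bootstrap practice); an
#' infant-level clustered bootstrap is available because observations within
#' an infant are autocorrelated. Clustered resamples in which one label
#' class is absent are redrawn and counted.
#'
#' @param labels,predictions Binary 0/1 vectors.
#' @param n_boot Number of bootstrap resamples (>= 100; default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed (required, for reproducibility).
#' @param unit `"observation"` (stratified) or `"infant"` (clustered;
#'   requires `infant_id`).
#' @param infant_id Infant id per observation, for the clustered bootstrap.
#' @return List of class `smnas_eval`: counts, `sensitivity`, `specificity`,
#'   `sens_ci`, `spec_ci` (length-2 vectors), `n_boot`, `level`, `seed`,
#'   `unit`, `n_degenerate_redraws`.
#' @export
bootstrap_ci <- function(labels, predictions, n_boot = 2000, level = 0.95,
                         seed, unit = c("observation", "infant"),
                         infant_id = NULL) {
  unit <- match.arg(unit)
  stopifnot(n_boot >= 100)
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  counts <- confusion(labels, predictions)
  point <- sens_spec(counts)
  alpha <- (1 - level) / 2
  n_degenerate <- 0L
  if (unit == "observation") {
    pred_pos <- predictions[labels == 1L]
    pred_neg <- predictions[labels == 0L]
    boots <- with_seed(seed, {
      n_pos <- length(pred_pos); n_neg <- length(pred_neg)
      sens_b <- colMeans(matrix(
        sample(pred_pos, n_pos * n_boot, replace = TRUE), nrow = n_pos))
      spec_b <- colMeans(matrix(
        1L - sample(pred_neg, n_neg * n_boot, replace = TRUE), nrow = n_neg))
      list(sens = sens_b, spec = spec_b)
    })
  } else {
    if (is.null(infant_id)) {
      stop_smnas("infant_id required for the clustered bootstrap",
                 class = "smnas_bad_input")
    }
    groups <- split(seq_along(labels), infant_id)
    boots <- with_seed(seed, {
      sens_b <- numeric(n_boot); spec_b <- numeric(n_boot)
      for (b in seq_len(n_boot)) {
        repeat {
          take <- unlist(groups[sample.int(length(groups), replace = TRUE)],
                         use.names = FALSE)
          lb <- labels[take]
          if (any(lb == 1L) && any(lb == 0L)) break
          n_degenerate <- n_degenerate + 1L
        }
        pb <- predictions[take]
        sens_b[[b]] <- mean(pb[lb == 1L])
        spec_b[[b]] <- mean(1L - pb[lb == 0L])
      }
      list(sens = sens_b, spec = spec_b)
    })
  }
  structure(list(
    counts = counts,
    sensitivity = point$sensitivity, specificity = point$specificity,
    sens_ci = unname(stats::quantile(boots$sens, c(alpha, 1 - alpha))),
    spec_ci = unname(stats::quantile(boots$spec, c(alpha, 1 - alpha))),
    n_boot = n_boot, level = level, seed = seed, unit = unit,
    n_degenerate_redraws = n_degenerate),
    class = "smnas_eval")
}

#' @export
print.smnas_eval <- function(x, ...) {
  cat(sprintf("sensitivity %.3f (%.3f-%.3f), specificity %.3f (%.3f-%.3f)  [n_boot %d, %s bootstrap]\n",
              x$sensitivity, x$sens_ci[[1]], x$sens_ci[[2]],
              x$specificity, x$spec_ci[[1]], x$spec_ci[[2]],
              x$n_boot, x$unit))
  invisible(x)
}

#' Evaluate derived short-scale rules on the test set
#'
#' Applies each derived short-scale cutoff to the test-set rows and measures
#' how well it reproduces the full-scale rule, reporting sensitivity and
#' specificity with bootstrap confidence intervals. Infant-level
#' train/test disjointness is asserted on every run: an error is raised if
#' any infant used for cutoff derivation appears in the evaluation rows.
#'
#' @param metrics Metrics table from [build_metrics_table()].
#' @param split Split assignment from [split_infants()].
#' @param cutoffs Cutoff table from [derive_all()].
#' @param specs Indicator table, default [indicator_specs()].
#' @param n_boot,level,seed,unit Passed to [bootstrap_ci()].
#' @return Data frame of class `smnas_eval_table`, one row per indicator:
#'   the matching short rule, tp/fp/tn/fn, sensitivity and specificity with
#'   CI bounds, and the number of rows dropped for missing metrics.
#' @export
evaluate_rules_on_test <- function(metrics, split, cutoffs,
                                   specs = indicator_specs(),
                                   n_boot = 2000, level = 0.95, seed,
                                   unit = c("observation", "infant")) {
  unit <- match.arg(unit)
  test_ids <- split$infant_id[split$set == "test"]
  train_used <- attr(cutoffs, "train_infants")
  leaked <- intersect(train_used, test_ids)
  if (length(leaked) > 0L) {
    stop_smnas("train/test leakage: infant %s used for derivation appears in the test set",
               leaked[[1L]], class = "smnas_leakage")
  }
  test <- metrics[metrics$infant_id %in% test_ids, , drop = FALSE]
  if (nrow(test) == 0L) {
    stop_smnas("no test-set rows to evaluate", class = "smnas_bad_input")
  }
  rows <- lapply(seq_len(nrow(cutoffs)), function(j) {
    cut <- cutoffs[j, ]
    spec <- specs[specs$name == cut$indicator, ]
    lab <- make_labels(test, spec)
    pred_vals <- test[[cut$short_metric]][lab$kept]
    preds <- as.integer(apply_comparator(pred_vals, cut$direction, cut$cutoff))
    ev <- bootstrap_ci(lab$labels, preds, n_boot = n_boot, level = level,
                       seed = seed, unit = unit,
                       infant_id = test$infant_id[lab$kept])
    data.frame(indicator = cut$indicator,
               short_rule = sprintf("%s %s %g", cut$short_metric,
                                    cut$direction, cut$cutoff),
               tp = ev$counts[["tp"]], fp = ev$counts[["fp"]],
               tn = ev$counts[["tn"]], fn = ev$counts[["fn"]],
               sensitivity = ev$sensitivity,
               sens_ci_low = ev$sens_ci[[1]], sens_ci_high = ev$sens_ci[[2]],
               specificity = ev$specificity,
               spec_ci_low = ev$spec_ci[[1]], spec_ci_high = ev$spec_ci[[2]],
               n_dropped = lab$n_dropped)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_boot") <- n_boot
  attr(out, "level") <- level
  attr(out, "seed") <- seed
  attr(out, "unit") <- unit
  class(out) <- c("smnas_eval_table", "data.frame")
  out
}
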