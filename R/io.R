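#' Read and write score-sheet CSV files
#'
#' A score sheet has columns `infant_id`, `timestamp_h`, then either one
#' numeric column per instrument item (0 = sign assessed and absent) or
#' precomputed `full_score`/`short_score` columns, or both. When item
#' columns are present and an instrument is supplied, the summed scores are
#' (re)computed from the items, so stored sums can never drift from the
#' item-level data.
#'
#' @param path CSV file path.
#' @param instrument An `smnas_instrument` to score item columns with, or
#'   `NULL` to require precomputed score columns.
#' @return Data frame of score records with `full_score` and `short_score`.
#' @export
read_score_sheet <- function(path, instrument = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_cols(df, c("infant_id", "timestamp_h"), "score sheet")
  if (!is.null(instrument) &&
      all(instrument_items(instrument) %in% names(df))) {
    df$full_score <- NULL; df$short_score <- NULL
    df <- score_records(instrument, df)
  } else {
    check_cols(df, c("full_score", "short_score"), "score sheet")
  }
  df$infant_id <- as.character(df$infant_id)
  order_by_infant_time(df)
}

#' @rdname read_score_sheet
#' @param scores Score table to write.
#' @export
write_score_sheet <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read and write dose-event CSV files
#'
#' Dose events have columns `infant_id`, `timestamp_h`, `drug`, `action`
#' (initiate / increase / decrease / maintain / rescue / discontinue) and
#' `dose` (the dose after the action, in the rule set's configured units).
#'
#' @param path CSV file path.
#' @return Data frame of dose events.
#' @export
read_dose_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_cols(df, c("infant_id", "timestamp_h", "drug", "action", "dose"),
             "dose table")
  df$infant_id <- as.character(df$infant_id)
  order_by_infant_time(df)
}

#' @rdname read_dose_events
#' @param doses Dose-event table to write.
#' @export
write_dose_events <- function(doses, path) {
  utils::write.csv(doses, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read and write metrics CSV files
#'
#' One row per score record with all longitudinal metric columns; an
#' undefined sum of 3 consecutive scores (fewer than 3 observations) is
#' written as an empty field and read back as `NA`.
#'
#' @param path CSV file path.
#' @return Data frame of metrics rows.
#' @export
read_metrics <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_cols(df, c("infant_id", "timestamp_h", "full_score", "short_score",
                   "avg24_full", "avg24_short", "sum3_full", "sum3_short"),
             "metrics table")
  df$infant_id <- as.character(df$infant_id)
  df
}

#' @rdname read_metrics
#' @param metrics Metrics table to write.
#' @export
write_metrics <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
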