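# internal helpers shared across modules

#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_smnas <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "smnas_error")))
}

check_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_smnas("%s is missing required column(s): %s", what,
               paste(missing, collapse = ", "), class = "smnas_bad_input")
  }
  invisible(df)
}

# chronological order within infant, stable for ties
order_by_infant_time <- function(df) {
  df[order(df$infant_id, df$timestamp_h), , drop = FALSE]
}
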