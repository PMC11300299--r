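#' Load a withdrawal-scoring instrument definition
#'
#' Reads a JSON instrument definition (items, ordered severity levels with
#' point values, and full/short scale membership flags) and validates its
#' structure. The package ships the MOTHER NAS scale (MNAS, 19 scored
#' elements, summed score 0-43) together with its nested 9-element
#' abbreviation (sMNAS-9, summed score 0-19); this shipped definition is
#' loaded when `path` is `NULL`.
#'
#' Structural requirements enforced here: item names are unique; every item
#' has at least one severity level; points are strictly increasing across a
#' given item's ordered levels; every short-scale item is also a full-scale
#' item (the short scale is a subset of the full scale).
#'
#' @param path Path to a JSON definition file, or `NULL` for the shipped
#'   MNAS/sMNAS-9 definition.
#' @return An object of class `smnas_instrument`: a list with `items` (each a
#'   list with `name`, `levels` data frame of `description`/`points`,
#'   `in_full`, `in_short`) and `unscored_elements` (character vector of
#'   elements recorded as present/absent but never summed).
#' @seealso [validate_instrument()], [score_record()], [write_instrument()]
#' @export
#' @examples
#' instr <- load_instrument()
#' validate_instrument(instr)
load_instrument <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mnas_smnas9.json", package = "smnas9",
                        mustWork = TRUE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  items <- lapply(raw$items, function(it) {
    levels <- do.call(rbind, lapply(it$levels, function(lv) {
      data.frame(description = as.character(lv$description),
                 points = as.numeric(lv$points))
    }))
    list(name = as.character(it$name),
         levels = levels,
         in_full = isTRUE(it$in_full),
         in_short = isTRUE(it$in_short))
  })
  instr <- structure(
    list(name = raw$name %||% "instrument",
         items = items,
         unscored_elements = vapply(raw$unscored_elements %||% list(),
                                    as.character, character(1))),
    class = "smnas_instrument")
  check_instrument_structure(instr)
  instr
}

# structural invariants; stops with the offending item named
check_instrument_structure <- function(instr) {
  nms <- vapply(instr$items, `[[`, character(1), "name")
  dup <- nms[duplicated(nms)]
  if (length(dup) > 0L) {
    stop_smnas("duplicate item name: %s", dup[[1L]],
               class = "smnas_invalid_instrument")
  }
  for (it in instr$items) {
    if (is.null(it$levels) || nrow(it$levels) < 1L) {
      stop_smnas("item '%s' has no severity levels", it$name,
                 class = "smnas_invalid_instrument")
    }
    if (any(it$levels$points < 0)) {
      stop_smnas("item '%s' has negative points", it$name,
                 class = "smnas_invalid_instrument")
    }
    if (nrow(it$levels) > 1L && any(diff(it$levels$points) <= 0)) {
      stop_smnas("item '%s' has non-monotone points across levels", it$name,
                 class = "smnas_invalid_instrument")
    }
    if (it$in_short && !it$in_full) {
      stop_smnas("short item not in full: '%s'", it$name,
                 class = "smnas_invalid_instrument")
    }
  }
  invisible(instr)
}

#' Validate an instrument definition against the printed score ranges
#'
#' Computes the attainable summed-score maxima of the full and short scales
#' and the item counts, and flags (without raising) any departure from the
#' expected MNAS/sMNAS-9 ranges: full-scale maximum 43 over 19 items, short
#' scale maximum 19 over 9 items.
#'
#' @param instr An `smnas_instrument`.
#' @param expected_full_max,expected_short_max Expected scale maxima; the
#'   MNAS/sMNAS-9 printed ranges by default.
#' @return A list of class `smnas_instrument_report` with `full_max`,
#'   `short_max`, `n_full`, `n_short`, a character vector `flags` (empty when
#'   all expectations hold) and logical `ok`.
#' @export
validate_instrument <- function(instr, expected_full_max = 43,
                                expected_short_max = 19) {
  stopifnot(inherits(instr, "smnas_instrument"))
  max_pts <- vapply(instr$items, function(it) max(it$levels$points), numeric(1))
  in_full <- vapply(instr$items, `[[`, logical(1), "in_full")
  in_short <- vapply(instr$items, `[[`, logical(1), "in_short")
  full_max <- sum(max_pts[in_full])
  short_max <- sum(max_pts[in_short])
  flags <- character(0)
  if (full_max != expected_full_max) {
    flags <- c(flags, sprintf("full-scale maximum %g != expected %g",
                              full_max, expected_full_max))
  }
  if (short_max != expected_short_max) {
    flags <- c(flags, sprintf("short-scale maximum %g != expected %g",
                              short_max, expected_short_max))
  }
  structure(list(full_max = full_max, short_max = short_max,
                 n_full = sum(in_full), n_short = sum(in_short),
                 flags = flags, ok = length(flags) == 0L),
            class = "smnas_instrument_report")
}

#' @export
print.smnas_instrument_report <- function(x, ...) {
  cat(sprintf("Instrument: %d full-scale items (max %g), %d short-scale items (max %g)\n",
              x$n_full, x$full_max, x$n_short, x$short_max))
  if (x$ok) cat("All expected score ranges hold.\n")
  else cat("Flags:\n", paste0("  - ", x$flags, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
print.smnas_instrument <- function(x, ...) {
  rep <- validate_instrument(x)
  cat(sprintf("<smnas_instrument> %s\n", x$name))
  print(rep)
  invisible(x)
}

#' Compute summed full- and short-scale scores for one assessment
#'
#' Sums the per-item points of a single scoring observation over the
#' full-scale items and over the short-scale items. Every full-scale item
#' must be present in `item_points`: a value of 0 is the explicit
#' "sign assessed and absent" marker (all items are assessed at every scoring
#' time), while a missing entry is an error, so data-entry omissions are not
#' silently zero-filled.
#'
#' @param instr An `smnas_instrument`.
#' @param item_points Named numeric vector or list mapping item name to the
#'   chosen level's points (0 = sign absent).
#' @return A list with integer `full_score` and `short_score`
#'   (`short_score <= full_score` always, since the short items are a subset).
#' @export
#' @examples
#' instr <- load_instrument()
#' pts <- setNames(rep(0, 19), vapply(instr$items, `[[`, "", "name"))
#' pts[["crying"]] <- 3; pts[["tremors_undisturbed"]] <- 2
#' score_record(instr, pts)
score_record <- function(instr, item_points) {
  stopifnot(inherits(instr, "smnas_instrument"))
  item_points <- unlist(item_points)
  nms <- vapply(instr$items, `[[`, character(1), "name")
  unknown <- setdiff(names(item_points), nms)
  if (length(unknown) > 0L) {
    stop_smnas("unknown item: %s", unknown[[1L]], class = "smnas_bad_score")
  }
  full <- 0; short <- 0
  for (it in instr$items) {
    if (!it$in_full) next
    if (!it$name %in% names(item_points) || is.na(item_points[[it$name]])) {
      stop_smnas("item '%s' neither scored nor marked absent", it$name,
                 class = "smnas_bad_score")
    }
    v <- item_points[[it$name]]
    if (v != 0 && !v %in% it$levels$points) {
      stop_smnas("illegal points value %g for item '%s'", v, it$name,
                 class = "smnas_bad_score")
    }
    full <- full + v
    if (it$in_short) short <- short + v
  }
  list(full_score = as.integer(full), short_score = as.integer(short))
}

#' Score every row of an item-level score sheet
#'
#' Vectorised [score_record()] over a data frame with one column per
#' instrument item, appending `full_score` and `short_score` columns.
#'
#' @param instr An `smnas_instrument`.
#' @param sheet Data frame with columns `infant_id`, `timestamp_h` and one
#'   numeric column per full-scale item (0 = sign absent).
#' @return `sheet` with `full_score` and `short_score` appended.
#' @export
score_records <- function(instr, sheet) {
  stopifnot(inherits(instr, "smnas_instrument"))
  check_cols(sheet, c("infant_id", "timestamp_h"), "score sheet")
  nms <- vapply(instr$items, `[[`, character(1), "name")
  check_cols(sheet, nms, "score sheet")
  full <- numeric(nrow(sheet)); short <- numeric(nrow(sheet))
  for (it in instr$items) {
    if (!it$in_full) next
    v <- sheet[[it$name]]
    if (anyNA(v)) {
      stop_smnas("item '%s' neither scored nor marked absent", it$name,
                 class = "smnas_bad_score")
    }
    bad <- v != 0 & !v %in% it$levels$points
    if (any(bad)) {
      stop_smnas("illegal points value %g for item '%s'", v[bad][[1L]],
                 it$name, class = "smnas_bad_score")
    }
    full <- full + v
    if (it$in_short) short <- short + v
  }
  sheet$full_score <- as.integer(full)
  sheet$short_score <- as.integer(short)
  sheet
}

#' Write an instrument definition to JSON
#'
#' Serialises an `smnas_instrument` so that [load_instrument()] on the
#' written file reproduces an identical definition (round-trip safe).
#'
#' @param instr An `smnas_instrument`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_instrument <- function(instr, path) {
  stopifnot(inherits(instr, "smnas_instrument"))
  out <- list(
    name = instr$name,
    items = lapply(instr$items, function(it) {
      list(name = it$name,
           in_full = it$in_full,
           in_short = it$in_short,
           levels = lapply(seq_len(nrow(it$levels)), function(i) {
             list(description = it$levels$description[[i]],
                  points = it$levels$points[[i]])
           }))
    }),
    unscored_elements = as.list(instr$unscored_elements))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Item names of an instrument
#'
#' @param instr An `smnas_instrument`.
#' @param scale `"full"` (all scored items) or `"short"`.
#' @return Character vector of item names.
#' @export
instrument_items <- function(instr, scale = c("full", "short")) {
  scale <- match.arg(scale)
  keep <- vapply(instr$items, `[[`, logical(1),
                 if (scale == "full") "in_full" else "in_short")
  vapply(instr$items, `[[`, character(1), "name")[keep]
}
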