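metrics_row <- function(scale = "short", single = 0, avg24 = 0, sum3 = 0,
                        t = 100, flag48 = TRUE, flag24 = TRUE,
                        had_dec = FALSE, id = "a") {
  row <- list(infant_id = id, timestamp_h = t,
              flag_48h_since_increase = flag48,
              flag_24h_since_decrease = flag24,
              had_first_decrease = had_dec)
  row[[paste0(scale, "_score")]] <- single
  row[[paste0("avg24_", scale)]] <- avg24
  row[[paste0("sum3_", scale)]] <- sum3
  row
}

test_that("indicator conditions match their boundary definitions", {
  full <- metrics_row("full", single = 5, avg24 = 7.9, sum3 = 20)
  ind <- evaluate_indicators(full, "full")
  expect_true(ind[["i"]])   # 7.9 < 8
  expect_true(ind[["ii"]])

  at8 <- evaluate_indicators(metrics_row("full", avg24 = 8, sum3 = 20), "full")
  expect_false(at8[["i"]])  # 8 is not < 8
  expect_true(at8[["ii"]])  # but is <= 8

  short <- evaluate_indicators(metrics_row("short", avg24 = 4.5, sum3 = 12), "short")
  expect_true(short[["i"]])  # 4.5 < 4.6 weaning indicator

  init <- evaluate_indicators(metrics_row("short", single = 7, avg24 = 9, sum3 = 21),
                              "short")
  expect_true(init[["vi"]])  # single short score of 7 triggers initiation/rescue

  # comparator asymmetry of indicator (iii): strict on full, non-strict on short
  expect_false(evaluate_indicators(metrics_row("full", sum3 = 18, avg24 = 9),
                                   "full")[["iii"]])
  expect_true(evaluate_indicators(metrics_row("short", sum3 = 10, avg24 = 9),
                                  "short")[["iii"]])

  # undefined sum of 3: indicators false, flagged
  m <- metrics_row("short", single = 8, avg24 = 8, sum3 = NA)
  ind_na <- evaluate_indicators(m, "short")
  expect_false(ind_na[["iv"]])
  expect_false(ind_na[["v"]])
  expect_true(attr(ind_na, "sum3_missing"))
})

test_that("all shipped rule sets load and are structurally complete", {
  for (nm in c("morphine_full", "morphine_short",
               "buprenorphine_full", "buprenorphine_short")) {
    rs <- load_ruleset(nm)
    expect_s3_class(rs, "smnas_ruleset")
    actions <- vapply(rs$rules, `[[`, character(1), "action")
    expect_true(all(c("initiate", "increase", "decrease", "discontinue")
                    %in% actions))
    prio <- vapply(rs$rules, `[[`, integer(1), "priority")
    expect_false(anyDuplicated(prio) > 0)
  }
})

test_that("malformed rule sets are rejected", {
  raw <- jsonlite::read_json(system.file("extdata", "rulesets",
                                         "morphine_short.json",
                                         package = "smnas9"))
  dup <- raw
  dup$rules[[2]]$priority <- dup$rules[[1]]$priority
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(dup, path, auto_unbox = TRUE)
  expect_error(load_ruleset(path), "unique")

  gutted <- raw
  gutted$rules <- Filter(function(r) r$action != "discontinue", gutted$rules)
  jsonlite::write_json(gutted, path, auto_unbox = TRUE)
  expect_error(load_ruleset(path), "lacks a 'discontinue' rule")
})

test_that("step fires the right rule, at most one per observation", {
  rs <- load_ruleset("morphine_short")
  state0 <- smnas9:::new_engine_state(rs, 0)

  # untreated infant with a single high score: initiation at the start dose
  res <- step(state0, metrics_row(single = 8, avg24 = 8, sum3 = NA), rs)
  expect_equal(res$event$action, "initiate")
  expect_equal(res$event$dose, rs$start_dose)
  expect_true(res$state$treating)

  # treated infant with escalation-level sum of 3: dose increase
  res2 <- step(res$state, metrics_row(single = 5, avg24 = 6, sum3 = 14), rs)
  expect_equal(res2$event$action, "increase")
  expect_gt(res2$state$dose, rs$start_dose)

  # weaning condition met but the 48-h stability guard blocks it
  res3 <- step(res2$state, metrics_row(avg24 = 3, sum3 = 6, flag48 = FALSE), rs)
  expect_null(res3$event)
  expect_true(is.na(res3$fired))

  # with the guard satisfied the wean fires
  res4 <- step(res2$state, metrics_row(avg24 = 3, sum3 = 6), rs)
  expect_equal(res4$event$action, "decrease")
  expect_lt(res4$state$dose, res2$state$dose)

  # dose clipped at max_dose under repeated escalation
  st <- res2$state
  for (i in 1:40) {
    st <- step(st, metrics_row(single = 9, avg24 = 9, sum3 = 18), rs)$state
    expect_lte(st$dose, rs$max_dose)
  }
  expect_equal(st$dose, rs$max_dose)

  # stepping after discontinuation is an error
  done <- res4$state; done$discontinued <- TRUE
  expect_error(step(done, metrics_row(), rs), "after discontinue")
})

test_that("randomised steps never fire more than one rule and stay in dose bounds", {
  rs <- load_ruleset("morphine_short")
  set.seed(42)
  state <- smnas9:::new_engine_state(rs, 0)
  for (i in 1:300) {
    row <- metrics_row(single = sample(0:19, 1),
                       avg24 = runif(1, 0, 19),
                       sum3 = if (runif(1) < 0.1) NA else sample(0:57, 1),
                       t = i * 3.5,
                       flag48 = runif(1) < 0.5, flag24 = runif(1) < 0.5,
                       had_dec = state$had_first_decrease)
    res <- step(state, row, rs)
    expect_lte(length(res$fired[!is.na(res$fired)]), 1L)
    state <- res$state
    expect_gte(state$dose, 0)
    expect_lte(state$dose, rs$max_dose)
    if (state$discontinued) break
  }
})

test_that("tightening a guard can only remove a firing, never add one", {
  rs_loose <- load_ruleset("morphine_short")
  rs_tight <- rs_loose
  wean_i <- which(vapply(rs_tight$rules, `[[`, character(1), "name") == "wean")
  rs_tight$rules[[wean_i]]$guards <- c(rs_tight$rules[[wean_i]]$guards,
                                       "had_first_decrease")
  set.seed(7)
  st <- smnas9:::new_engine_state(rs_loose, 0)
  st$treating <- TRUE; st$dose <- 0.4
  for (i in 1:200) {
    row <- metrics_row(single = sample(0:10, 1), avg24 = runif(1, 0, 10),
                       sum3 = sample(0:30, 1),
                       flag48 = runif(1) < 0.7, flag24 = runif(1) < 0.7,
                       had_dec = runif(1) < 0.5)
    fired_tight <- step(st, row, rs_tight)$fired
    fired_loose <- step(st, row, rs_loose)$fired
    if (identical(fired_tight, "wean")) expect_identical(fired_loose, "wean")
  }
})

test_that("a forced high-then-low course walks through a full episode", {
  sc <- forced_trajectory(high_full = 24, low_full = 2,
                          n_high = 3, n_low = 140)
  rs <- load_ruleset("morphine_short")
  trace <- run_episode(sc, rs)
  acts <- trace$action
  expect_equal(acts[1], "initiate")
  expect_true("increase" %in% acts)
  expect_true("decrease" %in% acts)
  expect_equal(acts[length(acts)], "discontinue")
  # canonical ordering: initiation before any increase, increases before
  # the first decrease, discontinuation last
  expect_lt(max(which(acts == "increase")), min(which(acts == "decrease")))
  expect_true(all(trace$dose >= 0))

  # determinism: identical inputs give identical traces
  expect_identical(run_episode(sc, rs), trace)

  # all-zero scores never initiate
  zero <- sc; zero$full_score <- 0; zero$short_score <- 0
  expect_equal(nrow(run_episode(zero, rs)), 0)
})

test_that("full- and short-scale rule sets agree when metrics are concordant", {
  # scores far from every cutoff boundary on both scales: the planted map
  # keeps each metric on the same side of its scale's cutoff throughout
  sc <- forced_trajectory(high_full = 24, low_full = 2,
                          n_high = 3, n_low = 140)
  t_full <- run_episode(sc, load_ruleset("morphine_full"))
  t_short <- run_episode(sc, load_ruleset("morphine_short"))
  expect_identical(t_full$action, t_short$action)
  expect_identical(t_full$timestamp_h, t_short$timestamp_h)
})
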