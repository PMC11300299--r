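test_that("make_labels encodes the full-scale conditions at their boundaries", {
  specs <- indicator_specs()
  m <- data.frame(infant_id = "a", timestamp_h = 1:3,
                  avg24_full = c(7.9, 8.0, 8.1),
                  sum3_full = c(NA, NA, NA),
                  full_score = c(7, 8, 9))
  lab_i <- make_labels(m, specs[specs$name == "i", ])
  expect_equal(lab_i$labels, c(1L, 0L, 0L))
  lab_ii <- make_labels(m, specs[specs$name == "ii", ])
  expect_equal(lab_ii$labels, c(1L, 1L, 0L))
  # all sum-of-3 values missing: empty labels, drops counted
  lab_iv <- make_labels(m, specs[specs$name == "iv", ])
  expect_length(lab_iv$labels, 0)
  expect_equal(lab_iv$n_dropped, 3)
})

test_that("empirical ROC enumerates candidate cutoffs correctly", {
  # perfectly separated data attains the perfect corner
  roc <- empirical_roc(c(0, 0, 1, 1), c(1, 2, 5, 6), "ge")
  expect_true(any(roc$sensitivity == 1 & roc$specificity == 1))

  # a constant predictor can only produce chance-line points
  roc_const <- empirical_roc(c(0, 1, 0, 1), rep(3, 4), "ge")
  expect_true(all(roc_const$sensitivity + roc_const$specificity == 1))

  # frozen enumeration over the 4 candidates (plus the infinite sentinel):
  # J = 0, 0.5, 0, 0.5, 0 at c = 1, 2, 3, 4, Inf
  roc4 <- empirical_roc(c(0, 1, 0, 1), c(1, 2, 3, 4), "ge")
  expect_equal(roc4$cutoff, c(1, 2, 3, 4, Inf))
  expect_equal(roc4$youden, c(0, 0.5, 0, 0.5, 0))
  expect_equal(max(roc4$youden), 0.5)

  expect_error(empirical_roc(c(1, 1), c(1, 2), "ge"), "degenerate ROC")
})

test_that("Youden optimisation picks the smallest maximising cutoff", {
  fit <- youden_optimal_cutoff(c(0, 1, 0, 1), c(1, 2, 3, 4), "ge")
  expect_equal(fit$cutoff, 2)  # 2 and 4 tie at J = 0.5; smallest wins
  expect_equal(fit$youden, 0.5)

  sep <- youden_optimal_cutoff(c(0, 1, 0, 1, 0), c(0, 10, 0, 10, 0), "ge")
  expect_equal(sep$cutoff, 10)
  expect_equal(sep$youden, 1)

  # planted calibration: the integer map interpolating the published pairs
  # makes "full >= 12" exactly equivalent to "short >= 7"
  full <- 0:43
  fit12 <- youden_optimal_cutoff(as.integer(full >= 12),
                                 planted_short_map(full), "ge",
                                 round_digits = 0)
  expect_equal(fit12$cutoff, 7)
  expect_equal(fit12$youden, 1)

  expect_error(youden_optimal_cutoff(rep(1, 4), 1:4, "ge"), "degenerate")
})

test_that("Youden cutoff agrees with exhaustive search on random instances", {
  set.seed(202)
  for (rep_i in 1:60) {
    n <- sample(5:120, 1)
    orientation <- sample(c("ge", "le"), 1)
    pred <- sample(0:25, n, replace = TRUE)
    labels <- as.integer(runif(n) < plogis((pred - 12) / 3))
    if (length(unique(labels)) < 2) next
    fit <- youden_optimal_cutoff(labels, pred, orientation)
    oracle <- naive_youden(labels, pred, orientation)
    expect_equal(fit$cutoff_raw, oracle$cutoff)
    expect_equal(fit$youden, oracle$youden)
  }
})

test_that("the Youden index is invariant under monotone predictor transforms", {
  set.seed(303)
  pred <- sample(1:30, 200, replace = TRUE)
  labels <- as.integer(runif(200) < plogis((pred - 15) / 4))
  fit <- youden_optimal_cutoff(labels, pred, "ge")
  trans <- function(x) x^3 + 2 * x   # strictly increasing
  fit_t <- youden_optimal_cutoff(labels, trans(pred), "ge")
  expect_equal(fit_t$youden, fit$youden)
  expect_equal(fit_t$cutoff_raw, trans(fit$cutoff_raw))
})

test_that("the decision stump minimises Gini impurity over midpoints", {
  # frozen by hand: candidate splits 1.5, 2.5, 3.5 give gains 1/6, 0, 1/6
  st <- stump_cutoff(c(0, 1, 0, 1), c(1, 2, 3, 4))
  expect_equal(st$cutoff, 1.5)
  expect_equal(st$gain, 1 / 6)

  # separable data: the stump split lands on the same boundary as Youden
  full <- 0:43
  st_sep <- stump_cutoff(as.integer(full >= 12), planted_short_map(full))
  expect_gt(st_sep$cutoff, 6)
  expect_lt(st_sep$cutoff, 7)

  # exchangeable predictor: no split reduces impurity
  st_null <- stump_cutoff(rep(c(0, 1), 50), rep(c(1, 2), each = 50))
  expect_false(st_null$informative)
  expect_true(is.na(st_null$cutoff))

  expect_error(stump_cutoff(rep(0, 5), 1:5), "degenerate")
})

test_that("the stump matches an independent depth-1 tree fit", {
  set.seed(404)
  pred <- sample(0:30, 400, replace = TRUE)
  labels <- as.integer(runif(400) < plogis((pred - 14) / 2))
  st <- stump_cutoff(labels, pred)
  fit <- rpart::rpart(y ~ x, data = data.frame(y = factor(labels), x = pred),
                      method = "class",
                      control = rpart::rpart.control(maxdepth = 1,
                                                     minsplit = 2,
                                                     minbucket = 1, cp = 0))
  expect_equal(st$cutoff, unname(fit$splits[1, "index"]))
})

test_that("Youden cutoffs match an independent ROC implementation", {
  set.seed(505)
  pred <- sample(0:30, 500, replace = TRUE)
  labels <- as.integer(runif(500) < plogis((pred - 14) / 3))
  fit <- youden_optimal_cutoff(labels, pred, "ge")
  roc <- pROC::roc(labels, pred, direction = "<", quiet = TRUE)
  best <- pROC::coords(roc, "best", best.method = "youden",
                       transpose = FALSE)
  # pROC places thresholds at midpoints; ours at observed values: the same
  # classification results
  expect_equal(fit$youden,
               max(best$sensitivity + best$specificity) - 1,
               tolerance = 1e-12)
})

test_that("derive_all recovers planted rules and validates inputs", {
  m <- planted_metrics(n_infants = 12, seed = 31)
  cuts <- derive_all(m)
  expect_s3_class(cuts, "smnas_cutoffs")
  expect_equal(nrow(cuts), 6)
  expect_equal(cuts$indicator, c("i", "ii", "iii", "iv", "v", "vi"))
  expect_true(all(!is.na(cuts$cutoff)))
  expect_true(all(cuts$youden >= 0.9))  # planted mapping is near-deterministic
  # the single-score rule is exactly the planted calibration pair
  expect_equal(cuts$cutoff[cuts$indicator == "vi"], 7)
  expect_equal(cuts$youden[cuts$indicator == "vi"], 1)
  # direction inherited from the full-scale comparator
  expect_equal(cuts$direction, c("<=", "<=", "<=", ">=", ">=", ">="))

  expect_error(derive_all(m[0, ]), "empty metrics")
})
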