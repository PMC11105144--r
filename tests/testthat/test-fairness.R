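test_that("group confusion counts match a hand-enumerated cohort", {
  # 8 subjects: (privileged, label, outcome)
  priv <- c(T, T, T, T, F, F, F, F)
  labels <- c(1, 1, 0, 0, 1, 0, 0, 1)
  outcomes <- c(1, 0, 1, 0, 1, 1, 0, 0)
  gc <- group_confusion(labels, outcomes, priv)
  p <- gc[gc$group == "privileged", ]
  u <- gc[gc$group == "unprivileged", ]
  expect_equal(c(p$tp, p$fp, p$tn, p$fn), c(1, 1, 1, 1))
  expect_equal(c(u$tp, u$fp, u$tn, u$fn), c(1, 1, 1, 1))
  expect_equal(p$n, 4)
  expect_equal(gc$tp + gc$fp + gc$tn + gc$fn, gc$n)
})

test_that("perfect predictions leave no errors in either group", {
  y <- c(1, 0, 1, 0, 1, 0)
  gc <- group_confusion(y, y, c(T, T, T, F, F, F))
  expect_true(all(gc$fp == 0) && all(gc$fn == 0))
})

test_that("swapping the privileged flag swaps the group rows", {
  withr::with_seed(9, {
    case <- random_eval_case(60)
    gc <- group_confusion(case$labels, case$outcomes, case$privileged)
    gs <- group_confusion(case$labels, case$outcomes, !case$privileged)
    for (col in c("n", "tp", "fp", "tn", "fn")) {
      expect_identical(gc[[col]], rev(gs[[col]]))
    }
  })
})

test_that("an empty group is an error naming the group", {
  expect_error(group_confusion(c(1, 0), c(1, 0), c(TRUE, TRUE)),
               "unprivileged group has zero subjects")
  expect_error(group_confusion(c(1, 0), c(1, 0), c(FALSE, FALSE)),
               "privileged group")
})

test_that("fairness metrics match hand arithmetic", {
  # unprivileged ppr 0.15 (3/20), privileged ppr 0.30 (6/20)
  priv <- rep(c(TRUE, FALSE), each = 20)
  labels <- c(rep(1, 6), rep(0, 14), rep(1, 3), rep(0, 17))
  outcomes <- c(rep(1, 8), rep(0, 12), rep(1, 8), rep(0, 12))
  gc <- group_confusion(labels, outcomes, priv)
  expect_equal(statistical_parity_difference(gc), -0.15)
  expect_equal(disparate_impact(gc), 0.5)
  # di times the privileged rate recovers the unprivileged rate
  expect_equal(disparate_impact(gc) * 0.30, 0.15)
})

test_that("difference metrics are zero for identical groups and follow definitions", {
  y <- c(1, 1, 0, 0)
  labels <- c(1, 0, 1, 0)
  gc <- group_confusion(rep(labels, 2), rep(y, 2), rep(c(TRUE, FALSE), each = 4))
  expect_equal(statistical_parity_difference(gc), 0)
  expect_equal(disparate_impact(gc), 1)
  expect_equal(equal_opportunity_difference(gc), 0)
  expect_equal(average_odds_difference(gc), 0)
  expect_equal(predictive_parity_difference(gc), 0)
})

test_that("average odds is the mean of the fpr and tpr differences", {
  withr::with_seed(23, {
    for (k in 1:25) {
      case <- random_eval_case()
      gc <- tryCatch(group_confusion(case$labels, case$outcomes, case$privileged),
                     error = function(e) NULL)
      if (is.null(gc)) next
      fpr_diff <- gc$fpr[gc$group == "unprivileged"] - gc$fpr[gc$group == "privileged"]
      expect_equal(average_odds_difference(gc),
                   mean(c(fpr_diff, equal_opportunity_difference(gc))))
    }
  })
})

test_that("all-negative predictions give zero parity difference and undefined ppv metrics", {
  priv <- c(TRUE, TRUE, FALSE, FALSE)
  gc <- group_confusion(c(0, 0, 0, 0), c(1, 0, 1, 0), priv)
  expect_equal(statistical_parity_difference(gc), 0)
  expect_true(is.na(disparate_impact(gc)))
  expect_true(is.na(predictive_parity_difference(gc)))
})

test_that("prevalence benchmark reproduces the published 2019 disparity pair", {
  # group prevalences 0.066 and 0.139: difference -0.073, ratio 0.476 within rounding
  n_u <- 1000; n_p <- 1000
  y <- c(rep(1, 66), rep(0, n_u - 66), rep(1, 139), rep(0, n_p - 139))
  priv <- rep(c(FALSE, TRUE), c(n_u, n_p))
  bm <- prevalence_benchmark(y, priv)
  expect_equal(bm$rate_difference, -0.073)
  expect_equal(bm$rate_ratio, 0.476, tolerance = 0.003)
  expect_equal(prevalence_benchmark(c(1, 0, 1, 0), c(T, T, F, F)),
               tibble::tibble(rate_difference = 0, rate_ratio = 1))
  expect_true(is.na(prevalence_benchmark(c(0, 0, 1, 0),
                                         c(T, T, F, F))$rate_ratio))
})

test_that("a generated crn-like cohort lands near its benchmark ratio", {
  prof <- dataset_profile("crn")
  off <- calibrate_offsets(prof)
  co <- generate_cohort(prof, n = 100000, seed = 14, offsets = off)
  bm <- prevalence_benchmark(co$outcome, is_privileged(co$race))
  expect_lt(abs(bm$rate_ratio - 1.005), 0.05)
})

test_that("the report flags ranges with inclusive endpoints and propagates NA", {
  # perfect predictor on a balanced cohort: all metrics at their ideals
  y <- rep(c(1, 0), 10)
  priv <- rep(c(TRUE, FALSE), each = 10)
  rep1 <- fairness_report(y, y, priv)
  expect_equal(rep1$value, c(0, 1, 0, 0, 0))
  expect_true(all(rep1$within_range))

  # spd exactly -0.1 is inside the closed interval
  labels <- c(rep(1, 4), rep(0, 6), rep(1, 3), rep(0, 7))
  priv2 <- rep(c(TRUE, FALSE), each = 10)
  outcomes <- rep(c(1, 0), 10)
  rep2 <- fairness_report(labels, outcomes, priv2)
  spd_row <- rep2[rep2$metric == "statistical_parity_difference", ]
  expect_equal(spd_row$value, -0.1)
  expect_true(spd_row$within_range)

  # undefined metrics surface as NA flags without aborting
  rep3 <- fairness_report(c(0, 0, 0, 0), c(1, 0, 1, 0), c(T, T, F, F))
  expect_true(is.na(rep3$value[rep3$metric == "disparate_impact"]))
  expect_true(is.na(rep3$within_range[rep3$metric == "disparate_impact"]))
})

test_that("excluding Unknown race drops those subjects from the audit", {
  race <- factor(c("White", "White", "Black", "Unknown"),
                 levels = race_levels())
  priv <- is_privileged(race, unknown = "exclude")
  expect_identical(priv, c(TRUE, TRUE, FALSE, NA))
  gc <- group_confusion(c(1, 0, 1, 1), c(1, 0, 1, 0), priv)
  expect_equal(sum(gc$n), 3)
  rep <- fairness_report(c(1, 0, 1, 1), c(1, 0, 1, 0), priv)
  expect_identical(attr(rep, "unknown_policy"), "excluded")
})

test_that("group-swap antisymmetry holds across random cases", {
  withr::with_seed(31, {
    for (k in 1:40) {
      case <- random_eval_case()
      gc <- group_confusion(case$labels, case$outcomes, case$privileged)
      gs <- group_confusion(case$labels, case$outcomes, !case$privileged)
      expect_equal(statistical_parity_difference(gs),
                   -statistical_parity_difference(gc))
      di <- disparate_impact(gc); dis <- disparate_impact(gs)
      if (!is.na(di) && !is.na(dis) && di > 0) {
        expect_equal(dis, 1 / di)
      }
      e1 <- equal_opportunity_difference(gc)
      e2 <- equal_opportunity_difference(gs)
      if (!is.na(e1)) expect_equal(e2, -e1)
      a1 <- average_odds_difference(gc); a2 <- average_odds_difference(gs)
      if (!is.na(a1)) expect_equal(a2, -a1)
      p1 <- predictive_parity_difference(gc)
      p2 <- predictive_parity_difference(gs)
      if (!is.na(p1)) expect_equal(p2, -p1)
    }
  })
})

test_that("group-independent predictions give vanishing parity difference", {
  withr::with_seed(55, {
    n <- 60000
    y <- rbinom(n, 1, 0.2)
    # probabilities depend on the outcome stratum only, never on the group
    p <- ifelse(y == 1, rbeta(n, 4, 2), rbeta(n, 2, 4))
    priv <- rbinom(n, 1, 0.5) == 1
    gc <- group_confusion(apply_threshold(p, 0.5), y, priv)
    expect_lt(abs(statistical_parity_difference(gc)), 0.02)
  })
})

test_that("fairness report JSON export captures metrics and benchmark", {
  rep <- fairness_report(c(1, 0, 1, 0), c(1, 0, 0, 1), c(T, T, F, F))
  path <- withr::local_tempfile(fileext = ".json")
  write_fairness_json(rep, path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(nrow(x$metrics), 5)
  expect_named(x$benchmark, c("rate_difference", "rate_ratio"))
  expect_equal(x$unknown_policy, "unprivileged")
})
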