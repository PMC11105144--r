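make_model <- function(intercept, coefficients, nullified = character(0)) {
  structure(
    list(intercept = intercept, coefficients = coefficients,
         l2_strength = 0, nullified_features = nullified,
         standardization = tibble::tibble(feature = names(coefficients),
                                          center = 0, scale = 1),
         training_meta = list(weighted = FALSE, n_obs = NA_integer_,
                              converged = TRUE, iterations = 0L,
                              feature_subset = names(coefficients))),
    class = "risk_model")
}

toy_data <- function(n = 400, p = 3, seed = 11) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", seq_len(p))))
    eta <- drop(X %*% seq(0.5, by = 0.3, length.out = p)) - 0.2
    tibble::as_tibble(X) |>
      dplyr::mutate(outcome = rbinom(n, 1, plogis(eta)))
  })
}

test_that("a dominant penalty shrinks coefficients to zero", {
  d <- toy_data()
  m <- fit_logistic_l2(d, c("x1", "x2", "x3"), l2_strength = 1e6)
  expect_true(all(abs(m$coefficients) < 0.01))
})

test_that("weight 2 for everyone equals duplicating everyone", {
  d <- toy_data(n = 300)
  m_dup <- fit_logistic_l2(dplyr::bind_rows(d, d), c("x1", "x2", "x3"),
                           l2_strength = 0.5)
  m_w <- fit_logistic_l2(d, c("x1", "x2", "x3"), l2_strength = 0.5,
                         weights = rep(2, nrow(d)))
  expect_equal(m_w$coefficients, m_dup$coefficients, tolerance = 1e-8)
  expect_equal(m_w$intercept, m_dup$intercept, tolerance = 1e-8)
})

test_that("scaling all weights by c equals rescaling the penalty", {
  d <- toy_data(n = 300, seed = 12)
  m_w <- fit_logistic_l2(d, c("x1", "x2", "x3"), l2_strength = 1,
                         weights = rep(3, nrow(d)))
  m_u <- fit_logistic_l2(d, c("x1", "x2", "x3"), l2_strength = 1 / 3)
  expect_equal(m_w$coefficients, m_u$coefficients, tolerance = 1e-8)
})

test_that("the fit maximizes the stated penalized likelihood (independent optimizer)", {
  withr::with_seed(202, {
    for (k in 1:20) {
      n <- sample(80:200, 1)
      p <- sample(2:4, 1)
      X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
      eta <- drop(X %*% rnorm(p, 0, 0.8))
      y <- rbinom(n, 1, plogis(eta))
      if (length(unique(y)) < 2) next
      w <- runif(n, 0.5, 2)
      l2 <- runif(1, 0.05, 2)
      d <- dplyr::mutate(tibble::as_tibble(X), outcome = y)
      m <- fit_logistic_l2(d, colnames(X), l2_strength = l2, weights = w)

      # same objective, standardized design built independently here
      Z <- scale(X, center = colMeans(X),
                 scale = apply(X, 2, function(v) sqrt(mean((v - mean(v))^2))))
      negobj <- function(b) {
        et <- b[1] + drop(Z %*% b[-1])
        -(sum(w * (y * et - log1p(exp(et)))) - l2 * sum(b[-1]^2))
      }
      o <- stats::optim(rep(0, p + 1), negobj, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-14))
      expect_equal(unname(c(m$intercept, m$coefficients)), o$par,
                   tolerance = 1e-4)
    }
  })
})

test_that("fitting rejects degenerate inputs", {
  d <- toy_data(n = 50)
  d$outcome <- 1L
  expect_error(fit_logistic_l2(d, "x1"), "single class")
  d2 <- toy_data(n = 50)
  d2$x1[3] <- Inf
  expect_error(fit_logistic_l2(d2, c("x1", "x2")), "Non-finite")
  expect_error(fit_logistic_l2(toy_data(), character(0)), "non-empty")
  expect_error(fit_logistic_l2(toy_data(), "nope"), "Missing columns")
  expect_error(fit_logistic_l2(toy_data(), "x1", weights = rep(-1, 400)),
               "positive")
})

test_that("predict_risk follows the logistic form and nullification semantics", {
  m <- make_model(0.4, c(a = 1, b = -2))
  d0 <- tibble::tibble(a = 0, b = 0)
  expect_equal(predict_risk(m, d0), plogis(0.4))

  m2 <- make_model(0, c(a = log(3)))
  expect_equal(predict_risk(m2, tibble::tibble(a = 1)), 0.75)

  # nullifying a feature is exactly scoring with that column zeroed
  d <- tibble::tibble(a = c(1, 0, 2), b = c(0.5, -1, 3))
  mn <- nullify_features(m, "b")
  dz <- dplyr::mutate(d, b = 0)
  expect_identical(predict_risk(mn, d), predict_risk(m, dz))
  # the nullified column need not even be present
  expect_identical(predict_risk(mn, d[, "a"]), predict_risk(mn, d))

  expect_error(predict_risk(m, tibble::tibble(a = 1)), "Missing feature.*b")
  expect_error(nullify_features(m, "zz"), "absent")
})

test_that("thresholding is inclusive and monotone", {
  probs <- c(0.1, 0.3, 0.9)
  expect_identical(apply_threshold(probs, 0.3)$label, c(0L, 1L, 1L))
  withr::with_seed(5, {
    p <- runif(200)
    pos02 <- which(apply_threshold(p, 0.2)$label == 1)
    pos04 <- which(apply_threshold(p, 0.4)$label == 1)
    expect_true(all(pos04 %in% pos02))
  })
  expect_identical(apply_threshold(c(0.1, 0.2), 0.5)$label, c(0L, 0L))
  expect_error(apply_threshold(probs, 0), "strictly inside")
  expect_error(apply_threshold(probs, 1), "strictly inside")
})

test_that("auc equals the Mann-Whitney probability with ties at one half", {
  expect_equal(auc(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auc(c(0.9, 0.6, 0.6, 0.2), c(1, 0, 1, 0)), 0.875)
  expect_error(auc(c(0.2, 0.3), c(1, 1)), "both outcome classes")
  # independent scores concentrate at 1/2
  withr::with_seed(77, {
    p <- runif(10000)
    y <- rbinom(10000, 1, 0.3)
    expect_lt(abs(auc(p, y) - 0.5), 0.02)
  })
})

test_that("auc is invariant to strictly increasing transforms", {
  withr::with_seed(13, {
    p <- runif(500)
    y <- rbinom(500, 1, plogis(3 * p - 1.5))
    a <- auc(p, y)
    expect_equal(auc(qlogis(p / 1.0000001 + 1e-9), y), a)
    expect_equal(auc(p^3, y), a)
    expect_equal(auc(rank(p), y), a)
  })
})

test_that("precision and sensitivity follow their definitions and degenerate rules", {
  # TP=10, FP=20, FN=5
  labels <- c(rep(1, 30), rep(0, 5))
  outcomes <- c(rep(1, 10), rep(0, 20), rep(1, 5))
  ps <- precision_sensitivity(labels, outcomes)
  expect_equal(ps$precision, 1 / 3)
  expect_equal(ps$sensitivity, 2 / 3)

  expect_equal(precision_sensitivity(c(1, 0, 1), c(1, 0, 1)),
               tibble::tibble(precision = 1, sensitivity = 1,
                              tp = 2L, fp = 0L, fn = 0L))

  deg <- precision_sensitivity(c(0, 0, 0), c(1, 0, 1))
  expect_true(is.na(deg$precision))
  expect_equal(deg$sensitivity, 0)
})

test_that("models round-trip through JSON with identical scores", {
  prof <- test_profile(n = 400)
  off <- calibrate_offsets(prof, n_calib = 20000)
  co <- generate_cohort(prof, seed = 17, offsets = off)
  enc <- encode_race(co)
  m <- fit_logistic_l2(enc, c(cohort_features(co), race_variables()))
  m <- nullify_features(m, "race_unknown")
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  back <- read_model_json(path)
  expect_identical(predict_risk(back, enc), predict_risk(m, enc))
  expect_identical(back$nullified_features, m$nullified_features)
})

test_that("tidy and glance summarize a fitted model", {
  d <- toy_data(n = 200)
  m <- fit_logistic_l2(d, c("x1", "x2"), l2_strength = 2)
  td <- tidy(m)
  expect_identical(td$term, c("(Intercept)", "x1", "x2"))
  gl <- glance(m)
  expect_identical(gl$n_features, 2L)
  expect_identical(gl$l2_strength, 2)
  expect_true(gl$converged)
})
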