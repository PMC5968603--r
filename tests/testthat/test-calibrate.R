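test_that("identity calibration returns the design weights unchanged", {
  d <- tibble::tibble(g = c("a", "a", "b"), survey_weight = c(2, 3, 5))
  bm <- tibble::tibble(variable = "g", level = c("a", "b"), target = c(5, 5))
  cal <- calibrate_weights(d, bm, bounds = c(0, Inf))
  expect_equal(cal$weights, d$survey_weight)
  expect_lte(cal$iterations, 1L)
  expect_true(cal$converged)
})

test_that("a single doubled total constraint doubles every weight", {
  set.seed(2)
  d <- tibble::tibble(all = "x", survey_weight = stats::runif(40, 0.5, 3))
  tot <- sum(d$survey_weight)
  bm <- tibble::tibble(variable = "all", level = "x", target = 2 * tot)
  cal <- calibrate_weights(d, bm, bounds = c(0, Inf))
  # closed-form: chi-square calibration under one total constraint
  # scales all weights uniformly
  expect_equal(cal$weights, 2 * d$survey_weight, tolerance = 1e-10)
})

test_that("small unbounded instances match the explicit GREG linear solve", {
  # 3 records, 2 overlapping constraints: w = d(1 + X lambda),
  # lambda = (X'DX)^{-1} (T - X'd), solved directly
  d <- c(1, 2, 3)
  X <- cbind(total = c(1, 1, 1), grp_a = c(1, 1, 0))
  targets <- c(8, 4)
  lambda <- solve(t(X) %*% diag(d) %*% X, targets - as.numeric(t(X) %*% d))
  w_oracle <- d * (1 + as.numeric(X %*% lambda))

  df <- tibble::tibble(total = "x", grp = c("a", "a", "b"),
                       survey_weight = d)
  bm <- tibble::tibble(variable = c("total", "grp"), level = c("x", "a"),
                       target = targets)
  cal <- calibrate_weights(df, bm, bounds = c(0, Inf))
  expect_equal(cal$weights, w_oracle, tolerance = 1e-10)
  expect_equal(as.numeric(crossprod(
    plycost:::constraint_matrix(df, tibble::as_tibble(bm)), cal$weights)),
    targets, tolerance = 1e-10)

  # randomised small instances against the same closed form
  set.seed(5)
  for (i in 1:10) {
    n <- sample(4:10, 1)
    d <- stats::runif(n, 0.5, 2)
    g <- sample(c("a", "b"), n, replace = TRUE)
    X <- cbind(1, as.numeric(g == "a"))
    t_tot <- sum(d) * stats::runif(1, 0.8, 1.2)
    t_a <- sum(d[g == "a"]) * stats::runif(1, 0.8, 1.2)
    lambda <- solve(t(X) %*% (X * d), c(t_tot, t_a) - as.numeric(t(X) %*% d))
    w_oracle <- d * (1 + as.numeric(X %*% lambda))
    cal <- calibrate_weights(
      tibble::tibble(all = "x", g = g, survey_weight = d),
      tibble::tibble(variable = c("all", "g"), level = c("x", "a"),
                     target = c(t_tot, t_a)),
      bounds = c(0, Inf))
    expect_equal(cal$weights, w_oracle, tolerance = 1e-10)
  }
})

test_that("weight bounds are respected exactly and clamping re-solves", {
  # overlapping constraints chosen so the unbounded solution pushes one
  # weight past the upper bound; after clamping it, the free records
  # still satisfy both targets exactly (worked out by hand)
  df <- tibble::tibble(g = c("a", "a", "b"), h = c("u", "v", "v"),
                       survey_weight = c(1, 1, 1))
  bm <- tibble::tibble(variable = c("g", "h"), level = c("a", "v"),
                       target = c(2.9, 2.7))
  cal <- calibrate_weights(df, bm, bounds = c(0.5, 1.5), tol = 1e-6)
  expect_true(all(cal$weights >= 0.5 - 1e-12 & cal$weights <= 1.5 + 1e-12))
  expect_equal(cal$weights, c(1.4, 1.5, 1.2), tolerance = 1e-9)
  expect_equal(cal$bounded_count, 1L)
  expect_lte(cal$max_constraint_gap, 1e-6)
  expect_gt(cal$iterations, 1L)
})

test_that("infeasible targets raise an infeasibility error", {
  d <- tibble::tibble(g = "a", survey_weight = rep(1, 10))
  bm <- tibble::tibble(variable = "g", level = "a", target = 200)
  expect_error(calibrate_weights(d, bm, bounds = c(0.5, 2)), "infeasible")
  expect_error(calibrate_weights(d, bm[0, ]), "no benchmark constraints")
  expect_error(calibrate_weights(
    dplyr::mutate(d, survey_weight = 0), bm), "positive")
})

test_that("calibrated solution minimises the chi-square distance", {
  set.seed(9)
  d <- stats::runif(12, 0.5, 2)
  g <- rep(c("a", "b"), 6)
  df <- tibble::tibble(g = g, survey_weight = d)
  targets <- c(sum(d[g == "a"]) * 1.3, sum(d[g == "b"]) * 0.8)
  bm <- tibble::tibble(variable = "g", level = c("a", "b"), target = targets)
  cal <- calibrate_weights(df, bm, bounds = c(0, Inf))
  chisq <- function(w) sum((w - d)^2 / d)
  # any feasible perturbation within the constraint null space does
  # not lower the objective
  for (i in 1:50) {
    z <- stats::rnorm(12, 0, 0.05)
    # project the perturbation so constraints stay satisfied
    za <- z[g == "a"] - mean(z[g == "a"])
    zb <- z[g == "b"] - mean(z[g == "b"])
    w2 <- cal$weights
    w2[g == "a"] <- w2[g == "a"] + za
    w2[g == "b"] <- w2[g == "b"] + zb
    expect_gte(chisq(w2), chisq(cal$weights) - 1e-12)
  }
  # tidiers expose constraint-level diagnostics
  td <- tidy(cal)
  expect_true(all(td$rel_gap <= 1e-6))
  gl <- glance(cal)
  expect_true(gl$converged)
})

test_that("uprating is multiplicative, composable and identity at base year", {
  p <- tibble::tibble(weekly_earnings = 100, weekly_other_income = 20,
                      weekly_welfare = 311.67,
                      weekly_total_income = 431.67, weekly_tax = 15)
  r <- uprating_rule()
  expect_equal(uprate_profile(p, r, 2013), p)
  p15 <- uprate_profile(p, r, 2015)
  expect_equal(p15$weekly_earnings, 102.01)
  expect_equal(p15$weekly_welfare, 311.67) # no real growth in welfare
  expect_equal(p15$weekly_total_income,
               p15$weekly_earnings + p15$weekly_other_income + 311.67)

  # composition: 2013 -> 2020 -> 2030 equals 2013 -> 2030
  r20 <- uprating_rule(base_year = 2020L)
  expect_equal(uprate_profile(uprate_profile(p, r, 2020), r20, 2030),
               uprate_profile(p, r, 2030), tolerance = 1e-12)
  expect_error(uprate_profile(p, r, 2012), "precedes")
})
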