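test_that("kaplan_meier reproduces hand-computed product-limit values", {
  # all events at 1, 2, 3: S = 2/3, 1/3, 0
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$times, c(1, 2, 3))
  expect_equal(km$surv, c(2/3, 1/3, 0))

  # worked censored example: 2/3 at t=2; at t=6 the only subject at risk
  # fails, so the product-limit drops to 2/3 * (1 - 1/1) = 0 (the censored
  # subject left the risk set at 4)
  hx <- km_hand_example()
  km2 <- kaplan_meier(hx$time, hx$event)
  expect_equal(km2$times, c(2, 6))
  expect_equal(km2$surv, c(2/3, 0))
  sf <- survival::survfit(survival::Surv(hx$time, hx$event) ~ 1)
  expect_equal(km2$surv, sf$surv[sf$time %in% km2$times])

  # all censored: S identically 1
  km3 <- kaplan_meier(c(3, 5, 9), c(0, 0, 0))
  expect_true(all(km3$surv == 1))

  expect_error(kaplan_meier(numeric(0), numeric(0)), "empty")
  expect_error(kaplan_meier(c(1, 2), c(1, 1), weights = c(-1, 1)), "weights")
})

test_that("weighted kaplan_meier agrees with the survfit oracle", {
  set.seed(7)
  n <- 60
  tme <- round(rexp(n, 0.1), 1) + 0.1
  ev <- rbinom(n, 1, 0.7)
  w <- sample(1:4, n, replace = TRUE)
  km <- kaplan_meier(tme, ev, weights = w)
  sf <- survival::survfit(survival::Surv(tme, ev) ~ 1, weights = w)
  at_events <- sf$time %in% km$times
  expect_equal(km$surv, sf$surv[at_events], tolerance = 1e-10)
  # unit weights equal the unweighted estimator exactly
  expect_identical(kaplan_meier(tme, ev, weights = rep(1, n)),
                   kaplan_meier(tme, ev))
})

test_that("KM with no censoring equals one minus the empirical CDF", {
  set.seed(11)
  tme <- sample(1:40, 25, replace = TRUE)
  km <- kaplan_meier(tme, rep(1, 25))
  for (k in seq_along(km$times)) {
    expect_equal(km$surv[k], mean(tme > km$times[k]))
  }
})

test_that("log_rank_test matches survdiff and is calibrated under the null", {
  set.seed(3)
  n <- 50
  tme <- rexp(n, 0.1); ev <- rbinom(n, 1, 0.8); g <- rbinom(n, 1, 0.5)
  lr <- log_rank_test(g, tme, ev)
  sd_fit <- survival::survdiff(survival::Surv(tme, ev) ~ g)
  expect_equal(lr$statistic, sd_fit$chisq, tolerance = 1e-8)

  # identical outcome lists in both groups: statistic 0, p = 1
  lr0 <- log_rank_test(c(rep(0, 4), rep(1, 4)), rep(c(1, 2, 3, 4), 2),
                       rep(c(1, 1, 0, 1), 2))
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p_value, 1)

  expect_error(log_rank_test(rep(1, 5), 1:5, rep(1, 5)), "two non-empty groups")

  # permutation calibration: empirical type-I error at alpha = .05
  set.seed(21)
  n <- 40
  tme <- rexp(n, 0.1); ev <- rbinom(n, 1, 0.8); g <- rep(0:1, each = 20)
  rej <- mean(replicate(2000, {
    log_rank_test(sample(g), tme, ev)$p_value < 0.05
  }))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("fit_cox matches a brute-force partial-likelihood grid search", {
  x <- c(0, 0, 0, 1, 1, 1)
  tme <- c(4, 7, 10, 2, 5, 8)
  ev <- c(1, 1, 0, 1, 1, 1)
  fit <- fit_cox(matrix(x, ncol = 1), tme, ev)
  grid <- seq(-3, 3, by = 1e-4)
  pll <- vapply(grid, cox_pll_direct, numeric(1), x = x, time = tme, event = ev)
  beta_grid <- grid[which.max(pll)]
  expect_equal(unname(fit$beta[1]), beta_grid, tolerance = 1e-3)
  expect_equal(fit$loglik, max(pll), tolerance = 1e-6)
})

test_that("fit_cox flags non-identifiable columns and honors preconditions", {
  n <- 20
  set.seed(5)
  tme <- rexp(n); ev <- rep(1, n)
  X <- cbind(const = rep(1, n), x = rnorm(n))
  fit <- fit_cox(X, tme, ev)
  expect_true(fit$flagged["const"])
  expect_equal(unname(fit$beta["const"]), 0)
  expect_equal(unname(fit$se["const"]), Inf)
  expect_false(fit$flagged["x"])

  expect_error(fit_cox(matrix(rnorm(5)), rexp(5), rep(0, 5)), "no events")
})

test_that("fit_cox row replication leaves beta fixed and scales se by 1/sqrt(k)", {
  co <- make_simple_cohort(n = 80, seed = 9)
  X <- as.matrix(co$covariates)
  f1 <- fit_cox(X, co$time, co$event)
  idx <- rep(seq_len(80), 2)
  f2 <- fit_cox(X[idx, ], co$time[idx], co$event[idx])
  expect_equal(f2$beta, f1$beta, tolerance = 1e-8)
  expect_equal(f2$se, f1$se / sqrt(2), tolerance = 1e-6)
})

test_that("cox fit: Breslow baseline curve and PH prediction structure", {
  co <- make_simple_cohort(n = 120, seed = 13)
  X <- as.matrix(co$covariates)
  fit <- fit_cox(X, co$time, co$event)
  expect_true(all(diff(fit$baseline_hazard) >= 0))
  expect_gte(fit$baseline_hazard[1], 0)
  # intercept-only fit: predicted curve independent of x
  fit0 <- fit_cox(matrix(numeric(0), nrow = 120, ncol = 0), co$time, co$event)
  c1 <- predict_cox_curve(fit0, numeric(0))
  expect_s3_class(c1, "survival_curve")
  expect_equal(c1$surv, exp(-fit0$baseline_hazard))
})

test_that("fit_logistic recovers the closed-form 2x2 odds ratio", {
  a <- 20; b <- 12; c <- 9; d <- 25
  x <- c(rep(1, a + b), rep(0, c + d))
  y <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  fit <- fit_logistic(matrix(x, ncol = 1), y)
  expect_equal(unname(fit$or[2]), (a * d) / (b * c), tolerance = 1e-6)
  expect_true(fit$or_low[2] < fit$or[2] && fit$or[2] < fit$or_high[2])
})

test_that("fit_logistic null slopes and failure modes", {
  set.seed(31)
  n <- 5000
  X <- cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
  y <- rbinom(n, 1, 0.5)
  fit <- fit_logistic(X, y)
  z <- fit$beta[-1] / fit$se[-1]
  expect_true(all(abs(z) < 3))

  expect_error(fit_logistic(matrix(rnorm(10)), rep(1, 10)), "single class")
  # complete separation
  xs <- c(rep(0, 10), rep(1, 10))
  ys <- c(rep(0, 10), rep(1, 10))
  expect_error(fit_logistic(matrix(xs, ncol = 1), ys), "separation")
})

test_that("chi_square_2x2 reproduces the published contingency comparison", {
  # censored/dead by arm: RT 409/1680, CRT 4510/13844 -> p < 0.001
  tab <- rbind(c(1680, 409), c(13844, 4510))
  res <- chi_square_2x2(tab)
  expect_lt(res$p_value, 0.001)

  eq <- chi_square_2x2(rbind(c(10, 10), c(10, 10)))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)

  # equals the squared two-proportion z statistic
  t2 <- rbind(c(30, 70), c(45, 55))
  res2 <- chi_square_2x2(t2)
  p1 <- 30 / 100; p2 <- 45 / 100; pp <- 75 / 200
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / 100 + 1 / 100))
  expect_equal(res2$statistic, z^2, tolerance = 1e-10)

  expect_error(chi_square_2x2(rbind(c(0, 0), c(5, 5))), "margin")
})

test_that("rmst_from_curve integrates the step curve", {
  flat <- survival_curve(c(10), c(1))
  expect_equal(rmst_from_curve(flat, 8), 8)

  hx <- km_hand_example()
  km <- kaplan_meier(hx$time, hx$event)
  expect_equal(rmst_from_curve(km, 6), 2 * 1 + 4 * (2/3), tolerance = 1e-12)

  expect_equal(rmst_from_curve(km, 0), 0)
  expect_error(rmst_from_curve(km, -1), "negative")

  # non-decreasing in tau, never exceeds tau
  taus <- seq(0.5, 12, by = 0.5)
  vals <- vapply(taus, function(t) rmst_from_curve(km, t), numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_true(all(vals <= taus + 1e-12))
})
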