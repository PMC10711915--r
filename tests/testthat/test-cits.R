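make_design <- function(analysis_id = 3, cal = short_calendar(), ...) {
  build_design(interruption_spec(analysis_id, cal), ...)
}

# a weekly series carrying arbitrary values on the calendar grid
series_on <- function(cal, values, label = "synthetic") {
  weekly_series(
    week_start_date = cal$weeks$week_start_date, value = values,
    category = label, measure = "volume", week = cal$weeks$week
  )
}

test_that("design columns encode the segmented-regression structure element-wise", {
  cal <- short_calendar()
  X <- make_design(3, cal)
  tA <- cal$announcement_week
  tI <- cal$implementation_week
  expect_equal(X$ann_level, as.numeric(X$week >= tA))
  expect_equal(X$imp_level, as.numeric(X$week >= tI))
  # weeks-since columns: zero before the interruption, then increment by 1
  expect_true(all(X$imp_slope[X$week < tI] == 0))
  expect_equal(diff(X$imp_slope[X$week >= tI]), rep(1, sum(X$week >= tI) - 1))
  expect_equal(X$ann_slope, pmax(X$week - tA, 0))
  # christmas flags exactly the weeks starting in December or January
  months <- as.integer(format(cal$weeks$week_start_date, "%m"))
  expect_equal(X$christmas, as.numeric(months %in% c(12, 1)))
  # analysis 1 carries no implementation terms and a shorter window
  X1 <- make_design(1, cal)
  expect_false(any(c("imp_level", "imp_slope") %in% names(X1)))
  expect_equal(max(X1$week), min(cal$n_weeks, tA + 103))
  full <- study_calendar()
  expect_equal(
    max(build_design(interruption_spec(1, full))$week),
    full$announcement_week + 103
  )
})

test_that("rank-deficient designs are rejected", {
  cal <- short_calendar()
  const_control <- series_on(cal, rep(5, cal$n_weeks), "control")
  expect_error(make_design(3, cal, control_series = const_control), "rank deficient")
})

test_that("a noiseless series generated from known coefficients is recovered exactly", {
  cal <- short_calendar()
  X <- make_design(3, cal)
  beta <- c(
    intercept = 700, time = -0.8, ann_level = 25, ann_slope = 0.3,
    imp_level = -120, imp_slope = -0.7, sin1 = 35, cos1 = -10,
    sin2 = 4, cos2 = 2, christmas = 80
  )
  M <- as.matrix(X[names(beta)])
  y <- series_on(cal, drop(M %*% beta))
  fit <- fit_cits(y, X)
  expect_equal(fit$coefficients[names(beta)], beta, tolerance = 1e-7)
  # counterfactual equals fitted before the first interruption...
  cf <- project_counterfactual(fit)
  pre <- X$week < cal$announcement_week
  expect_equal(cf$value[pre], fit$fitted$value[pre], tolerance = 1e-7)
  # ...and differs from it by the injected effect afterwards
  post <- X$week >= cal$implementation_week
  gap <- fit$fitted$value[post] - cf$value[post]
  injected <- 25 + 0.3 * (X$week[post] - cal$announcement_week) -
    120 - 0.7 * (X$week[post] - cal$implementation_week)
  expect_equal(gap, injected, tolerance = 1e-7)
})

test_that("scaling the outcome scales estimates equivariantly", {
  cal <- short_calendar()
  set.seed(4)
  X <- make_design(3, cal)
  beta <- c(
    intercept = 700, time = -0.8, ann_level = 25, ann_slope = 0.3,
    imp_level = -120, imp_slope = -0.7, sin1 = 35, cos1 = -10,
    sin2 = 4, cos2 = 2, christmas = 80
  )
  y0 <- drop(as.matrix(X[names(beta)]) %*% beta) +
    as.numeric(stats::arima.sim(list(ar = 0.5), cal$n_weeks, sd = 20))
  k <- 3.7
  f1 <- fit_cits(series_on(cal, y0), X)
  fk <- fit_cits(series_on(cal, k * y0), X)
  expect_equal(k * f1$coefficients, fk$coefficients, tolerance = 1e-8)
  expect_equal(k * f1$fitted$value, fk$fitted$value, tolerance = 1e-8)
  expect_equal(
    k * project_counterfactual(f1)$value,
    project_counterfactual(fk)$value,
    tolerance = 1e-8
  )
  expect_equal(k * absolute_effect(f1)$estimate, absolute_effect(fk)$estimate,
    tolerance = 1e-8
  )
  expect_equal(relative_effect(f1)$estimate, relative_effect(fk)$estimate,
    tolerance = 1e-8
  )
})

test_that("a white-noise control covariate leaves intervention estimates nearly unchanged", {
  deltas <- function(n_weeks) {
    start <- as.Date("2014-02-26")
    cal <- study_calendar(
      start_date = start, n_weeks = n_weeks,
      announcement_date = start + 7 * floor(n_weeks * 0.4),
      implementation_date = start + 7 * floor(n_weeks * 0.7)
    )
    X <- make_design(3, cal)
    beta <- c(
      intercept = 700, time = -0.3, ann_level = 25, ann_slope = 0.1,
      imp_level = -120, imp_slope = -0.2, sin1 = 35, cos1 = -10,
      sin2 = 4, cos2 = 2, christmas = 40
    )
    signal <- drop(as.matrix(X[names(beta)]) %*% beta)
    replicate(10, {
      y <- series_on(cal, signal + stats::rnorm(cal$n_weeks, 0, 20))
      ctrl <- series_on(cal, stats::rnorm(cal$n_weeks, 120, 5), "control")
      f_ctrl <- fit_cits(y, build_design(interruption_spec(3, cal), control_series = ctrl))
      f_none <- fit_cits(y, make_design(3, cal))
      abs(f_ctrl$coefficients["imp_level"] - f_none$coefficients["imp_level"])
    })
  }
  set.seed(7)
  expect_lt(mean(deltas(1000)), mean(deltas(250)))
  expect_lt(mean(deltas(1000)), 3)
})

test_that("fit validation rejects gaps, short windows and degenerate inputs", {
  cal <- short_calendar()
  X <- make_design(3, cal)
  y <- series_on(cal, rep(100, cal$n_weeks))
  y$value[40] <- NA
  expect_error(fit_cits(y, X), "missing")
  # 18 winter weeks: the Christmas indicator varies, but 9 parameters
  # need at least 19 observations
  start <- as.Date("2014-11-05")
  tiny <- study_calendar(
    start_date = start, n_weeks = 18,
    announcement_date = start + 7 * 5, implementation_date = start + 7 * 10
  )
  expect_error(
    fit_cits(
      series_on(tiny, stats::rnorm(18, 100)),
      make_design(3, tiny, harmonics = 1)
    ),
    "shorter"
  )
})

test_that("the AR(1) error model gives coefficients close to OLS with honest intervals", {
  cal <- short_calendar()
  X <- make_design(3, cal)
  beta <- c(
    intercept = 700, time = -0.8, ann_level = 25, ann_slope = 0.3,
    imp_level = -120, imp_slope = -0.7, sin1 = 35, cos1 = -10,
    sin2 = 4, cos2 = 2, christmas = 80
  )
  set.seed(11)
  y <- series_on(cal, drop(as.matrix(X[names(beta)]) %*% beta) +
    as.numeric(stats::arima.sim(list(ar = 0.5), cal$n_weeks, sd = 15)))
  f_hac <- fit_cits(y, X, error_model = "hac")
  f_ar1 <- fit_cits(y, X, error_model = "ar1")
  expect_equal(f_ar1$coefficients["imp_level"], f_hac$coefficients["imp_level"],
    tolerance = 0.2
  )
  expect_equal(f_hac$error_model, "hac")
  expect_equal(f_ar1$error_model, "ar1")
  expect_true(is.na(f_ar1$hac_lag))
  expect_gt(tidy(f_ar1)$std.error[5], 0)
  g <- glance(f_hac)
  expect_equal(g$hac_lag, floor(4 * (cal$n_weeks / 100)^(2 / 9)))
  expect_gt(g$r.squared, 0.9)
})
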