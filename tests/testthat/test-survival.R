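test_that("default anchors are the three digitized tumbling fractions", {
  a <- default_anchors()
  expect_equal(a$time_s, c(60, 3600, 86400))
  expect_equal(a$fraction, c(0.50, 0.03, 0.005))
  expect_true(all(diff(a$time_s) > 0))
  expect_true(all(diff(a$fraction) <= 0))
})

test_that("interpolant is exact at anchors and log-log linear between them", {
  curve <- survival_curve()
  a <- default_anchors()
  expect_equal(surviving_fraction(curve, a$time_s), a$fraction)
  # geometric midpoint in time maps to the geometric mean of the fractions
  expect_equal(surviving_fraction(curve, sqrt(60 * 3600)),
               sqrt(0.50 * 0.03), tolerance = 1e-12)
  expect_equal(surviving_fraction(curve, sqrt(3600 * 86400)),
               sqrt(0.03 * 0.005), tolerance = 1e-12)
})

test_that("out-of-range evaluation errors unless extrapolation is enabled", {
  curve <- survival_curve()
  expect_error(surviving_fraction(curve, 30), class = "marsalt_out_of_range")
  expect_error(surviving_fraction(curve, 2e5), class = "marsalt_out_of_range")
  # extended end segments, capped at 1
  expect_lte(surviving_fraction(curve, 1, extrapolate = TRUE), 1)
  expect_lt(surviving_fraction(curve, 2e5, extrapolate = TRUE), 0.005)
  expect_error(surviving_fraction(curve, -5), class = "marsalt_invalid_time")
})

test_that("weibull curve evaluates exp(-(t/lambda)^k)", {
  curve <- survival_curve(model = "weibull", shape = 0.6, scale = 120)
  expect_equal(surviving_fraction(curve, 120), exp(-1))
  tt <- c(1, 50, 120, 1e4)
  expect_equal(surviving_fraction(curve, tt), exp(-(tt / 120)^0.6))
})

test_that("weibull fit recovers exact parameters and flags degeneracy", {
  tt <- exp(seq(log(5), log(5000), length.out = 10))
  s <- exp(-(tt / 120)^0.6)
  fit <- fit_weibull(tt, s)
  expect_equal(fit$shape, 0.6, tolerance = 0.01)
  expect_equal(fit$scale, 120, tolerance = 0.01)
  expect_error(fit_weibull(60, 0.5), class = "marsalt_fit_error")
  expect_error(fit_weibull(c(60, 60), c(0.5, 0.4)),
               class = "marsalt_fit_error")
  expect_warning(f2 <- fit_weibull(c(tt, 10), c(s, 1.2)), "dropping")
  expect_equal(f2$n_used, 10L)
})

test_that("the digitized anchors imply sub-exponential inactivation (k < 1)", {
  a <- default_anchors()
  fit <- fit_weibull(a$time_s, a$fraction)
  expect_lt(fit$shape, 1)
  expect_gt(fit$shape, 0)
  # successive halvings of the surviving population take ever longer
  curve <- survival_curve(model = "weibull", shape = fit$shape,
                          scale = fit$scale)
  t0 <- c(0, 60, 3600, 86400, 5 * 86400)
  expect_true(all(diff(halving_time(curve, t0)) > 0))
})

test_that("surviving fraction is non-increasing in time for random curves", {
  set.seed(4)
  for (i in 1:15) {
    times <- sort(exp(runif(5, 0, 12)))
    fracs <- rev(sort(runif(5, 0.001, 1)))
    curve <- survival_curve(tibble::tibble(time_s = times, fraction = fracs))
    grid <- seq(min(times), max(times), length.out = 60)
    expect_true(all(diff(surviving_fraction(curve, grid)) <= 1e-15))
    wcurve <- survival_curve(model = "weibull",
                             shape = runif(1, 0.1, 3),
                             scale = exp(runif(1, 0, 8)))
    expect_true(all(diff(surviving_fraction(wcurve, grid)) <= 1e-15))
  }
})

test_that("invalid anchor sets are rejected", {
  expect_error(survival_curve(tibble::tibble(time_s = c(60, 30),
                                             fraction = c(0.5, 0.4))),
               class = "marsalt_invalid_curve")
  expect_error(survival_curve(tibble::tibble(time_s = c(30, 60),
                                             fraction = c(0.4, 0.5))),
               class = "marsalt_invalid_curve")
  expect_error(survival_curve(tibble::tibble(time_s = 60, fraction = 0.5)),
               class = "marsalt_invalid_curve")
  expect_error(survival_curve(model = "weibull", shape = -1, scale = 10),
               class = "marsalt_invalid_curve")
})

test_that("anchors round-trip through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_anchors(default_anchors(), path)
  back <- read_anchors(path)
  expect_equal(back$time_s, default_anchors()$time_s)
  expect_equal(back$fraction, default_anchors()$fraction)
})
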