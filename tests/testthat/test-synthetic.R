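test_that("expected-value mode returns rounded expected counts", {
  cfg <- synthetic_experiment_config(
    true_curve = survival_curve(model = "weibull", shape = 0.6, scale = 120),
    initial_cfu = 1000, sampling_times = c(60, 120, 600),
    replicates = 2, noise = "none", seed = 1)
  ser <- generate_tumbling_series(cfg)
  at_lambda <- ser$cfu[ser$group == "tumbled" & ser$time_s == 120]
  expect_equal(unique(at_lambda), round(1000 * exp(-1)))  # 368
  expect_equal(unique(ser$cfu[ser$group == "control"]), 1000L)
})

test_that("generated tables are reproducible and well-formed", {
  cfg <- synthetic_experiment_config(seed = 5)
  a <- generate_tumbling_series(cfg)
  b <- generate_tumbling_series(cfg)
  expect_identical(a, b)
  expect_false(identical(
    a, generate_tumbling_series(synthetic_experiment_config(seed = 6))))
  expect_true(all(a$cfu >= 0))
  expect_true(is.integer(a$cfu))
  expect_setequal(unique(a$group), c("tumbled", "control"))
  expect_equal(nrow(a), 2 * 20 * 3)
  # expected counts non-increasing in time: check replicate means loosely
  em <- estimate_survival(a)
  expect_lt(em$fraction[nrow(em)], em$fraction[1])
})

test_that("empirical fractions converge to the true curve (LLN)", {
  truth <- survival_curve(model = "weibull", shape = 0.6, scale = 120)
  cfg <- synthetic_experiment_config(
    true_curve = truth, initial_cfu = 200,
    sampling_times = c(30, 120, 600), replicates = 1000, seed = 17)
  ser <- generate_tumbling_series(cfg)
  est <- estimate_survival(ser)
  s_true <- surviving_fraction(truth, est$time_s)
  # Poisson mean mu over m replicates: SE of fraction ~ sqrt(mu/m)/n0
  se <- sqrt(200 * s_true / 1000) / 200
  expect_true(all(abs(est$fraction - s_true) < 3 * se))
})

test_that("fitting the generated assay recovers the ground truth within 10%", {
  cfg <- synthetic_experiment_config()  # k=0.6, lambda=120, 200 CFU, 3 reps
  est <- estimate_survival(generate_tumbling_series(cfg))
  fit <- suppressWarnings(fit_weibull(est$time_s, est$fraction))
  expect_equal(fit$shape, 0.6, tolerance = 0.1)
  expect_equal(fit$scale, 120, tolerance = 0.1)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_experiment_config(initial_cfu = 0),
               class = "marsalt_invalid_config")
  expect_error(synthetic_experiment_config(sampling_times = c(10, 5)),
               class = "marsalt_invalid_config")
  expect_error(synthetic_experiment_config(replicates = 0),
               class = "marsalt_invalid_config")
  expect_error(generate_tumbling_series(list()),
               class = "marsalt_invalid_config")
})
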