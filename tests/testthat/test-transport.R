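test_that("tumbling duration maps to hop count at the rotation rate", {
  expect_identical(hops_from_duration(tumbling_protocol(1, 60)), 60L)
  expect_identical(hops_from_duration(tumbling_protocol(1, 86400)), 86400L)
  expect_identical(hops_from_duration(tumbling_protocol(5, 0)), 0L)
  expect_identical(hops_from_duration(tumbling_protocol(0.5, 61)), 31L)
  expect_error(tumbling_protocol(1, -10), class = "marsalt_invalid_protocol")
  expect_error(tumbling_protocol(0, 10), class = "marsalt_invalid_protocol")
})

test_that("deterministic end-member distances", {
  expect_identical(linear_distance(0, 29), 0)
  expect_identical(linear_distance(2, 5), 10)
  expect_identical(random_walk_distance(1, 17.3), 17.3)
  expect_identical(random_walk_distance(100, 2), 20)
  expect_error(linear_distance(-1, 5), class = "marsalt_invalid_scenario")
  expect_error(random_walk_distance(3, -5), class = "marsalt_invalid_scenario")
})

test_that("random-walk bound equals the linear bound over sqrt(n)", {
  set.seed(9)
  for (i in 1:25) {
    n <- sample(1:1e6, 1)
    L <- runif(1, 0.01, 100)
    expect_equal(random_walk_distance(n, L), linear_distance(n, L) / sqrt(n),
                 tolerance = 1e-12)
  }
  n <- c(1, 5, 60, 3600, 86400)
  expect_true(all(diff(vapply(n, linear_distance, numeric(1),
                              hop_length = 29)) > 0))
  expect_true(all(diff(vapply(n, random_walk_distance, numeric(1),
                              hop_length = 29)) > 0))
})

test_that("prevailing-wind walkers all land exactly n * L downwind", {
  w <- simulate_walk(60, 29, mode = "prevailing_wind", n_walkers = 50,
                     seed = 123)
  expect_identical(w$mean, 1740)
  expect_identical(w$rms, 1740)
  expect_identical(w$max, 1740)
})

test_that("isotropic walk RMS and mean match the fixed-step closed forms", {
  w <- simulate_walk(100, 1, mode = "isotropic", n_walkers = 1e4, seed = 2)
  # RMS -> sqrt(n) * L
  expect_lt(abs(w$rms - 10), 3 * w$rms_se)
  # mean -> sqrt(pi)/2 * sqrt(n) * L (Rayleigh limit); 0.15 ~ 3 SE of the mean
  expect_lt(abs(w$mean - sqrt(pi) / 2 * 10), 0.15)
  expect_lte(w$max, 100)  # can never beat the linear bound
})

test_that("simulations are seed-reproducible and leave the RNG untouched", {
  a <- simulate_walk(50, 2, n_walkers = 500, seed = 7)
  b <- simulate_walk(50, 2, n_walkers = 500, seed = 7)
  expect_identical(a, b)
  c2 <- simulate_walk(50, 2, n_walkers = 500, seed = 8)
  expect_false(identical(a$rms, c2$rms))
  expect_equal(c2$rms / sqrt(50) / 2, 1, tolerance = 0.1)
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(simulate_walk(10, 1, n_walkers = 10, seed = 1))
  expect_identical(runif(1), before)
  expect_error(simulate_walk(10, 1, n_walkers = 0),
               class = "marsalt_invalid_simulation")
})

test_that("transport_result couples hop physics with survival", {
  res <- transport_result(particle = particle_class(1e-3), n_hops = 3600,
                          curve = survival_curve())
  expect_equal(res$linear_distance_m, 3600 * res$hop_length_m)
  expect_equal(res$random_walk_distance_m, 60 * res$hop_length_m)
  expect_equal(res$surviving_fraction, 0.03)
  res0 <- transport_result(particle = particle_class(1e-3), n_hops = 0)
  expect_identical(res0$linear_distance_m, 0)
  expect_true(is.na(res0$surviving_fraction))
})
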