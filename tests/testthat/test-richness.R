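test_that("productivity curve pairs d_t with the prior cumulative total", {
  ser <- series_from_counts(c(5, 3, 2))
  pts <- productivity_curve(ser)
  expect_equal(pts$c_prev, c(5, 8))
  expect_equal(pts$d, c(3, 2))

  zero <- series_from_counts(rep(0, 5))
  ptz <- productivity_curve(zero)
  expect_true(all(ptz$c_prev == 0) && all(ptz$d == 0))

  # conservation: last x equals total minus the final year's count
  h <- simulate_description_history(500, 1900, 15, seed = 2)
  pth <- productivity_curve(h$series)
  expect_equal(pth$c_prev[nrow(pth)],
               sum(h$series$count) - h$series$count[nrow(h$series)])

  expect_error(productivity_curve(series_from_counts(4)), "2 years")
})

test_that("the declining-phase detector finds the productivity apex", {
  # tent: rises for 15 years then falls for 15
  tent <- series_from_counts(c(seq(2, 30, by = 2), seq(28, 0, by = -2)))
  pts <- productivity_curve(tent)
  idx <- detect_negative_slope_start(pts)
  apex <- which.max(pts$d)
  expect_lte(abs(idx - apex), 1L)

  declining <- series_from_counts(seq(40, 2, by = -2))
  expect_equal(
    detect_negative_slope_start(productivity_curve(declining)), 1L)

  rising <- series_from_counts(seq(2, 40, by = 2))
  expect_error(
    detect_negative_slope_start(productivity_curve(rising)),
    "no declining phase")
})

test_that("x-intercept estimator is exact on a noiseless linear decline", {
  # construct counts so that every point lies on d = 100 - 0.01 C
  d <- numeric(40)
  C <- 0
  for (t in seq_along(d)) {
    d[t] <- 100 - 0.01 * C
    C <- C + d[t]
  }
  ser <- series_from_counts(d)
  est <- estimate_richness_productivity(ser, n_boot = 200, seed = 7)
  expect_equal(est$estimate, 10000, tolerance = 1e-8)
  expect_equal(est$upper - est$lower, 0, tolerance = 1e-6)
  expect_false(est$below_observed)
})

test_that("x-intercept estimator recovers a logistic history within 10%", {
  h <- simulate_description_history(15000, 1900, 20,
                                    years = c(1758, 2007), seed = 3)
  est <- estimate_richness_productivity(h$series, n_boot = 500, seed = 2)
  expect_lt(abs(est$estimate - 15000) / 15000, 0.10)
  expect_true(est$lower <= est$estimate && est$estimate <= est$upper)

  # bootstrap interval width shrinks (stochastically) with record length
  short <- simulate_description_history(15000, 1900, 20,
                                        years = c(1880, 1957), seed = 3)
  est_s <- estimate_richness_productivity(short$series, n_boot = 500,
                                          seed = 2)
  expect_lt(est$upper - est$lower, est_s$upper - est_s$lower)

  expect_error(
    estimate_richness_productivity(h$series, start_year = 2500),
    "after the end")
})

test_that("NHPP fit recovers truth and flags pre-asymptote records", {
  h <- simulate_description_history(5000, 1900, 20, seed = 11)
  post <- fit_nhpp_bayes(h$series, seed = 5)
  q <- stats::quantile(post$draws$n, c(0.025, 0.975))
  expect_true(q[1] <= 5000 && 5000 <= q[2])
  expect_false(post$no_finite_estimate)
  expect_true(all(post$rhat < 1.1))
  expect_true(all(post$draws$n >= post$n_bounds[1] &
                    post$draws$n <= post$n_bounds[2]))

  # still-accelerating record: no finite estimate
  pre <- simulate_description_history(5000, 2100, 30,
                                      years = c(1758, 2007), seed = 12)
  post_pre <- fit_nhpp_bayes(pre$series, seed = 5)
  expect_true(post_pre$no_finite_estimate)

  degenerate <- series_from_counts(5)
  expect_error(fit_nhpp_bayes(degenerate), "degenerate")
})

test_that("NHPP fits are reproducible given the seed", {
  h <- simulate_description_history(2000, 1920, 25, seed = 8)
  p1 <- fit_nhpp_bayes(h$series, nhpp_config(iter = 500, burn_in = 500),
                       seed = 99)
  p2 <- fit_nhpp_bayes(h$series, nhpp_config(iter = 500, burn_in = 500),
                       seed = 99)
  expect_equal(p1$draws, p2$draws)
})

test_that("forecasts match the analytic Poisson oracle and are monotone", {
  # degenerate posterior tuned to a constant rate of 10 descriptions/yr:
  # N * f(m) = 4e7 / (4e6) = 10 across the forecast window
  flat <- structure(
    list(draws = tibble::tibble(n = rep(4e7, 4000), midpoint = 2027,
                                scale = 1e6, chain = 1L),
         rhat = c(n = 1, midpoint = 1, scale = 1),
         no_finite_estimate = FALSE, n_bounds = c(1, 1e9),
         last_year = 2007L, observed = 100L),
    class = "nhpp_posterior")
  fc <- forecast_descriptions(flat, 2047, seed = 21)
  expect_lt(abs(fc$estimate - stats::qpois(0.5, 400)), 3)
  expect_lt(abs(fc$lower - stats::qpois(0.025, 400)), 5)
  expect_lt(abs(fc$upper - stats::qpois(0.975, 400)), 5)

  # per-draw monotonicity across horizons on a real posterior
  h <- simulate_description_history(2000, 1920, 25, seed = 8)
  post <- fit_nhpp_bayes(h$series, nhpp_config(iter = 500, burn_in = 500),
                         seed = 3)
  fcs <- forecast_descriptions(post, c(2050, 2100), seed = 4)
  expect_lte(fcs[[1]]$estimate, fcs[[2]]$estimate)
  expect_lte(fcs[[1]]$upper, fcs[[2]]$upper)

  expect_error(forecast_descriptions(post, 2007), "after the last")
})

test_that("reference-fauna ratio extrapolation is exact arithmetic", {
  avian <- extrapolate_from_reference(1107, 100, 1235)
  expect_equal(avian$estimate, 13671.45)
  expect_equal(avian$ratio_2dp, 11.07)

  mammal <- extrapolate_from_reference(1247, 100, 1235)
  expect_equal(mammal$estimate, 15400.45)

  expect_equal(extrapolate_from_reference(50, 50, 777)$estimate, 777)
  expect_error(extrapolate_from_reference(0, 10, 10), "positive")
})
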