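lags_std <- 10^seq(-0.3, 3.3, 0.05)

test_that("noiseless model curves are recovered exactly (100 random draws)", {
  set.seed(30)
  worst <- 0
  for (i in 1:100) {
    N <- runif(1, 0.2, 20)
    tau <- runif(1, 1, 500)
    off <- runif(1, -0.02, 0.02)
    f <- fit_fcs(synth_fcs_curve(N, tau, off, lags = lags_std))
    expect_true(f$success)
    worst <- max(worst, abs(f$N / N - 1), abs(f$tau_D / tau - 1))
  }
  expect_lt(worst, 1e-6)
})

test_that("synthetic curve values match the closed form", {
  crv <- synth_fcs_curve(N = 1, tau_D = 1, offset = 0, lags = c(1e-9, 1, 3))
  expect_equal(crv$G[1], 1, tolerance = 1e-8)   # tau -> 0 limit: 1/N
  expect_equal(crv$G[2], 0.5)                   # half amplitude at tau_D
  expect_equal(crv$G[3], 0.25)                  # direct substitution
  crv2 <- synth_fcs_curve(N = 2, tau_D = 50, offset = 0.1,
                          lags = c(1e-9, 50))
  expect_equal(crv2$G, c(0.6, 0.35), tolerance = 1e-8)
})

test_that("noisy transit times are recovered in the median", {
  set.seed(31)
  taus <- replicate(30, {
    crv <- synth_fcs_curve(2, 50, 0, lags = lags_std, noise_sd = 0.01)
    fit_fcs(crv)$tau_D
  })
  expect_equal(median(taus), 50, tolerance = 0.05)
})

test_that("fit range is enforced", {
  crv <- synth_fcs_curve(2, 50, 0, lags = c(1, 2, 5, 10, 20, 50, 100))
  expect_error(fit_fcs(crv, fit_range = c(1000, 4000)), "No lags")
  expect_error(fit_fcs(crv, fit_range = c(0.5, 4000)), "at least 8")
})

test_that("log-normal transit-time summary behaves and recovers parameters", {
  # identical samples: degenerate log-normal
  s0 <- transit_time_stats(rep(50, 10))
  expect_equal(s0$median_tau, 50)
  expect_equal(s0$lognorm_sigma, 0)
  expect_true(s0$agreement)
  # parameter recovery at n = 1000
  set.seed(32)
  x <- rlnorm(1000, meanlog = log(50), sdlog = 0.3)
  st <- transit_time_stats(x)
  expect_equal(st$median_tau, 50, tolerance = 0.05)
  expect_true(st$agreement)
  expect_equal(st$lognorm_sigma, 0.3, tolerance = 0.15)
  # scale equivariance
  st2 <- transit_time_stats(2 * x)
  expect_equal(st2$median_tau, 2 * st$median_tau, tolerance = 1e-8)
  # order and duplication invariance
  expect_equal(transit_time_stats(rev(x))$median_tau, st$median_tau)
  # duplication changes only the histogram binning of the density form
  expect_equal(transit_time_stats(c(x, x))$median_tau, st$median_tau,
               tolerance = 1e-3)
  # guards
  expect_error(transit_time_stats(c(1, 2, -3, 4, 5)), "positive")
  expect_error(transit_time_stats(c(1, 2)), "at least 5")
})

test_that("spot-geometry conversion follows d^2/(8 ln2 tau)", {
  expect_equal(transit_to_D_spot(11.27, 250), 1.0, tolerance = 1e-3)
  expect_equal(transit_to_D_spot(11.27 / 6.25, 100), 1.0, tolerance = 1e-3)
  expect_equal(transit_to_D_spot(20, 250), 2 * transit_to_D_spot(40, 250))
  expect_error(transit_to_D_spot(-1, 250))
})

test_that("calibrated conversion reproduces the measured pairs", {
  expect_equal(transit_to_D_calibrated(50, 50, 0.14), 0.14)
  expect_equal(round(transit_to_D_calibrated(35, 50, 0.14), 2), 0.20)
  D33 <- transit_to_D_calibrated(33, 50, 0.14)
  expect_gt(D33, 0.20)
  expect_lt(D33, 0.24)
})

test_that("calibrated and spot-geometry conversions agree for a consistent pair", {
  d <- 250
  tau_ref <- 20
  D_ref <- transit_to_D_spot(tau_ref, d)
  taus <- c(5, 20, 80)
  expect_equal(transit_to_D_calibrated(taus, tau_ref, D_ref),
               transit_to_D_spot(taus, d), tolerance = 1e-12)
})

test_that("fit_fcs_many fits one row per curve group", {
  curves <- dplyr::bind_rows(
    dplyr::mutate(synth_fcs_curve(2, 50, 0, lags_std), id = "a"),
    dplyr::mutate(synth_fcs_curve(5, 10, 0, lags_std), id = "b"))
  fits <- fit_fcs_many(curves)
  expect_equal(nrow(fits), 2)
  expect_equal(sort(fits$tau_D), c(10, 50), tolerance = 1e-6)
})
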