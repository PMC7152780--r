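frap_protocol_times <- c(-2, -1, 0:100)  # 2 prebleach frames, 1 frame/s

test_that("preprocessing normalizes to the prebleach level", {
  raw <- tibble::tibble(
    time = frap_protocol_times,
    roi = c(200, 200, 20 + 1:101),
    background = 10)
  tr <- preprocess_frap(raw, n_prebleach = 2)
  expect_equal(mean(tr$value[tr$phase == "prebleach"]), 1)
  expect_equal(tr$time[tr$phase == "recovery"][1], 0)
  # pure rescaling when background is zero and control absent
  raw2 <- tibble::tibble(time = frap_protocol_times,
                         roi = c(4, 4, rep(2, 101)), background = 0)
  tr2 <- preprocess_frap(raw2)
  expect_equal(tr2$value, c(1, 1, rep(0.5, 101)))
})

test_that("a no-bleach control divides out acquisition decay", {
  decay <- exp(-seq_along(frap_protocol_times) / 80)
  truth <- c(1, 1, 0.2 + 0.6 * (1 - exp(-(0:100) / 10)))
  raw <- tibble::tibble(
    time = frap_protocol_times,
    roi = 100 * truth * decay + 7,
    background = 7,
    control = 100 * decay + 7)
  tr <- preprocess_frap(raw)
  expect_equal(tr$value, truth, tolerance = 1e-10)
  # without the control the recovered tail is visibly distorted
  tr_no <- preprocess_frap(raw[, c("time", "roi", "background")])
  tail_slope <- coef(lm(value ~ time, data = tr_no[tr_no$time > 50, ]))[[2]]
  expect_lt(tail_slope, -1e-3)
})

test_that("degenerate FRAP inputs raise errors", {
  raw <- tibble::tibble(time = frap_protocol_times, roi = 5, background = 5)
  expect_error(preprocess_frap(raw), "non-positive")
  expect_error(preprocess_frap(tibble::tibble(time = 1:2, roi = 1:2,
                                              background = 0)),
               "beyond the prebleach")
})

test_that("noiseless double-exponential recovery is exact", {
  crv <- synth_frap_curve(0.5, 0.5, 2, 17.5, times = 0:100)
  f <- fit_frap(crv)
  expect_true(f$success)
  expect_equal(c(f$A1, f$A2, f$tau1, f$tau2), c(0.5, 0.5, 2, 17.5),
               tolerance = 1e-6)
  expect_equal(f$mobile_fraction, 1, tolerance = 1e-6)
  # closed-form value at one fast time constant after the bleach
  expect_equal(crv$value[crv$time == 2],
               0.5 * (1 - exp(-1)) + 0.5 * (1 - exp(-2 / 17.5)))
  # components are relabeled so tau1 < tau2
  expect_lt(f$tau1, f$tau2)
})

test_that("a single-component truth yields a vanishing second amplitude", {
  crv <- synth_frap_curve(0.8, 1e-9, 3, 30, times = 0:100)
  f <- fit_frap(crv)
  small <- min(f$A1, f$A2)
  big <- max(f$A1, f$A2)
  expect_lt(small, 0.01 * big)
  expect_equal(big, 0.8, tolerance = 1e-3)
})

test_that("the fit is invariant to time shifts when t0 is floated", {
  crv <- synth_frap_curve(0.5, 0.5, 2, 17.5, t0 = 0, times = seq(0, 100, 1))
  f0 <- fit_frap(crv, float_t0 = TRUE)
  shifted <- tibble::tibble(time = crv$time + 7,
                            value = crv$value)
  f7 <- fit_frap(shifted, float_t0 = TRUE)
  expect_equal(f7$t0 - f0$t0, 7, tolerance = 1e-8)
  expect_equal(c(f7$A1, f7$A2, f7$tau1, f7$tau2),
               c(f0$A1, f0$A2, f0$tau1, f0$tau2), tolerance = 1e-8)
})

test_that("mobile fraction stays bounded for normalized noisy curves", {
  set.seed(40)
  for (i in 1:10) {
    crv <- synth_frap_curve(0.52, 0.48, 2.5, 17.5, times = 0:100,
                            noise_sd = 0.02)
    f <- fit_frap(crv)
    expect_lte(f$mobile_fraction, 1 + 3 * 0.02)
  }
})

test_that("fraction recovery degrades gracefully at 5% noise", {
  set.seed(41)
  ff <- replicate(15, {
    crv <- synth_frap_curve(0.52, 0.48, 2.5, 17.5, times = 0:100,
                            noise_sd = 0.05)
    fit_frap(crv)$fast_fraction
  })
  expect_lt(abs(mean(ff, na.rm = TRUE) - 0.52), 0.05)
})

test_that("recovery-time to D conversion follows r^2/(4 tau)", {
  expect_equal(frap_tau_to_D(2, roi_radius = 1), 0.125)
  expect_equal(frap_tau_to_D(12.5, roi_radius = 1), 0.02)
  expect_equal(frap_tau_to_D(2, roi_radius = 2), 4 * frap_tau_to_D(2, 1))
})
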