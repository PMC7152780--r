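test_that("bleach correction preserves the mean of a stationary trace", {
  set.seed(20)
  tr <- tibble::tibble(time_ms = seq_len(20000), intensity = 100 + rnorm(20000))
  out <- bleach_correct(tr, crop_s = 5, window_s = 16)
  expect_equal(max(out$time_ms) - min(out$time_ms), 15000 - 1)
  kept <- tr$intensity[tr$time_ms >= 5000]
  expect_equal(mean(out$intensity), mean(kept), tolerance = 1e-3)
})

test_that("bleach correction flattens an exponential decay", {
  set.seed(21)
  t_ms <- seq(0, 60000, by = 10)
  v <- 100 * 2^(-t_ms / 30000) * (1 + rnorm(length(t_ms), sd = 0.01))
  out <- bleach_correct(tibble::tibble(time_ms = t_ms, intensity = v),
                        crop_s = 5, window_s = 16)
  sl <- coef(lm(intensity ~ time_ms, data = out))[[2]]
  duration <- max(out$time_ms) - min(out$time_ms)
  expect_lt(abs(sl) * duration, 0.01 * mean(out$intensity))
})

test_that("cropping more than the trace raises an error", {
  tr <- tibble::tibble(time_ms = 1:1000, intensity = 1)
  expect_error(bleach_correct(tr, crop_s = 5, window_s = 1), "shorter")
})

test_that("direct correlator handles constant, noise and periodic traces", {
  # constant trace: zero correlation at all lags
  tr <- tibble::tibble(time_ms = 1:2000, intensity = 5)
  d <- autocorrelate(tr, max_lag_ms = 50, method = "direct")
  expect_true(all(d$G == 0))
  # white noise: |G| bounded by the sampling error
  set.seed(22)
  n <- 20000
  trn <- tibble::tibble(time_ms = seq_len(n), intensity = 10 + rnorm(n))
  dn <- autocorrelate(trn, max_lag_ms = 50, method = "direct")
  expect_true(all(abs(dn$G) < 3 / sqrt(n) / 100))  # G normalized by mean^2 = 100
  # sinusoid of period P: correlation maxima at lags k*P
  P <- 50
  trs <- tibble::tibble(time_ms = seq_len(4000),
                        intensity = 10 + sin(2 * pi * seq_len(4000) / P))
  ds <- autocorrelate(trs, max_lag_ms = 160, method = "direct")
  expect_equal(ds$lag_ms[which.max(ds$G[ds$lag_ms > 25 & ds$lag_ms < 75])] + 25,
               P, tolerance = 0.05)
  loc <- ds$G[ds$lag_ms %in% c(P, 2 * P)]
  expect_true(all(loc > ds$G[ds$lag_ms %in% c(P / 2, 3 * P / 2)]))
})

test_that("correlation is invariant to time reversal", {
  tr <- free_trace(seed = 23, duration = 0.5)
  rev_tr <- tibble::tibble(time_ms = tr$time_ms,
                           intensity = rev(tr$intensity))
  g1 <- autocorrelate(tr, max_lag_ms = 20, method = "direct")
  g2 <- autocorrelate(rev_tr, max_lag_ms = 20, method = "direct")
  expect_lt(max(abs(g1$G - g2$G)), 1e-10)
})

test_that("multi-tau agrees with the direct estimator on shared lags", {
  tr <- free_trace(seed = 3, duration = 1)
  d <- autocorrelate(tr, max_lag_ms = 25, method = "direct")
  m <- autocorrelate(tr, max_lag_ms = 100, method = "multitau")
  shared <- dplyr::inner_join(d, m, by = "lag_ms", suffix = c("_d", "_m"))
  shared <- shared[shared$lag_ms <= 100 / 4, ]
  expect_gt(nrow(shared), 50)
  expect_lt(max(abs(shared$G_m / shared$G_d - 1)), 0.01)
  # constant trace through the multi-tau path
  trc <- tibble::tibble(time_ms = 1:4000, intensity = 2)
  expect_true(all(autocorrelate(trc, max_lag_ms = 100)$G == 0))
})

test_that("fitted transit times agree across both correlators", {
  tr <- free_trace(seed = 24, duration = 2, n_mol = 30, sampling = 0.05)
  d <- autocorrelate(tr, max_lag_ms = 80, method = "direct")
  m <- autocorrelate(tr, max_lag_ms = 80, method = "multitau")
  # fit both estimators on their shared (log-spaced) lag grid so the two
  # fits weight the decay identically
  fd <- fit_fcs(d[match(m$lag_ms, d$lag_ms), ], fit_range = c(0.1, 80))
  fm <- fit_fcs(m, fit_range = c(0.1, 80))
  expect_equal(fm$tau_D, fd$tau_D, tolerance = 0.03)
})

test_that("degenerate correlator inputs raise errors", {
  tr0 <- tibble::tibble(time_ms = 1:1000, intensity = 0)
  expect_error(autocorrelate(tr0, max_lag_ms = 50), "mean is zero")
  tr <- tibble::tibble(time_ms = 1:100, intensity = rnorm(100) + 5)
  expect_error(autocorrelate(tr, max_lag_ms = 60), "half the trace")
})

test_that("sFCS carpet correlates each pixel independently", {
  set.seed(25)
  base <- 50 + rnorm(4000)
  carpet <- dplyr::bind_rows(lapply(1:3, function(p) {
    tibble::tibble(pixel = p, time_ms = seq_len(4000) * 0.47273,
                   intensity = base)
  }))
  out <- sfcs_carpet(carpet, crop_s = 0.2, window_s = 0.5, max_lag_ms = 40)
  g1 <- out[out$pixel == 1, c("lag_ms", "G")]
  g2 <- out[out$pixel == 2, c("lag_ms", "G")]
  expect_equal(g1, g2)
  # single-pixel carpet reduces to bleach-corrected autocorrelation
  single <- carpet[carpet$pixel == 1, ]
  solo <- sfcs_carpet(single, crop_s = 0.2, window_s = 0.5, max_lag_ms = 40)
  ref <- autocorrelate(
    bleach_correct(single[, c("time_ms", "intensity")], 0.2, 0.5),
    max_lag_ms = 40)
  expect_equal(solo$G, ref$G)
})

test_that("ragged carpets are rejected", {
  carpet <- dplyr::bind_rows(
    tibble::tibble(pixel = 1, time_ms = 1:100, intensity = 1),
    tibble::tibble(pixel = 2, time_ms = 1:90, intensity = 1))
  expect_error(sfcs_carpet(carpet), "Ragged")
})

test_that("carpet from simulated free diffusion recovers the transit time", {
  # per-pixel estimates from one trajectory are strongly correlated, so
  # pool the pixels of three independent line-scan repetitions
  taus <- unlist(lapply(1:3, function(r) {
    cfg <- sim_config("test", n_molecules = 30, duration = 6, dt = 0.005,
                      sampling_interval = 0.47273 / 2,
                      p_trap = 0, p_hop = 1, rng_seed = 25 + r)
    traj <- simulate_trajectories(
      cfg, record_stride = round(0.47273 / cfg$dt), record_unwrapped = FALSE)
    px_x <- seq(-1050, 1050, by = 300)
    carpet <- dplyr::bind_rows(lapply(seq_along(px_x), function(i) {
      tr <- generate_intensity_trace(traj, fwhm = 250,
                                     center = c(px_x[i], 0))
      tibble::tibble(pixel = i, time_ms = tr$time_ms,
                     intensity = tr$intensity)
    }))
    curves <- sfcs_carpet(carpet, crop_s = 0.25, window_s = 4,
                          max_lag_ms = 400)
    fits <- curves |>
      dplyr::group_by(pixel) |>
      dplyr::group_modify(function(df, key) {
        glance(fit_fcs(df, c(0.5, 200)))
      }) |>
      dplyr::ungroup()
    fits$tau_D
  }))
  tau_true <- 250^2 / (8 * log(2) * 400)  # Eq. 3 inversion at D = 0.4
  expect_equal(median(taus), tau_true, tolerance = 0.1)
})
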