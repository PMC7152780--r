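#' Fit the one-component 2-D diffusion FCS model to a correlation curve
#'
#' Fits `G(tau) = (1/N) / (1 + tau/tau_D) + offset` by (optionally
#' weighted) nonlinear least squares. `N` (mean occupancy, amplitude `1/N`)
#' and `tau_D` (transit time) are bounded positive; the offset is free.
#' Starting values: `tau_D` at the half-amplitude lag, `N` from the first
#' in-range lag, offset from the curve tail.
#'
#' @param curve data frame with `lag_ms`, `G` (e.g. from [autocorrelate()]
#'   or [synth_fcs_curve()]).
#' @param fit_range lag range used for fitting, ms (default `c(0.5, 4000)`).
#' @param weights optional per-lag weights (same length as the in-range
#'   curve); uniform when `NULL`.
#' @param refine two-pass fitting: after a first fit, refit over a window
#'   scaled to the fitted decay (`tau_D/30` to `30 tau_D`, clamped to the
#'   requested range and the available lags). Balances the weight of the
#'   amplitude plateau and the noise tail across very different transit
#'   times, e.g. when the same nominal range is applied to 50- and 250-nm
#'   spots.
#' @return an object of class `fcs_fit` with elements `N`, `tau_D` (ms),
#'   `offset`, `fit_range`, `residual_norm`, `success`, `n_points`.
#' @examples
#' crv <- synth_fcs_curve(N = 2, tau_D = 50, lags = 10^seq(-0.3, 3.2, 0.05))
#' fit <- fit_fcs(crv)
#' c(fit$N, fit$tau_D)
#' @export
fit_fcs <- function(curve, fit_range = c(0.5, 4000), weights = NULL,
                    refine = FALSE) {
  stopifnot(all(c("lag_ms", "G") %in% names(curve)),
            length(fit_range) == 2, fit_range[1] < fit_range[2])
  keep <- curve$lag_ms >= fit_range[1] & curve$lag_ms <= fit_range[2] &
    is.finite(curve$G)
  lag <- curve$lag_ms[keep]
  G <- curve$G[keep]
  if (length(lag) == 0) abort("No lags inside the fit range.")
  if (length(lag) < 8) abort("Need at least 8 lag points inside the fit range.")
  off0 <- mean(G[lag >= stats::quantile(lag, 0.9)])
  amp0 <- G[1] - off0
  if (!is.finite(amp0) || amp0 <= 0) amp0 <- max(G) - min(G) + 1e-12
  half <- off0 + amp0 / 2
  tau0 <- lag[which.min(abs(G - half))]
  if (tau0 <= 0) tau0 <- stats::median(lag)
  w <- weights %||% rep(1, length(lag))
  stopifnot(length(w) == length(lag))
  sw <- sqrt(w)
  resid_fn <- function(p) {
    sw * (G - fcs_model_2d(lag, p[["N"]], p[["tau_D"]], p[["offset"]]))
  }
  lower <- c(N = 1e-12, tau_D = 1e-12, offset = -Inf)
  starts <- lapply(c(1, 1 / 3, 3), function(f) {
    c(N = 1 / amp0, tau_D = f * tau0, offset = off0)
  })
  best <- NULL
  msgs <- character(0)
  for (s in starts) {
    r <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fn, lower = lower,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) e)
    if (inherits(r, "error")) { msgs <- c(msgs, conditionMessage(r)); next }
    if (!r$info %in% 1:4) { msgs <- c(msgs, r$message); next }
    if (is.null(best) || r$deviance < best$deviance) best <- r
  }
  if (is.null(best)) {
    out <- list(N = NA_real_, tau_D = NA_real_, offset = NA_real_,
                fit_range = fit_range, residual_norm = NA_real_,
                success = FALSE, n_points = length(lag),
                message = paste(unique(msgs), collapse = "; "))
  } else {
    cf <- best$par
    out <- list(N = cf[["N"]], tau_D = cf[["tau_D"]],
                offset = cf[["offset"]], fit_range = fit_range,
                residual_norm = sqrt(best$deviance),
                success = TRUE, n_points = length(lag), message = NULL)
  }
  class(out) <- "fcs_fit"
  if (refine && out$success) {
    rng <- c(max(fit_range[1], out$tau_D / 30),
             min(fit_range[2], 30 * out$tau_D))
    if (sum(curve$lag_ms >= rng[1] & curve$lag_ms <= rng[2]) >= 8) {
      out2 <- tryCatch(fit_fcs(curve, fit_range = rng, weights = NULL,
                               refine = FALSE),
                       error = function(e) NULL)
      if (!is.null(out2) && out2$success) out <- out2
    }
  }
  out
}

#' @export
print.fcs_fit <- function(x, ...) {
  if (x$success) {
    cat(sprintf("<fcs_fit> N = %.4g, tau_D = %.4g ms, offset = %.3g (%d lags)\n",
                x$N, x$tau_D, x$offset, x$n_points))
  } else {
    cat("<fcs_fit> fit failed:", x$message %||% "unknown", "\n")
  }
  invisible(x)
}

#' @method tidy fcs_fit
#' @export
tidy.fcs_fit <- function(x, ...) {
  tibble(term = c("N", "tau_D", "offset"),
         estimate = c(x$N, x$tau_D, x$offset))
}

#' @method glance fcs_fit
#' @export
glance.fcs_fit <- function(x, ...) {
  tibble(N = x$N, tau_D = x$tau_D, offset = x$offset,
         residual_norm = x$residual_norm, n_points = x$n_points,
         success = x$success)
}

#' Fit many correlation curves at once
#'
#' Groups a long table of correlation curves by every column other than
#' `lag_ms`, `G` and `n_samples` (e.g. `rep`, `fwhm_nm`, `pixel`), fits each
#' group with [fit_fcs()] and returns one row per curve.
#'
#' @param curves long tibble of correlation curves.
#' @param fit_range,refine passed to [fit_fcs()].
#' @return tibble of per-curve fit results (the `glance()` columns plus
#'   the grouping columns).
#' @export
fit_fcs_many <- function(curves, fit_range = c(0.5, 4000), refine = FALSE) {
  keys <- setdiff(names(curves), c("lag_ms", "G", "n_samples", "n_curves"))
  if (length(keys) == 0) {
    return(glance(fit_fcs(curves, fit_range, refine = refine)))
  }
  curves |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(df, key) {
      glance(fit_fcs(df, fit_range, refine = refine))
    }) |>
    dplyr::ungroup()
}

#' Log-normal summary of a transit-time population
#'
#' Scanning-FCS transit-time histograms follow a log-normal distribution;
#' this fits the log-normal in three analytical representations — (i) the
#' binned density ("linear" form), (ii) the empirical cumulative
#' distribution, and (iii) a Gaussian on the log-transformed samples — and
#' reports the per-form medians `exp(mu)`. The consensus median is the
#' geometric mean of the three; the agreement flag is lowered when any pair
#' of medians differs by more than 20%.
#'
#' @param samples positive transit times (ms), at least 5.
#' @return an object of class `transit_summary`: list with `samples`,
#'   `lognorm_mu`, `lognorm_sigma`, `median_tau` (consensus, ms), `medians`
#'   (named vector: linear, cumulative, logarithmic) and `agreement`.
#' @export
transit_time_stats <- function(samples) {
  samples <- as.numeric(samples)
  if (any(!is.finite(samples)) || any(samples <= 0)) {
    abort("All transit-time samples must be positive and finite.")
  }
  if (length(samples) < 5) abort("Need at least 5 samples.")
  lx <- log(samples)
  mu3 <- mean(lx); sig3 <- sd(lx)
  if (sig3 == 0) {
    med <- exp(mu3)
    out <- list(samples = samples, lognorm_mu = mu3, lognorm_sigma = 0,
                median_tau = med,
                medians = c(linear = med, cumulative = med, logarithmic = med),
                agreement = TRUE)
    class(out) <- "transit_summary"
    return(out)
  }
  # (i) linear form: log-normal density fitted to a Freedman-Diaconis
  # histogram built on the log scale
  brk_log <- seq(min(lx), max(lx),
                 length.out = max(5L, nclass_fd(lx) + 1L))
  h <- graphics::hist(samples, breaks = exp(brk_log), plot = FALSE)
  hd <- data.frame(x = h$mids, d = h$density)
  hd <- hd[hd$d > 0, , drop = FALSE]
  med1 <- tryCatch({
    f <- minpack.lm::nlsLM(
      d ~ stats::dlnorm(x, mu, sig), data = hd,
      start = list(mu = mu3, sig = sig3),
      lower = c(mu = -Inf, sig = 1e-9))
    exp(coef(f)[["mu"]])
  }, error = function(e) exp(mu3))
  # (ii) cumulative form: log-normal CDF fitted to the empirical CDF
  sx <- sort(samples)
  ec <- (seq_along(sx) - 0.5) / length(sx)
  med2 <- tryCatch({
    f <- minpack.lm::nlsLM(
      ec ~ stats::plnorm(sx, mu, sig),
      data = data.frame(sx = sx, ec = ec),
      start = list(mu = mu3, sig = sig3),
      lower = c(mu = -Inf, sig = 1e-9))
    exp(coef(f)[["mu"]])
  }, error = function(e) exp(mu3))
  # (iii) logarithmic form: Gaussian on log-samples (closed form)
  med3 <- exp(mu3)
  meds <- c(linear = med1, cumulative = med2, logarithmic = med3)
  consensus <- exp(mean(log(meds)))
  pair_ok <- function(a, b) max(a, b) / min(a, b) - 1 <= 0.2
  agreement <- pair_ok(med1, med2) && pair_ok(med1, med3) && pair_ok(med2, med3)
  out <- list(samples = samples, lognorm_mu = log(consensus),
              lognorm_sigma = sig3, median_tau = consensus,
              medians = meds, agreement = agreement)
  class(out) <- "transit_summary"
  out
}

nclass_fd <- function(x) {
  h <- 2 * stats::IQR(x) / length(x)^(1 / 3)
  if (h <= 0) return(5L)
  max(3L, ceiling(diff(range(x)) / h))
}

#' @export
print.transit_summary <- function(x, ...) {
  cat(sprintf(
    "<transit_summary> n = %d, median tau = %.3g ms (forms: %.3g / %.3g / %.3g), sigma_log = %.3g%s\n",
    length(x$samples), x$median_tau, x$medians[1], x$medians[2], x$medians[3],
    x$lognorm_sigma, if (x$agreement) "" else " [forms disagree >20%]"))
  invisible(x)
}

#' @method glance transit_summary
#' @export
glance.transit_summary <- function(x, ...) {
  tibble(n = length(x$samples), median_tau = x$median_tau,
         median_linear = unname(x$medians["linear"]),
         median_cumulative = unname(x$medians["cumulative"]),
         median_logarithmic = unname(x$medians["logarithmic"]),
         lognorm_mu = x$lognorm_mu, lognorm_sigma = x$lognorm_sigma,
         agreement = x$agreement)
}

#' Convert a transit time to a diffusion coefficient via the spot geometry
#'
#' `D = d^2 / (8 ln2 tau_D)` for a Gaussian observation spot of full width
#' at half maximum `d`. With `d` in nm and `tau_D` in ms the result is in
#' nm^2/ms and is converted to um^2/s (1 nm^2/ms = 1e-3 um^2/s).
#'
#' @param tau_d transit time(s), ms.
#' @param fwhm spot FWHM, nm.
#' @return diffusion coefficient(s), um^2/s.
#' @examples
#' transit_to_D_spot(11.27, 250)  # ~1.0 um^2/s
#' @export
transit_to_D_spot <- function(tau_d, fwhm) {
  stopifnot(all(tau_d > 0), all(fwhm > 0))
  nm2ms_to_um2s(fwhm^2 / (8 * ln2 * tau_d))
}

#' Convert a transit time to a diffusion coefficient via a calibration pair
#'
#' Uses an instrument calibration (`tau_ref`, `D_ref`) measured on the same
#' optical configuration: `D = D_ref * tau_ref / tau_d`. This effective-focus
#' calibration is kept separate from [transit_to_D_spot()] because measured
#' confocal transit-time/diffusion pairs reflect the instrument's effective
#' focal geometry rather than the nominal spot diameter.
#'
#' @param tau_d transit time(s), ms.
#' @param tau_ref reference transit time, ms.
#' @param D_ref reference diffusion coefficient, um^2/s.
#' @return diffusion coefficient(s), um^2/s.
#' @examples
#' transit_to_D_calibrated(35, tau_ref = 50, D_ref = 0.14)  # 0.20
#' @export
transit_to_D_calibrated <- function(tau_d, tau_ref, D_ref) {
  stopifnot(all(tau_d > 0), tau_ref > 0, D_ref > 0)
  D_ref * tau_ref / tau_d
}
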