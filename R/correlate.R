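#' Bleaching correction of an intensity trace
#'
#' Removes the initial bleaching transient by cropping off the first
#' `crop_s` seconds, then corrects residual bleaching by local averaging
#' over consecutive `window_s`-second intervals: the interval means,
#' interpolated smoothly across the trace, form a local baseline and the
#' trace is rescaled as `F'(t) = F(t) * mean(F) / baseline(t)`. The
#' multiplicative form preserves the relative fluctuation amplitude on
#' which the correlation amplitude `1/N` depends. A trailing interval
#' shorter than half the window is merged into its predecessor.
#'
#' @param trace data frame with columns `time_ms`, `intensity`.
#' @param crop_s seconds cropped from the start (default 5).
#' @param window_s local-averaging window in seconds (default 16).
#' @return corrected trace (tibble `time_ms`, `intensity`).
#' @export
bleach_correct <- function(trace, crop_s = 5, window_s = 16) {
  stopifnot(all(c("time_ms", "intensity") %in% names(trace)),
            crop_s >= 0, window_s > 0)
  t_ms <- trace$time_ms
  duration_s <- (max(t_ms) - min(t_ms)) / 1000
  if (crop_s >= duration_s) {
    abort("Trace is shorter than the crop interval.")
  }
  keep <- t_ms >= min(t_ms) + crop_s * 1000
  t_ms <- t_ms[keep]
  v <- trace$intensity[keep]
  seg <- floor((t_ms - min(t_ms)) / (window_s * 1000))
  # merge a short trailing interval into its predecessor
  last <- max(seg)
  if (last > 0 && sum(seg == last) < sum(seg == last - 1) / 2) {
    seg[seg == last] <- last - 1
  }
  # interval means anchored at the interval centres, interpolated into a
  # smooth baseline; interpolation in log space is exact for exponential
  # photobleaching and keeps the baseline positive
  centers <- tapply(t_ms, seg, mean)
  logspace <- all(v > 0)
  # geometric interval means are exact anchors for exponential
  # photobleaching whatever the interval length; fall back to arithmetic
  # means when the trace touches zero
  means <- if (logspace) {
    exp(tapply(log(v), seg, mean))
  } else {
    tapply(v, seg, mean)
  }
  if (length(means) < 2) {
    local <- rep(mean(v), length(v))
  } else {
    y <- if (logspace) log(means) else means
    local <- stats::approx(centers, y, xout = t_ms, rule = 2)$y
    k <- length(centers)
    sl_lo <- (y[2] - y[1]) / (centers[2] - centers[1])
    sl_hi <- (y[k] - y[k - 1]) / (centers[k] - centers[k - 1])
    lo <- t_ms < centers[1]
    hi <- t_ms > centers[k]
    local[lo] <- y[1] + sl_lo * (t_ms[lo] - centers[1])
    local[hi] <- y[k] + sl_hi * (t_ms[hi] - centers[k])
    if (logspace) local <- exp(local)
  }
  g <- mean(v)
  if (any(local <= 0)) {
    abort("Local mean is non-positive; cannot rescale trace.")
  }
  tibble(time_ms = t_ms, intensity = v * g / local)
}

trace_dt <- function(trace) {
  d <- diff(trace$time_ms)
  if (any(d <= 0)) abort("Trace times must be strictly increasing.")
  stats::median(d)
}

#' Autocorrelate an intensity trace
#'
#' Computes the normalized fluorescence autocorrelation
#' `G(tau) = <dF(t) dF(t+tau)> / <F>^2`. The `"direct"` estimator evaluates
#' every multiple of the sampling interval up to `max_lag_ms` (O(n * lags);
#' the reference estimator). The `"multitau"` estimator uses the standard
#' quasi-logarithmic multiple-tau scheme: `points_per_octave` lags per
#' octave, with the trace pairwise-binned at each coarser level, which keeps
#' the cost near-linear for long traces and produces the familiar
#' log-spaced FCS curve.
#'
#' @param trace data frame with `time_ms`, `intensity`.
#' @param max_lag_ms largest lag (default a quarter of the trace for
#'   multitau, 1/20 for direct).
#' @param method `"multitau"` (production) or `"direct"` (reference).
#' @param points_per_octave lags per octave for the multitau scheme.
#' @return a correlation curve: tibble with `lag_ms`, `G`, `n_samples`.
#' @export
autocorrelate <- function(trace, max_lag_ms = NULL,
                          method = c("multitau", "direct"),
                          points_per_octave = 16) {
  method <- match.arg(method)
  stopifnot(all(c("time_ms", "intensity") %in% names(trace)))
  v <- trace$intensity
  dt <- trace_dt(trace)
  n <- length(v)
  span <- (n - 1) * dt
  max_lag_ms <- max_lag_ms %||% (span / if (method == "direct") 20 else 4)
  if (max_lag_ms >= span / 2) {
    abort("`max_lag_ms` must be below half the trace duration.")
  }
  m <- mean(v)
  if (abs(m) < .Machine$double.eps * max(1, max(abs(v)))) {
    abort("Trace mean is zero; correlation amplitude is undefined.")
  }
  if (method == "direct") {
    kmax <- floor(max_lag_ms / dt)
    G <- numeric(kmax); ns <- integer(kmax)
    d <- v - m
    for (k in seq_len(kmax)) {
      G[k] <- mean(d[seq_len(n - k)] * d[seq_len(n - k) + k]) / m^2
      ns[k] <- n - k
    }
    out <- new_corr_curve(seq_len(kmax) * dt, G)
    out$n_samples <- ns
    return(out)
  }
  multitau_correlate(v, dt, max_lag_ms, points_per_octave)
}

multitau_correlate <- function(v, dt, max_lag_ms, m_oct) {
  lags <- numeric(0); G <- numeric(0); ns <- integer(0)
  s <- v
  spacing <- dt
  level <- 0L
  repeat {
    ks <- if (level == 0L) seq_len(2L * m_oct) else (m_oct + 1L):(2L * m_oct)
    mu <- mean(s)
    d <- s - mu
    n <- length(s)
    for (k in ks) {
      lag <- k * spacing
      if (lag > max_lag_ms) break
      if (k >= n) break
      G <- c(G, mean(d[seq_len(n - k)] * d[seq_len(n - k) + k]) / mu^2)
      lags <- c(lags, lag)
      ns <- c(ns, n - k)
    }
    if (2L * m_oct * spacing >= max_lag_ms) break
    if (length(s) < 4L * m_oct) break
    # pairwise binning for the next octave
    nn <- (length(s) %/% 2L) * 2L
    s <- (s[seq(1L, nn, 2L)] + s[seq(2L, nn, 2L)]) / 2
    spacing <- spacing * 2
    level <- level + 1L
  }
  out <- new_corr_curve(lags, G)
  out$n_samples <- ns
  out
}

#' Average correlation curves over repetitions
#'
#' Averages `G` per lag across repeated measurements, keeping the supplied
#' grouping columns (typically the spot size). Fitting the averaged curve
#' is the standard way to stabilise FCS estimates over repetitions.
#'
#' @param curves long tibble of correlation curves (e.g. several `rep`s per
#'   `fwhm_nm`).
#' @param by character vector of columns to keep (default `"fwhm_nm"` when
#'   present, otherwise none: one pooled curve).
#' @return tibble with the `by` columns plus `lag_ms`, `G`, `n_curves`.
#' @export
average_curves <- function(curves, by = intersect("fwhm_nm", names(curves))) {
  stopifnot(all(c("lag_ms", "G") %in% names(curves)))
  curves |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "lag_ms")))) |>
    dplyr::summarise(n_curves = dplyr::n(), G = mean(.data$G),
                     .groups = "drop")
}

#' Per-pixel correlation of a scanning-FCS carpet
#'
#' A line-scan carpet holds one intensity trace per pixel along the scanned
#' line, all sharing the line-scan period as sampling interval. Each pixel
#' trace is bleach-corrected and autocorrelated; the pixel index is carried
#' through to the output.
#'
#' @param carpet data frame with columns `pixel`, `time_ms`, `intensity`.
#' @param crop_s,window_s bleach-correction parameters (see
#'   [bleach_correct()]); `crop_s = 0` disables cropping.
#' @param max_lag_ms,method,points_per_octave passed to [autocorrelate()].
#' @return tibble with `pixel`, `lag_ms`, `G`, `n_samples`.
#' @export
sfcs_carpet <- function(carpet, crop_s = 5, window_s = 16,
                        max_lag_ms = NULL, method = "multitau",
                        points_per_octave = 16) {
  stopifnot(all(c("pixel", "time_ms", "intensity") %in% names(carpet)))
  counts <- table(carpet$pixel)
  if (length(unique(as.integer(counts))) != 1) {
    abort("Ragged carpet: all pixel traces must have the same length.")
  }
  carpet |>
    dplyr::group_by(.data$pixel) |>
    dplyr::group_modify(function(df, key) {
      tr <- tibble(time_ms = df$time_ms, intensity = df$intensity)
      tr <- bleach_correct(tr, crop_s = crop_s, window_s = window_s)
      autocorrelate(tr, max_lag_ms = max_lag_ms, method = method,
                    points_per_octave = points_per_octave)
    }) |>
    dplyr::ungroup()
}

#' Plot a correlation curve
#'
#' @param object a correlation curve (tibble with `lag_ms`, `G`).
#' @param fit optional `fcs_fit` whose model curve is overlaid.
#' @param ... unused.
#' @return a ggplot object (log-scaled lag axis).
#' @method autoplot corr_curve
#' @export
autoplot.corr_curve <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$lag_ms, y = .data$G)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(tau ~ "(ms)"), y = expression(G(tau)))
  if (!is.null(fit)) {
    pr <- tibble(lag_ms = object$lag_ms,
                 G = fcs_model_2d(object$lag_ms, fit$N, fit$tau_D, fit$offset))
    p <- p + ggplot2::geom_line(data = pr, colour = "red")
  }
  p
}
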