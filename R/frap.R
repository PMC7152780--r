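#' Preprocess a FRAP recording
#'
#' Applies background subtraction, optional correction by a no-bleach
#' acquisition control (divides out acquisition photobleaching), normalizes
#' to the prebleach mean, and sets the time origin to the first post-bleach
#' frame. The standard protocol records `n_prebleach` frames, a bleach
#' event, and the recovery; bleach frames themselves are assumed absent
#' from the series (prebleach frames are immediately followed by recovery
#' frames).
#'
#' @param data data frame with columns `time`, `roi`, `background` and
#'   optionally `control` (a matched ROI acquired without the bleach).
#' @param n_prebleach number of prebleach frames (default 2).
#' @return a `frap_trace` tibble with `time` (origin at the first
#'   post-bleach frame), `value` (normalized intensity) and `phase`
#'   (`"prebleach"`/`"recovery"`).
#' @export
preprocess_frap <- function(data, n_prebleach = 2) {
  stopifnot(all(c("time", "roi", "background") %in% names(data)),
            n_prebleach >= 1)
  if (nrow(data) <= n_prebleach + 1) {
    abort("Series must extend beyond the prebleach frames.")
  }
  v <- data$roi - data$background
  if ("control" %in% names(data) && !all(is.na(data$control))) {
    ctrl <- data$control - data$background
    if (any(ctrl <= 0)) abort("Background-subtracted control is non-positive.")
    v <- v / ctrl
  }
  pre <- mean(v[seq_len(n_prebleach)])
  if (!is.finite(pre) || pre <= 0) {
    abort("Prebleach mean is non-positive after background subtraction.")
  }
  v <- v / pre
  t0 <- data$time[n_prebleach + 1]
  out <- tibble(
    time = data$time - t0,
    value = v,
    phase = c(rep("prebleach", n_prebleach),
              rep("recovery", nrow(data) - n_prebleach)))
  class(out) <- c("frap_trace", class(out))
  out
}

#' Fit the two-component FRAP recovery model
#'
#' Fits `F(t) = A1 (1 - exp(-(t - t0)/tau1)) + A2 (1 - exp(-(t - t0)/tau2))`
#' to the post-bleach frames by nonlinear least squares. Components are
#' relabeled after fitting so that `tau1 < tau2` (fast component first).
#' `t0` is fixed at the first post-bleach frame unless floated.
#'
#' @param trace a `frap_trace` from [preprocess_frap()], or any data frame
#'   with `time` and `value` columns whose `time >= 0` rows are the
#'   recovery (a `phase` column, when present, selects the recovery
#'   frames).
#' @param float_t0 also fit the time origin `t0`.
#' @return an object of class `frap_fit`: `A1`, `A2`, `tau1`, `tau2`, `t0`,
#'   `mobile_fraction` (`A1 + A2`), `fast_fraction` (`A1/(A1 + A2)`),
#'   `residual_norm`, `success`.
#' @examples
#' crv <- synth_frap_curve(0.5, 0.5, 2, 17.5, times = 0:100)
#' fit <- fit_frap(crv)
#' fit$fast_fraction
#' @export
fit_frap <- function(trace, float_t0 = FALSE) {
  stopifnot(all(c("time", "value") %in% names(trace)))
  rec <- if ("phase" %in% names(trace)) {
    trace[trace$phase == "recovery", , drop = FALSE]
  } else {
    trace[trace$time >= 0, , drop = FALSE]
  }
  if (nrow(rec) < 10) abort("Need at least 10 post-bleach points.")
  t <- rec$time; v <- rec$value
  span <- mean(v[t >= stats::quantile(t, 0.9)])
  if (!is.finite(span) || span <= 0) span <- max(v) - min(v)
  i_half <- which(v >= min(v) + (span - min(v)) / 2)[1]
  tau0 <- if (!is.na(i_half) && t[i_half] > min(t)) {
    t[i_half] - min(t)
  } else {
    diff(range(t)) / 10
  }
  resid_fn <- function(p) {
    t0v <- if (float_t0) p[["t0"]] else 0
    v - frap_model(t, p[["A1"]], p[["A2"]], p[["tau1"]], p[["tau2"]], t0v)
  }
  lower <- c(A1 = 0, A2 = 0, tau1 = 1e-12, tau2 = 1e-12)
  if (float_t0) lower <- c(lower, t0 = -Inf)
  # a small multi-start guards against the degenerate local optimum where
  # one component collapses onto the bound
  make_start <- function(f1, f2) {
    s <- c(A1 = span / 2, A2 = span / 2, tau1 = f1 * tau0, tau2 = f2 * tau0)
    if (float_t0) s <- c(s, t0 = min(t))
    s
  }
  starts <- list(make_start(1, 10), make_start(1 / 3, 3), make_start(2, 20))
  best <- NULL
  msgs <- character(0)
  for (s in starts) {
    r <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fn, lower = lower,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) e)
    if (inherits(r, "error")) { msgs <- c(msgs, conditionMessage(r)); next }
    if (!r$info %in% 1:4) { msgs <- c(msgs, r$message); next }
    if (is.null(best) || r$deviance < best$deviance) best <- r
  }
  if (is.null(best)) {
    out <- list(A1 = NA_real_, A2 = NA_real_, tau1 = NA_real_,
                tau2 = NA_real_, t0 = NA_real_, mobile_fraction = NA_real_,
                fast_fraction = NA_real_, residual_norm = NA_real_,
                success = FALSE,
                message = paste(unique(msgs), collapse = "; "))
    class(out) <- "frap_fit"
    return(out)
  }
  cf <- best$par
  A1 <- cf[["A1"]]; A2 <- cf[["A2"]]
  tau1 <- cf[["tau1"]]; tau2 <- cf[["tau2"]]
  if (tau1 > tau2) {  # relabel so the fast component is first
    tmp <- tau1; tau1 <- tau2; tau2 <- tmp
    tmp <- A1; A1 <- A2; A2 <- tmp
  }
  mob <- A1 + A2
  out <- list(A1 = A1, A2 = A2, tau1 = tau1, tau2 = tau2,
              t0 = if (float_t0) cf[["t0"]] else 0,
              mobile_fraction = mob,
              fast_fraction = if (mob > 0) A1 / mob else NA_real_,
              residual_norm = sqrt(best$deviance),
              success = TRUE, message = NULL)
  class(out) <- "frap_fit"
  out
}

#' @export
print.frap_fit <- function(x, ...) {
  if (x$success) {
    cat(sprintf(
      "<frap_fit> A1 = %.3g (tau1 = %.3g), A2 = %.3g (tau2 = %.3g); mobile %.2f, fast %.1f%%\n",
      x$A1, x$tau1, x$A2, x$tau2, x$mobile_fraction, 100 * x$fast_fraction))
  } else {
    cat("<frap_fit> fit failed:", x$message %||% "unknown", "\n")
  }
  invisible(x)
}

#' @method tidy frap_fit
#' @export
tidy.frap_fit <- function(x, ...) {
  tibble(term = c("A1", "A2", "tau1", "tau2", "t0"),
         estimate = c(x$A1, x$A2, x$tau1, x$tau2, x$t0))
}

#' @method glance frap_fit
#' @export
glance.frap_fit <- function(x, ...) {
  tibble(A1 = x$A1, A2 = x$A2, tau1 = x$tau1, tau2 = x$tau2, t0 = x$t0,
         mobile_fraction = x$mobile_fraction,
         fast_fraction = x$fast_fraction,
         residual_norm = x$residual_norm, success = x$success)
}

#' Plot a FRAP trace with its fitted recovery
#'
#' @param object a `frap_trace`.
#' @param fit optional `frap_fit` overlay.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot frap_trace
#' @export
autoplot.frap_trace <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (frames after bleach)",
                  y = "normalized intensity")
  if (!is.null(fit) && fit$success) {
    tt <- seq(0, max(object$time), length.out = 200)
    pr <- tibble(time = tt,
                 value = frap_model(tt, fit$A1, fit$A2, fit$tau1, fit$tau2,
                                    fit$t0))
    p <- p + ggplot2::geom_line(data = pr, colour = "red")
  }
  p
}

#' Convert a FRAP recovery time to a diffusion coefficient
#'
#' Simple-diffusion approximation for a circular bleach region:
#' `D = r^2 / (4 tau)` with bleach-spot radius `r`. A rough scale estimate,
#' not a full reaction-diffusion treatment.
#'
#' @param tau recovery time (s).
#' @param roi_radius bleach region radius (um, default 1).
#' @return diffusion coefficient, um^2/s.
#' @examples
#' frap_tau_to_D(2, roi_radius = 1)  # 0.125
#' @export
frap_tau_to_D <- function(tau, roi_radius = 1) {
  stopifnot(all(tau > 0), roi_radius > 0)
  roi_radius^2 / (4 * tau)
}
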