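#' Calibrate STED observation-spot diameters from transit-time ratios
#'
#' The STED spot diameter at depletion power `P_STED` follows from the
#' transit times of a reference (supported lipid bilayer) sample:
#' `d = fwhm_conf * sqrt(tau_sted / tau_conf)`. Replicate measurements at
#' the same power are averaged before applying the relation. Entries with
#' `tau_sted > tau_conf` (an unphysical calibration, since depletion can
#' only shrink the spot) are flagged but retained.
#'
#' @param measurements data frame with columns `P_STED` (mW), `tau_sted`,
#'   `tau_conf` (ms); replicate rows per power allowed.
#' @param fwhm_conf confocal spot FWHM, nm (default 250).
#' @return a `spot_calibration` tibble with `P_STED`, `tau_sted`,
#'   `tau_conf`, `d` (nm) and `flagged`.
#' @examples
#' calibrate_spot(data.frame(P_STED = c(0, 100), tau_sted = c(50, 12.5),
#'                           tau_conf = 50))
#' @export
calibrate_spot <- function(measurements, fwhm_conf = 250) {
  stopifnot(all(c("P_STED", "tau_sted", "tau_conf") %in% names(measurements)),
            fwhm_conf > 0)
  if (any(measurements$tau_sted <= 0) || any(measurements$tau_conf <= 0)) {
    abort("Transit times must be positive.")
  }
  out <- measurements |>
    dplyr::group_by(.data$P_STED) |>
    dplyr::summarise(tau_sted = mean(.data$tau_sted),
                     tau_conf = mean(.data$tau_conf), .groups = "drop") |>
    dplyr::mutate(
      d = fwhm_conf * sqrt(.data$tau_sted / .data$tau_conf),
      flagged = .data$tau_sted > .data$tau_conf) |>
    dplyr::arrange(.data$P_STED)
  attr(out, "fwhm_conf") <- fwhm_conf
  class(out) <- c("spot_calibration", class(out))
  out
}

#' Assemble the spot-size-dependent diffusion law D(d)
#'
#' For each observation spot size, converts every fitted transit time to an
#' apparent diffusion coefficient via [transit_to_D_spot()] and summarises
#' mean, sd and n. The dependence of the apparent `D` on the spot diameter
#' `d` discriminates diffusion modes: a flat `D(d)` indicates free
#' diffusion, a drop of `D` at small spots indicates transient trapping,
#' and a rise of `D` at small spots indicates compartmentalized (hop)
#' diffusion across a meshwork.
#'
#' @param fits tibble of FCS fits with columns `fwhm_nm` and `tau_D`
#'   (e.g. from [fit_fcs_many()]); rows with failed fits are dropped.
#' @param tolerance classification tolerance on the D-ratio (see
#'   [classify_mode()]).
#' @return an object of class `diffusion_law`: list with `points` (tibble
#'   `d_nm`, `D`, `sd`, `n`, sorted by `d` descending), `ratio_stat`
#'   (`D(d_min)/D(d_max)`) and `label` (free/trapped/hop/ambiguous).
#' @export
diffusion_law <- function(fits, tolerance = 0.2) {
  stopifnot(all(c("fwhm_nm", "tau_D") %in% names(fits)))
  spots_in <- unique(fits$fwhm_nm)
  if ("success" %in% names(fits)) fits <- dplyr::filter(fits, .data$success)
  fits <- dplyr::filter(fits, is.finite(.data$tau_D), .data$tau_D > 0)
  dropped <- setdiff(spots_in, unique(fits$fwhm_nm))
  if (length(dropped)) {
    warn(paste0("Dropping spot size(s) without usable fits: ",
                paste(dropped, collapse = ", "), " nm"))
  }
  pts <- fits |>
    dplyr::mutate(D = transit_to_D_spot(.data$tau_D, .data$fwhm_nm)) |>
    dplyr::group_by(d_nm = .data$fwhm_nm) |>
    dplyr::summarise(D_mean = mean(.data$D), sd = sd(.data$D),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::rename(D = "D_mean") |>
    dplyr::arrange(dplyr::desc(.data$d_nm))
  if (nrow(pts) < 2) abort("Need fits at >= 2 distinct spot sizes.")
  law <- structure(list(points = pts, ratio_stat = NA_real_,
                        label = NA_character_),
                   class = "diffusion_law")
  law$ratio_stat <- law_ratio(law)
  law$label <- classify_mode(law, tolerance = tolerance)
  law
}

law_ratio <- function(law) {
  pts <- law$points
  pts$D[which.min(pts$d_nm)] / pts$D[which.max(pts$d_nm)]
}

#' Classify the diffusion mode from a diffusion law
#'
#' Uses the ratio `rho = D(d_min) / D(d_max)` of the apparent diffusion
#' coefficients at the extreme spot sizes: `free` when `|rho - 1|` is within
#' `tolerance`, `trapped` when `rho < 1 - tolerance` (apparent D falls at
#' small spots), `hop` when `rho > 1 + tolerance` (apparent D rises at
#' small spots). When the standard errors of the two endpoint means
#' straddle the decision threshold, the label is `ambiguous`.
#'
#' @param law a `diffusion_law`.
#' @param tolerance fractional tolerance on the ratio (default 0.2).
#' @return one of `"free"`, `"trapped"`, `"hop"`, `"ambiguous"`.
#' @export
classify_mode <- function(law, tolerance = 0.2) {
  stopifnot(inherits(law, "diffusion_law"), tolerance > 0)
  pts <- law$points
  i_min <- which.min(pts$d_nm); i_max <- which.max(pts$d_nm)
  rho <- pts$D[i_min] / pts$D[i_max]
  lab <- function(r) {
    if (abs(r - 1) <= tolerance) "free"
    else if (r < 1 - tolerance) "trapped"
    else "hop"
  }
  label <- lab(rho)
  se_min <- pts$sd[i_min] / sqrt(pts$n[i_min])
  se_max <- pts$sd[i_max] / sqrt(pts$n[i_max])
  if (is.finite(se_min) && is.finite(se_max)) {
    # propagate endpoint standard errors onto the ratio
    se_rho <- rho * sqrt((se_min / pts$D[i_min])^2 + (se_max / pts$D[i_max])^2)
    if (lab(rho - se_rho) != lab(rho + se_rho)) label <- "ambiguous"
  }
  label
}

#' @export
print.diffusion_law <- function(x, ...) {
  cat(sprintf("<diffusion_law> %d spot sizes, D(d_min)/D(d_max) = %.3g -> %s\n",
              nrow(x$points), x$ratio_stat, x$label))
  print(x$points)
  invisible(x)
}

#' @method tidy diffusion_law
#' @export
tidy.diffusion_law <- function(x, ...) x$points

#' @method glance diffusion_law
#' @export
glance.diffusion_law <- function(x, ...) {
  tibble(n_spots = nrow(x$points), ratio_stat = x$ratio_stat, label = x$label)
}

#' Plot a diffusion law D(d)
#'
#' @param object a `diffusion_law`.
#' @param ... unused.
#' @return a ggplot of apparent D (mean +/- sd) against spot diameter.
#' @method autoplot diffusion_law
#' @export
autoplot.diffusion_law <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$d_nm, y = .data$D)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$D - .data$sd, ymax = .data$D + .data$sd)) +
    ggplot2::geom_line(linetype = 2, colour = "grey50") +
    ggplot2::expand_limits(y = 0) +
    ggplot2::labs(x = "observation spot diameter d (nm)",
                  y = expression(D ~ "(" * mu * m^2 * "/s)"),
                  title = paste("Diffusion mode:", object$label))
}
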