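#' Synthesize a parametric FCS correlation curve
#'
#' Generates `G(tau) = (1/N) / (1 + tau/tau_D) + offset` — the
#' single-component two-dimensional diffusion model — at the supplied lags,
#' optionally with additive Gaussian noise.
#'
#' @param N mean occupancy of the observation spot (amplitude is `1/N`).
#' @param tau_D transit time (ms).
#' @param offset additive offset.
#' @param lags lag times (ms), strictly increasing and positive.
#' @param noise_sd sd of additive Gaussian noise (0 = noiseless).
#' @param rng_seed optional seed.
#' @return a correlation curve: tibble with `lag_ms`, `G`.
#' @examples
#' crv <- synth_fcs_curve(N = 2, tau_D = 50, lags = 10^seq(-1, 3, 0.1))
#' head(crv)
#' @export
synth_fcs_curve <- function(N, tau_D, offset = 0, lags,
                            noise_sd = 0, rng_seed = NULL) {
  stopifnot(N > 0, tau_D > 0, all(lags > 0), !is.unsorted(lags, strictly = TRUE))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  G <- fcs_model_2d(lags, N, tau_D, offset)
  if (noise_sd > 0) G <- G + rnorm(length(G), sd = noise_sd)
  new_corr_curve(lags, G)
}

# the 2-D one-component diffusion model shared by generator and fitter
fcs_model_2d <- function(tau, N, tau_D, offset) {
  (1 / N) / (1 + tau / tau_D) + offset
}

new_corr_curve <- function(lags, G, provenance = list()) {
  out <- tibble(lag_ms = lags, G = G)
  attr(out, "provenance") <- provenance
  class(out) <- c("corr_curve", class(out))
  out
}

#' Synthesize a two-component FRAP recovery curve
#'
#' `F(t) = A1 (1 - exp(-(t - t0)/tau1)) + A2 (1 - exp(-(t - t0)/tau2))` for
#' `t >= t0` and 0 before, with optional multiplicative Gaussian noise.
#' Time units are whatever `times` carries (the analysis is unit-agnostic).
#'
#' @param A1,A2 recovery amplitudes (fractions of the prebleach level).
#' @param tau1,tau2 recovery times, `tau1 < tau2`.
#' @param t0 time origin of the recovery.
#' @param times sample times.
#' @param noise_sd sd of multiplicative Gaussian noise.
#' @param rng_seed optional seed.
#' @return tibble with `time`, `value`.
#' @export
synth_frap_curve <- function(A1, A2, tau1, tau2, t0 = 0, times,
                             noise_sd = 0, rng_seed = NULL) {
  stopifnot(A1 >= 0, A2 >= 0, tau1 > 0, tau2 > 0, tau1 < tau2)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  v <- frap_model(times, A1, A2, tau1, tau2, t0)
  if (noise_sd > 0) v <- v * (1 + rnorm(length(v), sd = noise_sd))
  tibble(time = times, value = v)
}

frap_model <- function(t, A1, A2, tau1, tau2, t0) {
  ifelse(t < t0, 0,
         A1 * (1 - exp(-(t - t0) / tau1)) + A2 * (1 - exp(-(t - t0) / tau2)))
}

#' Synthesize a fluorescent-bead image with known ground truth
#'
#' Places `n_beads` bright disks on a dark background with a minimum
#' centre-to-centre separation, then adds Gaussian noise. Intended as a
#' ground-truth fixture for the watershed bead counter; separations below
#' `2 * bead_radius` produce touching/overlapping pairs.
#'
#' @param n_beads number of beads.
#' @param image_size image side length in pixels (square image).
#' @param bead_radius bead radius (pixels).
#' @param min_separation minimum centre separation (pixels).
#' @param noise_sd sd of additive Gaussian background noise.
#' @param rng_seed optional seed.
#' @param max_tries placement attempts before giving up.
#' @return list with `image` (numeric matrix, disks near 1 on a noisy
#'   background), `centers` (tibble
#'   `x`, `y` in pixels) and `n_beads`.
#' @export
synth_bead_image <- function(n_beads, image_size = 256, bead_radius = 5,
                             min_separation = 4 * bead_radius,
                             noise_sd = 0.02, rng_seed = NULL,
                             max_tries = 20000) {
  stopifnot(n_beads >= 0, image_size > 2 * bead_radius + 2)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  margin <- bead_radius + 1
  cx <- numeric(0); cy <- numeric(0)
  tries <- 0
  while (length(cx) < n_beads) {
    tries <- tries + 1
    if (tries > max_tries) {
      abort(sprintf(
        "Could not place %d beads at separation %.1f px in a %d-px image.",
        n_beads, min_separation, image_size))
    }
    px <- runif(1, margin, image_size - margin)
    py <- runif(1, margin, image_size - margin)
    if (length(cx) == 0 ||
        all((cx - px)^2 + (cy - py)^2 >= min_separation^2)) {
      cx <- c(cx, px); cy <- c(cy, py)
    }
  }
  img <- matrix(0, image_size, image_size)
  if (n_beads > 0) {
    xs <- row(img); ys <- col(img)
    for (i in seq_len(n_beads)) {
      img[(xs - cx[i])^2 + (ys - cy[i])^2 <= bead_radius^2] <- 1
    }
  }
  if (noise_sd > 0) img <- img + matrix(rnorm(length(img), sd = noise_sd),
                                        image_size, image_size)
  list(image = img, centers = tibble(x = cx, y = cy), n_beads = n_beads)
}
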