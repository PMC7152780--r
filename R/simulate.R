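#' Simulate corral-confined membrane diffusion
#'
#' Propagates molecules by Brownian motion inside a circular arena overlaid
#' with a Voronoi confinement mesh. Each time step a free molecule becomes
#' trapped with probability `p_trap` (its diffusion coefficient drops to
#' `D_trap`, practically immobile) and a trapped molecule is released with
#' the same probability. Displacements are Gaussian with per-axis variance
#' `2 D dt`. A proposed move whose endpoint lies in a different Voronoi
#' compartment is accepted with probability `p_hop`, otherwise the molecule
#' remains at its pre-step position. Molecules leaving the arena re-enter
#' antipodally (the exit point is mapped through the centre), which
#' preserves density on a circular boundary.
#'
#' Positions are recorded every `record_stride` steps (by default at the
#' configured intensity sampling interval). Unwrapped coordinates, which
#' accumulate displacements without the wrap jumps, are kept alongside the
#' wrapped ones so mean-square displacements can be computed without
#' boundary artefacts.
#'
#' @param config a [sim_config()].
#' @param mesh a `corral_mesh`; generated from `config` when `NULL`.
#' @param record_stride record every this-many steps (default:
#'   `sampling_interval / dt`).
#' @param record_states keep per-record trapped flags and compartment ids
#'   (costs memory on long runs).
#' @param record_unwrapped keep unwrapped coordinates (needed for [msd()];
#'   disable to halve memory on long intensity-only runs).
#' @param start_trapped logical, start all molecules trapped (default all
#'   free).
#' @return an object of class `trajectory_ensemble`: matrices `x`, `y`
#'   (wrapped positions, nm, records x molecules), `ux`, `uy` (unwrapped),
#'   optionally `trapped` and `compartment`, plus `times` (ms), `config` and
#'   `mesh`.
#' @examples
#' cfg <- sim_config("test", n_molecules = 5, duration = 0.01, rng_seed = 1)
#' traj <- simulate_trajectories(cfg)
#' dim(traj$x)
#' @export
simulate_trajectories <- function(config, mesh = NULL,
                                  record_stride = NULL,
                                  record_states = FALSE,
                                  record_unwrapped = TRUE,
                                  start_trapped = FALSE) {
  validate_sim_config(config)
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  if (is.null(mesh)) {
    mesh <- generate_corral_mesh(config$seed_spacing, config$arena_diameter)
  }
  if (!isTRUE(all.equal(mesh$arena_diameter, config$arena_diameter))) {
    abort("Mesh and config arena diameters disagree.")
  }
  if (is.null(record_stride)) {
    record_stride <- max(1L, round(config$sampling_interval / config$dt))
  }
  record_stride <- as.integer(record_stride)
  n_steps <- round(config$duration * 1000 / config$dt)
  step_sd <- sqrt(2 * um2s_to_nm2ms(config$D_free) * config$dt)
  if (step_sd > config$seed_spacing) {
    warn(sprintf(
      "Per-step displacement sd (%.1f nm) exceeds seed spacing (%.1f nm); corral hopping is undersampled.",
      step_sd, config$seed_spacing))
  }
  radius <- config$arena_diameter / 2
  n <- config$n_molecules
  r0 <- radius * sqrt(runif(n))
  th0 <- runif(n, 0, 2 * pi)
  res <- cpp_simulate(
    x0 = r0 * cos(th0), y0 = r0 * sin(th0),
    trapped0 = rep(isTRUE(start_trapped), n),
    seed_x = mesh$seeds$x, seed_y = mesh$seeds$y,
    arena_radius = radius, n_steps = n_steps, dt = config$dt,
    d_free = um2s_to_nm2ms(config$D_free),
    d_trap = um2s_to_nm2ms(config$D_trap),
    p_trap = config$p_trap, p_hop = config$p_hop,
    record_stride = record_stride, record_states = record_states,
    record_unwrapped = record_unwrapped, grid_cell = grid_cell_size(mesh))
  res$times <- seq(0, n_steps %/% record_stride) * record_stride * config$dt
  res$config <- config
  res$mesh <- mesh
  res$record_stride <- record_stride
  class(res) <- "trajectory_ensemble"
  res
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf(
    "<trajectory_ensemble> %d molecules, %d records at %.4g ms, arena %.0f nm\n",
    ncol(x$x), nrow(x$x), diff(x$times[1:2]), x$config$arena_diameter))
  invisible(x)
}

#' Tidy a trajectory ensemble into a long tibble
#'
#' @param x a `trajectory_ensemble`.
#' @param ... unused.
#' @return tibble with columns `molecule`, `time_ms`, `x`, `y` (wrapped, nm)
#'   and, when recorded, `trapped` and `compartment`. Large for long runs.
#' @method tidy trajectory_ensemble
#' @export
tidy.trajectory_ensemble <- function(x, ...) {
  n_rec <- nrow(x$x); n_mol <- ncol(x$x)
  out <- tibble(
    molecule = rep(seq_len(n_mol), each = n_rec),
    time_ms = rep(x$times, n_mol),
    x = as.vector(x$x), y = as.vector(x$y))
  if (!is.null(x$trapped)) {
    out$trapped <- as.vector(x$trapped) == 1L
    out$compartment <- as.vector(x$compartment)
  }
  out
}

#' Mean-square displacement of a trajectory ensemble
#'
#' Computed on the unwrapped coordinates with averaging over all time
#' origins and molecules. The apparent diffusion coefficient per lag is
#' `MSD / (4 lag)`.
#'
#' @param traj a `trajectory_ensemble`.
#' @param max_lag_ms largest lag evaluated (default a quarter of the run).
#' @param n_lags number of (evenly spaced) record lags.
#' @return tibble with `lag_ms`, `msd_nm2`, `D_apparent` (um^2/s).
#' @export
msd <- function(traj, max_lag_ms = NULL, n_lags = 25) {
  if (is.null(traj$ux)) {
    abort("Trajectories were recorded without unwrapped coordinates.")
  }
  dt_rec <- diff(traj$times[1:2])
  n_rec <- nrow(traj$ux)
  max_lag_ms <- max_lag_ms %||% (traj$times[n_rec] / 4)
  kmax <- min(n_rec - 1, floor(max_lag_ms / dt_rec))
  stopifnot(kmax >= 1)
  ks <- unique(pmax(1, round(seq(1, kmax, length.out = min(n_lags, kmax)))))
  rows <- lapply(ks, function(k) {
    dx <- traj$ux[-seq_len(k), , drop = FALSE] -
      traj$ux[seq_len(n_rec - k), , drop = FALSE]
    dy <- traj$uy[-seq_len(k), , drop = FALSE] -
      traj$uy[seq_len(n_rec - k), , drop = FALSE]
    m <- mean(dx^2 + dy^2)
    tibble(lag_ms = k * dt_rec, msd_nm2 = m,
           D_apparent = nm2ms_to_um2s(m / (4 * k * dt_rec)))
  })
  dplyr::bind_rows(rows)
}

#' Read out fluorescence intensity through Gaussian observation spots
#'
#' The intensity at each recorded time point is the sum over molecules of
#' `brightness * exp(-4 ln2 r^2 / fwhm^2)` with `r` the molecule-to-centre
#' distance — a Gaussian observation spot of full width at half maximum
#' `fwhm`. Optional Poisson shot noise replaces each sample by a Poisson
#' draw with that mean.
#'
#' @param traj a `trajectory_ensemble`.
#' @param fwhm spot FWHM(s), nm. One trace per value.
#' @param center spot centre `c(x, y)` in nm (default arena centre).
#' @param brightness expected counts per molecule per sample at the spot
#'   centre (default from the simulation config).
#' @param shot_noise apply Poisson shot noise per sample.
#' @return tibble with columns `time_ms`, `fwhm_nm`, `intensity`; the
#'   sampling interval is carried in attribute `sampling_interval_ms`.
#' @export
generate_intensity_trace <- function(traj, fwhm = NULL, center = c(0, 0),
                                     brightness = NULL, shot_noise = FALSE) {
  fwhm <- fwhm %||% traj$config$spot_fwhms
  brightness <- brightness %||% traj$config$brightness
  stopifnot(all(fwhm > 0), length(center) == 2)
  if (sum(center^2) > (traj$config$arena_diameter / 2)^2) {
    abort("Spot centre lies outside the arena.")
  }
  if (ncol(traj$x) == 0) {
    vals <- matrix(0, nrow = nrow(traj$x), ncol = length(fwhm))
  } else {
    vals <- cpp_gaussian_intensity(traj$x, traj$y,
                                   rep(center[1], length(fwhm)),
                                   rep(center[2], length(fwhm)),
                                   fwhm, brightness)
  }
  if (shot_noise) {
    vals <- matrix(rpois(length(vals), lambda = vals), nrow = nrow(vals))
  }
  out <- tibble(
    time_ms = rep(traj$times, length(fwhm)),
    fwhm_nm = rep(fwhm, each = length(traj$times)),
    intensity = as.vector(vals))
  attr(out, "sampling_interval_ms") <- diff(traj$times[1:2])
  out
}

#' Simulate an ensemble of intensity traces (repetitions x spots)
#'
#' Runs `config$n_repetitions` independent simulations (each with a freshly
#' generated confinement mesh) and reads out the intensity through every
#' configured spot size at one or more observation positions. Reading out
#' several well-separated positions per realization mirrors the
#' experimental practice of measuring several regions per cell and gives
#' near-independent correlation curves at no extra simulation cost.
#'
#' @param config a [sim_config()].
#' @param centers matrix (or data frame) of spot-centre coordinates in nm,
#'   one row per position; default a single spot at the arena centre.
#' @param shot_noise apply Poisson shot noise per sample.
#' @return tibble with `rep`, `spot`, `time_ms`, `fwhm_nm`, `intensity`.
#' @export
simulate_intensity_ensemble <- function(config, centers = NULL,
                                        shot_noise = FALSE) {
  validate_sim_config(config)
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  if (is.null(centers)) centers <- matrix(0, 1, 2)
  centers <- as.matrix(centers)
  stopifnot(ncol(centers) == 2)
  cfg1 <- config
  cfg1$rng_seed <- NULL  # one seeding above; repetitions draw from the stream
  reps <- lapply(seq_len(config$n_repetitions), function(r) {
    traj <- simulate_trajectories(cfg1, record_unwrapped = FALSE)
    spots <- lapply(seq_len(nrow(centers)), function(s) {
      tr <- generate_intensity_trace(traj, center = centers[s, ],
                                     shot_noise = shot_noise)
      tr$spot <- s
      tr
    })
    out_r <- dplyr::bind_rows(spots)
    out_r$rep <- r
    out_r
  })
  out <- dplyr::bind_rows(reps)
  attr(out, "sampling_interval_ms") <- config$sampling_interval
  out
}

#' Evenly spaced observation positions inside the arena
#'
#' Returns `n` spot centres: the arena centre plus positions on a ring,
#' spaced so neighbouring spots are several spot diameters apart.
#'
#' @param n number of positions.
#' @param arena_diameter arena diameter, nm.
#' @param ring_fraction ring radius as a fraction of the arena radius.
#' @return an `n` x 2 matrix of coordinates (nm).
#' @export
spot_grid <- function(n, arena_diameter = 3000, ring_fraction = 0.45) {
  stopifnot(n >= 1)
  if (n == 1) return(matrix(0, 1, 2))
  th <- seq(0, 2 * pi, length.out = n)[-n]
  rr <- ring_fraction * arena_diameter / 2
  rbind(c(0, 0), cbind(rr * cos(th), rr * sin(th)))
}

#' Fraction of molecules trapped at each recorded time
#'
#' Requires a run with `record_states = TRUE`.
#' @param traj a `trajectory_ensemble`.
#' @return tibble with `time_ms`, `trapped_fraction`.
#' @export
trapped_fraction <- function(traj) {
  if (is.null(traj$trapped)) {
    abort("Run simulate_trajectories() with record_states = TRUE.")
  }
  tibble(time_ms = traj$times,
         trapped_fraction = rowMeans(traj$trapped == 1L))
}
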