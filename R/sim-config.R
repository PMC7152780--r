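#' Monte-Carlo simulation configuration
#'
#' Collects every parameter of the corral-diffusion Monte-Carlo simulation.
#' The `"paper"` preset holds the full-scale study conditions: 200 molecules
#' in a 3,000-nm circular arena, 15 s at 0.001-ms steps, free diffusion
#' coefficient 0.4 um^2/s, trapped diffusion coefficient 0.1e-9 um^2/s
#' (practically immobile), per-step trapping/release probability 5e-5,
#' corral-boundary passage probability `p_hop` (1 = unrestricted passage),
#' Voronoi seed spacing 50 nm, 10 repetitions, observation spots of
#' 250/150/100/50 nm FWHM. The `"test"` preset scales the run down
#' (50 molecules, 2 s, dt 0.002 ms) for fast exercises; all physics
#' parameters are unchanged.
#'
#' @param preset `"paper"` or `"test"`.
#' @param ... named overrides of any field below.
#' @return an object of class `sim_config` (a named list) with fields
#'   `n_molecules`, `arena_diameter` (nm), `duration` (s), `dt` (ms),
#'   `D_free`, `D_trap` (um^2/s), `p_trap` (per step), `p_hop` (per boundary
#'   encounter), `seed_spacing` (nm), `n_repetitions`, `rng_seed`,
#'   `spot_fwhms` (nm), `brightness` (counts/molecule/sample),
#'   `sampling_interval` (ms).
#' @examples
#' cfg <- sim_config("test", p_hop = 0.05, rng_seed = 1)
#' cfg$n_molecules
#' @export
sim_config <- function(preset = c("paper", "test"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    n_molecules = 200L,
    arena_diameter = 3000,
    duration = 15,
    dt = 0.001,
    D_free = 0.4,
    D_trap = 0.1e-9,
    p_trap = 5e-5,
    p_hop = 1,
    seed_spacing = 50,
    n_repetitions = 10L,
    rng_seed = NULL,
    spot_fwhms = c(250, 150, 100, 50),
    brightness = 1,
    sampling_interval = 0.01
  )
  if (preset == "test") {
    cfg$n_molecules <- 50L
    cfg$duration <- 2
    cfg$dt <- 0.002
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    abort(paste0("Unknown sim_config field(s): ",
                 paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(
      n_molecules >= 0,
      arena_diameter > 0, duration > 0, dt > 0,
      D_free > D_trap, D_trap >= 0,
      p_trap >= 0, p_trap <= 1,
      p_hop >= 0, p_hop <= 1,
      seed_spacing > 0, arena_diameter > seed_spacing,
      n_repetitions >= 1,
      all(spot_fwhms > 0), brightness > 0,
      sampling_interval >= dt
    )
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d molecules, arena %.0f nm, %.3g s at dt %.4g ms\n",
              x$n_molecules, x$arena_diameter, x$duration, x$dt))
  cat(sprintf("  D_free %.3g um^2/s, D_trap %.3g um^2/s, p_trap %.3g, p_hop %.3g\n",
              x$D_free, x$D_trap, x$p_trap, x$p_hop))
  cat(sprintf("  mesh spacing %.0f nm, spots %s nm, %d repetition(s)\n",
              x$seed_spacing, paste(x$spot_fwhms, collapse = "/"),
              x$n_repetitions))
  invisible(x)
}
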