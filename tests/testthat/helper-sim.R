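# Shared helpers for simulation-backed tests.

# Simulate -> correlate -> average over repetitions/positions -> fit per spot.
# Returns one fitted row per spot size with the apparent D from the spot
# geometry relation.
study_fits <- function(p_trap, p_hop, seed, dt = 0.002, dur = 3, nrep = 3,
                       n_mol = 50, spots = c(250, 100, 50), n_centers = 5,
                       max_lag_ms = 400, fit_range = c(0.1, 200),
                       sampling = 0.05) {
  cfg <- sim_config("test", n_molecules = n_mol, dt = dt, duration = dur,
                    sampling_interval = sampling,
                    p_trap = p_trap, p_hop = p_hop, spot_fwhms = spots,
                    n_repetitions = nrep, rng_seed = seed)
  traces <- simulate_intensity_ensemble(cfg, centers = spot_grid(n_centers))
  curves <- traces |>
    dplyr::group_by(rep, spot, fwhm_nm) |>
    dplyr::group_modify(function(df, key) {
      autocorrelate(df, max_lag_ms = max_lag_ms)
    }) |>
    dplyr::ungroup()
  average_curves(curves) |>
    dplyr::group_by(fwhm_nm) |>
    dplyr::group_modify(function(df, key) {
      glance(fit_fcs(df, fit_range = fit_range, refine = TRUE))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(D = transit_to_D_spot(tau_D, fwhm_nm))
}

# Minimal hand-built trajectory ensemble (e.g. one immobile molecule).
manual_traj <- function(x, y, times, config) {
  structure(list(x = x, y = y, ux = x, uy = y, times = times,
                 config = config),
            class = "trajectory_ensemble")
}

# A short free-diffusion intensity trace for correlator tests.
free_trace <- function(seed = 3, duration = 1, fwhm = 250, n_mol = 20,
                       dt = 0.005, sampling = 0.02) {
  cfg <- sim_config("test", n_molecules = n_mol, duration = duration,
                    dt = dt, sampling_interval = sampling,
                    p_trap = 0, p_hop = 1, rng_seed = seed)
  traj <- simulate_trajectories(cfg)
  tr <- generate_intensity_trace(traj, fwhm = fwhm)
  tr[, c("time_ms", "intensity")]
}
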