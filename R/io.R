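#' Read and write delimited traces, curves and tables
#'
#' All tabular artefacts (intensity traces, correlation curves, fit tables,
#' diffusion laws) are written as tab-separated text with `#`-prefixed
#' header lines carrying provenance, and numerics at full double precision
#' so that `read(write(x))` reproduces `x` exactly.
#'
#' @param x data frame to write.
#' @param path file path.
#' @param comments named character vector written as `# key: value` lines.
#' @return `write_table_txt()` returns `path` invisibly;
#'   `read_table_txt()` returns a tibble with the comment header in
#'   attribute `header`.
#' @export
write_table_txt <- function(x, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) {
    writeLines(sprintf("# %s: %s", names(comments), comments), con)
  }
  out <- as.data.frame(lapply(x, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else as.character(col)
  }), check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- names(x)
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out)) {
    writeLines(do.call(paste, c(unname(out), sep = "\t")), con)
  }
  invisible(path)
}

#' @rdname write_table_txt
#' @export
read_table_txt <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  df <- utils::read.delim(text = lines[!grepl("^#", lines)], sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  out <- as_tibble(df)
  attr(out, "header") <- sub("^#\\s*", "", hdr)
  out
}

#' Write / read a simulation configuration as a flat YAML file
#'
#' Keys are exactly the [sim_config()] field names.
#'
#' @param config a `sim_config`.
#' @param path file path.
#' @return `read_sim_config()` returns a validated `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(sim_config, c(list(preset = "paper"), vals))
}

#' Run the simulation-to-diffusion-law pipeline
#'
#' Executes the configured stages end to end: Monte-Carlo simulation of
#' intensity traces (one fresh confinement mesh per repetition), optional
#' bleaching correction, multiple-tau correlation per repetition and spot
#' size, FCS model fitting, and assembly of the spot-size-dependent
#' diffusion law with its mode classification. When `out_dir` is given,
#' traces, curves, the fit table, the diffusion law and a JSON manifest
#' (parameters, seed, package version) are written there as text files.
#'
#' @param config a [sim_config()]; its `rng_seed` governs all randomness.
#' @param centers observation positions passed to
#'   [simulate_intensity_ensemble()] (default: the arena centre; see
#'   [spot_grid()] for several positions per run).
#' @param out_dir optional output directory (created if needed).
#' @param crop_s,window_s bleaching-correction parameters; the default
#'   (`crop_s = 0`, `window_s = NULL`) skips the correction, which is
#'   appropriate for simulated traces without photobleaching.
#' @param fit_range FCS fit range in ms.
#' @param average average the correlation curves over repetitions (and
#'   spot positions) per spot size before fitting — the standard way to
#'   stabilise FCS estimates from repeated measurements; with `FALSE`
#'   every curve is fitted separately and the diffusion law summarises
#'   the per-curve spread.
#' @param refine two-pass fitting (see [fit_fcs()]).
#' @param max_lag_ms largest correlation lag (default: quarter trace).
#' @param tolerance classification tolerance for [classify_mode()].
#' @param keep_traces include the (large) trace table in the return value.
#' @return list with `curves`, `fits`, `law`, `manifest` and optionally
#'   `traces`.
#' @export
run_pipeline <- function(config, centers = NULL, out_dir = NULL,
                         crop_s = 0, window_s = NULL,
                         fit_range = c(0.5, 4000), average = FALSE,
                         refine = FALSE, max_lag_ms = NULL,
                         tolerance = 0.2, keep_traces = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  validate_sim_config(config)
  traces <- stage("simulate",
                  simulate_intensity_ensemble(config, centers = centers))
  curves <- stage("correlate", {
    traces |>
      dplyr::group_by(.data$rep, .data$spot, .data$fwhm_nm) |>
      dplyr::group_modify(function(df, key) {
        tr <- tibble(time_ms = df$time_ms, intensity = df$intensity)
        if (crop_s > 0 || !is.null(window_s)) {
          dur_s <- (max(tr$time_ms) - min(tr$time_ms)) / 1000
          tr <- bleach_correct(tr, crop_s = crop_s,
                               window_s = window_s %||% dur_s)
        }
        autocorrelate(tr, max_lag_ms = max_lag_ms)
      }) |>
      dplyr::ungroup()
  })
  fits <- stage("fit-fcs", {
    to_fit <- if (average) average_curves(curves) else curves
    fit_fcs_many(to_fit, fit_range = fit_range, refine = refine)
  })
  law <- stage("sted-law", diffusion_law(fits, tolerance = tolerance))
  manifest <- list(
    package = "corralfcs",
    version = as.character(utils::packageVersion("corralfcs")),
    rng_seed = config$rng_seed,
    config = unclass(config),
    stages = c("simulate", "correlate", "fit-fcs", "sted-law"),
    parameters = list(crop_s = crop_s, window_s = window_s,
                      fit_range = fit_range, tolerance = tolerance))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table_txt(traces, file.path(out_dir, "traces.tsv"),
                    c(seed = as.character(config$rng_seed %||% NA)))
    write_table_txt(curves, file.path(out_dir, "curves.tsv"))
    write_table_txt(fits, file.path(out_dir, "fits.tsv"))
    write_table_txt(dplyr::mutate(law$points, label = law$label),
                    file.path(out_dir, "diffusion_law.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }
  out <- list(curves = curves, fits = fits, law = law, manifest = manifest)
  if (keep_traces) out$traces <- traces
  out
}
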