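#' Run the full SCR analysis pipeline
#'
#' From validated inputs to every result artifact: applies the
#' identification exclusions, builds the capture history and survey
#' summary, constructs the state space (suggesting a buffer from capture
#' spread when `buffer_km = "auto"`), fits the augmented M0 model by
#' MCMC, assesses convergence, and computes the density estimate, the
#' trap-array MCP with its density, and the realized activity-centre
#' raster. Entirely reproducible given `config$seed`. Non-convergence
#' (any Gelman-Rubin 95% upper bound at or above 1.1) flags the result
#' and raises a warning; it never suppresses output.
#'
#' @param detections An `scr_detections` tibble (see
#'   [read_detections()]).
#' @param traps An `scr_traps` table (see [read_traps()]).
#' @param config An [scr_config()].
#' @param flank_policy Passed to [apply_exclusions()].
#' @param raster_extent `"mcp"` (default) or `"state_space"`.
#' @return An `scr_analysis`: list with `summary`, `history`, `fit`,
#'   `convergence`, `converged`, `estimate`, `mcp`, `mcp_density`,
#'   `raster`, `buffer_km`, `config`.
#' @export
scr_analyze <- function(detections, traps, config,
                        flank_policy = "drop-single-flank",
                        raster_extent = "mcp") {
  filtered <- apply_exclusions(detections, flank_policy)
  history <- build_capture_history(filtered, traps, config)
  summary <- summarize_survey(history)

  buffer_km <- config$buffer_km
  if (identical(buffer_km, "auto")) {
    buffer_km <- suggest_buffer(history)$buffer_km
  }
  ss <- make_state_space(traps, buffer_km)
  fit <- fit_scr(history, ss, M = config$M, mcmc = config$mcmc,
                 seed = config$seed)
  conv <- convergence_report(fit)
  if (!attr(conv, "converged")) {
    warning("MCMC has not converged: some Gelman-Rubin 95% upper bounds >= 1.1",
            call. = FALSE)
  }
  est <- density_estimate(fit)
  mcp <- mcp_polygon(traps)
  mcpd <- mcp_density(fit, mcp = mcp)
  raster <- activity_center_raster(fit, extent = raster_extent,
                                   pixel_km = config$raster_pixel_km)
  structure(
    list(summary = summary, history = history, fit = fit,
         convergence = conv, converged = attr(conv, "converged"),
         estimate = est, mcp = mcp, mcp_density = mcpd, raster = raster,
         buffer_km = buffer_km, config = config),
    class = "scr_analysis"
  )
}

#' @export
print.scr_analysis <- function(x, ...) {
  print(x$summary)
  cat(sprintf("State-space buffer: %.2f km | area %.1f km^2 | M = %d\n",
              x$buffer_km, x$fit$area_km2, x$fit$M))
  cat(if (x$converged) "Converged" else "NOT converged",
      "(Gelman-Rubin 95% upper bounds",
      if (x$converged) "< 1.1)\n" else ">= 1.1 for some parameters)\n")
  with(x$estimate, cat(sprintf(
    "Density: %.2f / 100 km^2 (95%% HPD %.2f-%.2f), CV = %.2f (%s precision)\n",
    mean_density, hpd_lower, hpd_upper, cv, precision)))
  cat(sprintf("MCP: %.1f km^2, density %.2f / 100 km^2\n",
              x$mcp$area_km2, x$mcp_density$density_per_100km2))
  invisible(x)
}

#' Run a configured analysis from files and write all artifacts
#'
#' Thin file-to-files wrapper over [scr_analyze()] +
#' [write_scr_results()]: the batch entry point for scripted use.
#'
#' @param config_path YAML run configuration (see [read_run_config()]).
#' @param traps_path,detections_path Input CSVs.
#' @param out_dir Output directory.
#' @param usage_path Optional per-day trap status CSV.
#' @return The `scr_analysis`, invisibly.
#' @export
run_analysis_files <- function(config_path, traps_path, detections_path,
                               out_dir, usage_path = NULL) {
  config <- read_run_config(config_path)
  traps <- read_traps(traps_path, usage = usage_path)
  detections <- read_detections(detections_path, traps)
  res <- scr_analyze(detections, traps, config)
  write_scr_results(res, out_dir)
  invisible(res)
}
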