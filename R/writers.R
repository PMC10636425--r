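#' Write every artifact of an analysis as plain text
#'
#' Serialises an [scr_analyze()] result into a directory:
#' `summary.json` (survey-report summary and exclusion log),
#' `chain_<i>.csv` (one file per MCMC chain: `iter, g0, sigma, psi, N,
#' D`), `activity_centres.csv` (thinned realized activity-centre draws),
#' `diagnostics.json` (per-parameter Gelman-Rubin table and the
#' converged flag), `estimates.json` (density mean, HPD, CV, MCP
#' density), `mcp.geojson` and `raster.asc` (ESRI ASCII grid,
#' individuals per pixel).
#'
#' @param result An `scr_analysis`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scr_results <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  smry <- as.list(tibble::as_tibble(result$summary))
  smry$recaptures <- smry$recaptures[[1]]
  smry$survey_start <- as.character(smry$survey_start)
  smry$survey_end <- as.character(smry$survey_end)
  smry <- purrr::map(smry, function(v) if (length(v) == 1) v[[1]] else v)
  smry$exclusions <- result$history$exclusion_log
  jsonlite::write_json(smry, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)

  for (i in seq_along(result$fit$chains)) {
    readr::write_csv(result$fit$chains[[i]],
                     file.path(dir, sprintf("chain_%d.csv", i)),
                     progress = FALSE)
  }
  readr::write_csv(result$fit$ac_draws,
                   file.path(dir, "activity_centres.csv"), progress = FALSE)

  diag <- list(
    parameters = tibble::as_tibble(result$convergence),
    converged = result$converged
  )
  jsonlite::write_json(diag, file.path(dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  est <- as.list(tibble::as_tibble(result$estimate))
  est <- purrr::map(est, 1)
  est$buffer_km <- result$buffer_km
  est$mcp <- purrr::map(as.list(result$mcp_density), 1)
  est$artifacts <- list(mcp = "mcp.geojson", raster = "raster.asc")
  jsonlite::write_json(est, file.path(dir, "estimates.json"),
                       auto_unbox = TRUE, digits = NA)

  write_mcp_geojson(result$mcp, file.path(dir, "mcp.geojson"),
                    density_per_100km2 = result$mcp_density$density_per_100km2)
  write_ascii_grid(result$raster, file.path(dir, "raster.asc"))
  invisible(dir)
}

#' Write an MCP as a GeoJSON polygon
#'
#' Planar km coordinates are written as-is (the package never
#' reprojects); the ring is closed as GeoJSON requires.
#'
#' @param mcp An `scr_mcp`.
#' @param path Output path.
#' @param ... Extra scalar properties to store on the feature.
#' @return `path`, invisibly.
#' @export
write_mcp_geojson <- function(mcp, path, ...) {
  v <- mcp$vertices
  ring <- lapply(c(seq_len(nrow(v)), 1L),
                 function(i) c(v$x_km[i], v$y_km[i]))
  gj <- list(
    type = "FeatureCollection",
    features = list(list(
      type = "Feature",
      properties = c(list(area_km2 = mcp$area_km2), list(...)),
      geometry = list(type = "Polygon", coordinates = list(ring))
    ))
  )
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an MCP back from GeoJSON
#' @param path GeoJSON file written by [write_mcp_geojson()].
#' @return An `scr_mcp`.
#' @export
read_mcp_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  ring <- gj$features[[1]]$geometry$coordinates[[1]]
  ring <- ring[-length(ring)]  # drop the closing vertex
  v <- tibble::tibble(
    x_km = purrr::map_dbl(ring, 1),
    y_km = purrr::map_dbl(ring, 2)
  )
  structure(list(vertices = v, area_km2 = shoelace_area(as.matrix(v))),
            class = "scr_mcp")
}

#' Write a density raster as an ESRI ASCII grid
#'
#' @param raster An `scr_raster`.
#' @param path Output path (`.asc`).
#' @param nodata NODATA sentinel (the grid itself has no missing cells).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(raster, path, nodata = -9999) {
  v <- raster$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", raster$x0),
    paste("yllcorner", raster$y0),
    paste("cellsize", raster$pixel_km),
    paste("NODATA_value", nodata)
  ), con)
  # ASCII grids run north to south; row 1 of `values` is the south edge
  for (r in rev(seq_len(nrow(v)))) {
    writeLines(paste(formatC(v[r, ], format = "g", digits = 15),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid
#' @param path `.asc` file written by [write_ascii_grid()].
#' @return An `scr_raster` (with `n_draws = NA`).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  vals <- setNames(as.numeric(vapply(hdr, `[`, "", 2)),
                   vapply(hdr, `[`, "", 1))
  body <- do.call(rbind, lapply(lines[-(1:6)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  structure(
    list(values = body[rev(seq_len(nrow(body))), , drop = FALSE],
         x0 = vals[["xllcorner"]], y0 = vals[["yllcorner"]],
         pixel_km = vals[["cellsize"]], n_draws = NA_integer_),
    class = "scr_raster"
  )
}
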