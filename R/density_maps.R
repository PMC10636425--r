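#' Minimum convex polygon of the trap array
#'
#' The convex hull of the camera-trap coordinates, the conventional
#' reporting region for camera-trap density ("size of the study area").
#'
#' @param traps An `scr_traps` table (or data frame with `x_km`, `y_km`).
#' @return An `scr_mcp`: list with `vertices` (tibble `x_km`, `y_km`,
#'   counter-clockwise, first vertex not repeated) and `area_km2`
#'   (shoelace formula).
#' @export
#' @examples
#' tr <- as_scr_traps(data.frame(site_id = letters[1:4],
#'                               x_km = c(0, 10, 10, 0),
#'                               y_km = c(0, 0, 10, 10)))
#' mcp_polygon(tr)$area_km2
mcp_polygon <- function(traps) {
  xy <- unique(cbind(traps$x_km, traps$y_km))
  if (nrow(xy) < 3) stop("an MCP needs at least 3 distinct trap locations")
  h <- grDevices::chull(xy[, 1], xy[, 2])  # clockwise order
  v <- xy[rev(h), , drop = FALSE]          # counter-clockwise
  area <- shoelace_area(v)
  if (area <= 0) stop("trap locations are collinear: MCP is degenerate")
  structure(
    list(vertices = tibble::tibble(x_km = v[, 1], y_km = v[, 2]),
         area_km2 = area),
    class = "scr_mcp"
  )
}

#' @export
print.scr_mcp <- function(x, ...) {
  cat("MCP:", nrow(x$vertices), "vertices, area",
      round(x$area_km2, 2), "km^2\n")
  invisible(x)
}

shoelace_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  j <- c(seq_len(nrow(v))[-1], 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# boundary-inclusive membership for a counter-clockwise convex polygon:
# a point is inside iff every edge cross product is >= -tol
points_in_convex <- function(px, py, vertices, tol = 1e-9) {
  vx <- vertices$x_km; vy <- vertices$y_km
  nv <- length(vx)
  inside <- rep(TRUE, length(px))
  for (e in seq_len(nv)) {
    f <- if (e == nv) 1L else e + 1L
    cross <- (vx[f] - vx[e]) * (py - vy[e]) - (vy[f] - vy[e]) * (px - vx[e])
    inside <- inside & cross >= -tol
  }
  inside
}

#' Raster of realized activity-centre density
#'
#' Bins the thinned posterior draws of realized activity centres (rows
#' with `z = 1`) onto a square-pixel grid aligned to the integer
#' multiples of the pixel size. Each pixel holds the posterior expected
#' number of realized activity centres it contains — count across draws
#' divided by the number of draws — i.e. individuals per pixel; with the
#' default 1-km pixels that is individuals per km^2. Pixels are the
#' half-open cells `[x0, x0 + w) x [y0, y0 + w)`, so they partition the
#' plane and no centre is counted twice.
#'
#' @param draws Realized activity-centre draws: tibble with `x`, `y` (km)
#'   and one row per realized centre per draw (`ac_draws` of an
#'   `scr_fit`), or an `scr_fit`, in which case its draws and draw count
#'   are used.
#' @param extent Either `"mcp"` (default; grid covers the trap MCP),
#'   `"state_space"`, or a list with `xlim`, `ylim`. For a bare draw
#'   table an explicit extent is required.
#' @param pixel_km Pixel side length in km (default 1).
#' @param n_draws Number of thinned posterior draws the centres came
#'   from; taken from the fit when `draws` is an `scr_fit`.
#' @param traps Trap table, needed only for `extent = "mcp"` with bare
#'   draws.
#' @return An `scr_raster`: list with `values` (ny x nx matrix, row 1 =
#'   southernmost), `x0`, `y0` (lower-left corner), `pixel_km`,
#'   `n_draws`.
#' @export
activity_center_raster <- function(draws, extent = "mcp", pixel_km = 1,
                                   n_draws = NULL, traps = NULL) {
  if (inherits(draws, "scr_fit")) {
    fit <- draws
    draws <- fit$ac_draws
    if (is.null(n_draws)) n_draws <- fit$n_ac_draws
    if (identical(extent, "state_space")) {
      extent <- fit$state_space
    } else if (identical(extent, "mcp")) {
      mcp <- mcp_polygon(fit$history$traps)
      extent <- list(xlim = range(mcp$vertices$x_km),
                     ylim = range(mcp$vertices$y_km))
    }
  } else if (identical(extent, "mcp")) {
    if (is.null(traps)) stop("`traps` is required for extent = \"mcp\"")
    mcp <- mcp_polygon(traps)
    extent <- list(xlim = range(mcp$vertices$x_km),
                   ylim = range(mcp$vertices$y_km))
  }
  if (is.null(n_draws) || n_draws < 1) {
    stop("`n_draws` (number of posterior draws) is required")
  }
  if (nrow(draws) == 0) stop("no activity-centre draws to rasterise")
  w <- pixel_km
  x0 <- floor(extent$xlim[1] / w) * w
  y0 <- floor(extent$ylim[1] / w) * w
  nx <- max(1L, ceiling((extent$xlim[2] - x0) / w))
  ny <- max(1L, ceiling((extent$ylim[2] - y0) / w))
  ix <- floor((draws$x - x0) / w) + 1
  iy <- floor((draws$y - y0) / w) + 1
  keep <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  counts <- matrix(0, nrow = ny, ncol = nx)
  if (any(keep)) {
    tab <- table(factor(iy[keep], levels = seq_len(ny)),
                 factor(ix[keep], levels = seq_len(nx)))
    counts <- matrix(as.numeric(tab), nrow = ny, ncol = nx)
  }
  structure(
    list(values = counts / n_draws, x0 = x0, y0 = y0,
         pixel_km = w, n_draws = n_draws),
    class = "scr_raster"
  )
}

#' @export
print.scr_raster <- function(x, ...) {
  cat("Activity-centre raster:", nrow(x$values), "x", ncol(x$values),
      "pixels of", x$pixel_km, "km;",
      "total mass", round(sum(x$values), 3), "individuals\n")
  invisible(x)
}

#' Tidy a density raster to a long tibble
#' @param x An `scr_raster`.
#' @param ... Unused.
#' @return Tibble `x_km`, `y_km` (pixel centres), `density` (individuals
#'   per pixel).
#' @method tidy scr_raster
#' @export
tidy.scr_raster <- function(x, ...) {
  ny <- nrow(x$values); nx <- ncol(x$values)
  tibble::tibble(
    x_km = x$x0 + (rep(seq_len(nx), each = ny) - 0.5) * x$pixel_km,
    y_km = x$y0 + (rep(seq_len(ny), times = nx) - 0.5) * x$pixel_km,
    density = as.vector(x$values)
  )
}

#' Density over the minimum convex polygon
#'
#' Realized activity centres falling inside the MCP (boundary inclusive),
#' totalled over all posterior draws, divided by the number of draws and
#' the MCP area: the expected number of individuals centred in the
#' reporting region, per 100 km^2.
#'
#' @param draws Realized activity-centre draws (tibble with `x`, `y`) or
#'   an `scr_fit`.
#' @param mcp An `scr_mcp`; computed from the fit's traps when `draws` is
#'   an `scr_fit` and `mcp` is missing.
#' @param n_draws Number of posterior draws; taken from the fit when
#'   available. Fitting with `mcmc_config(ac_from = "all")` makes the
#'   draw set (and this denominator) span every iteration including
#'   burn-in, mirroring the literal all-iterations convention some
#'   analyses use; the default spans post-burn-in draws only.
#' @return One-row tibble: `density_per_100km2`, `mean_ac_inside`,
#'   `area_km2`, `n_draws`.
#' @export
mcp_density <- function(draws, mcp = NULL, n_draws = NULL) {
  if (inherits(draws, "scr_fit")) {
    fit <- draws
    if (is.null(mcp)) mcp <- mcp_polygon(fit$history$traps)
    if (is.null(n_draws)) n_draws <- fit$n_ac_draws
    draws <- fit$ac_draws
  }
  if (is.null(mcp)) stop("`mcp` is required")
  if (mcp$area_km2 <= 0) stop("degenerate MCP: zero area")
  if (is.null(n_draws) || n_draws < 1) stop("`n_draws` is required")
  inside <- points_in_convex(draws$x, draws$y, mcp$vertices)
  mean_inside <- sum(inside) / n_draws
  tibble::tibble(
    density_per_100km2 = mean_inside / mcp$area_km2 * 100,
    mean_ac_inside = mean_inside,
    area_km2 = mcp$area_km2,
    n_draws = n_draws
  )
}
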