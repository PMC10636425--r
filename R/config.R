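#' MCMC sampler settings
#'
#' Settings for the Metropolis-within-Gibbs sampler used by [fit_scr()].
#' Defaults follow the standard protocol for closed-population Bayesian SCR
#' on sparse carnivore data: three chains of 10,000 iterations with a
#' burn-in of 2,000, so each chain retains 8,000 draws.
#'
#' @param n_chains Number of independent chains (>= 2; the Gelman-Rubin
#'   diagnostic needs at least two).
#' @param n_iter Iterations per chain.
#' @param burn_in Iterations discarded from the start of each chain
#'   (`burn_in < n_iter`). Proposal adaptation, when enabled, happens only
#'   during burn-in so the retained draws form a valid Markov chain.
#' @param thin_ac Thinning interval for the stored activity-centre draws
#'   (the scalar chains are never thinned). Mapping products use the
#'   thinned draws.
#' @param adapt Adapt proposal scales during burn-in (Robbins-Monro toward
#'   0.44 acceptance for scalar parameters and 0.25 for the bivariate
#'   activity centres)?
#' @param ac_from Which iterations contribute stored activity-centre
#'   draws: `"post_burnin"` (default; the statistically defensible
#'   choice) or `"all"` (every iteration including burn-in, for analyses
#'   that divide activity-centre counts by the literal total iteration
#'   count). The scalar chains always exclude burn-in.
#' @param prop_s,prop_g0,prop_sigma Initial random-walk proposal standard
#'   deviations for the activity centres (km), logit(g0) and log(sigma).
#' @return A list of class `mcmc_config`.
#' @export
#' @examples
#' mcmc_config(n_iter = 2000, burn_in = 500)
mcmc_config <- function(n_chains = 3L, n_iter = 10000L, burn_in = 2000L,
                        thin_ac = 10L, adapt = TRUE,
                        ac_from = c("post_burnin", "all"),
                        prop_s = 1.0, prop_g0 = 0.3, prop_sigma = 0.1) {
  ac_from <- match.arg(ac_from)
  n_chains <- as.integer(n_chains)
  n_iter <- as.integer(n_iter)
  burn_in <- as.integer(burn_in)
  thin_ac <- as.integer(thin_ac)
  if (n_chains < 2L) stop("`n_chains` must be >= 2 (R-hat needs multiple chains)")
  if (burn_in >= n_iter) stop("`burn_in` must be smaller than `n_iter`")
  if (burn_in < 0L) stop("`burn_in` must be non-negative")
  if (thin_ac < 1L) stop("`thin_ac` must be >= 1")
  stopifnot(prop_s > 0, prop_g0 > 0, prop_sigma > 0)
  structure(
    list(n_chains = n_chains, n_iter = n_iter, burn_in = burn_in,
         thin_ac = thin_ac, adapt = isTRUE(adapt), ac_from = ac_from,
         prop_s = prop_s, prop_g0 = prop_g0, prop_sigma = prop_sigma),
    class = "mcmc_config"
  )
}

#' Survey analysis configuration
#'
#' Bundles the survey window, state-space buffer, augmented population size
#' and sampler settings for one analysis. Occasions are one day long and
#' numbered 1..K from `occasion_start` (inclusive of both end dates).
#'
#' @param occasion_start,occasion_end First and last day of the survey
#'   window (`Date` or ISO-8601 string). Records outside the window are
#'   dropped when the capture history is built, so seasonal exclusions
#'   (e.g. leaving out the March mating peak) are expressed through the
#'   window, never hard-coded.
#' @param buffer_km State-space buffer width in km around the trap bounding
#'   box, or `"auto"` to derive it from capture-location spread via
#'   [suggest_buffer()].
#' @param M Augmented (super-)population size; must exceed the number of
#'   detected individuals, and generously so (posterior N piling up near M
#'   signals M is too small).
#' @param mcmc An [mcmc_config()].
#' @param raster_pixel_km Pixel size for activity-centre rasters (km).
#' @param seed Integer seed governing every random draw of the analysis.
#' @return A list of class `scr_config`.
#' @export
#' @examples
#' scr_config("2020-11-01", "2021-02-28", buffer_km = 16, M = 300)
scr_config <- function(occasion_start, occasion_end, buffer_km = "auto",
                       M = 100L, mcmc = mcmc_config(), raster_pixel_km = 1,
                       seed = 1L) {
  occasion_start <- as.Date(occasion_start)
  occasion_end <- as.Date(occasion_end)
  if (is.na(occasion_start) || is.na(occasion_end)) {
    stop("occasion dates must be valid ISO-8601 dates")
  }
  if (occasion_end < occasion_start) {
    stop("`occasion_end` must not precede `occasion_start`")
  }
  if (!identical(buffer_km, "auto")) {
    buffer_km <- as.numeric(buffer_km)
    if (!is.finite(buffer_km) || buffer_km <= 0) {
      stop("`buffer_km` must be a positive number or \"auto\"")
    }
  }
  M <- as.integer(M)
  if (M < 1L) stop("`M` must be a positive integer")
  if (!inherits(mcmc, "mcmc_config")) stop("`mcmc` must be an mcmc_config()")
  if (raster_pixel_km <= 0) stop("`raster_pixel_km` must be positive")
  structure(
    list(occasion_start = occasion_start, occasion_end = occasion_end,
         occasion_length = 1L, buffer_km = buffer_km, M = M, mcmc = mcmc,
         raster_pixel_km = raster_pixel_km, seed = as.integer(seed)),
    class = "scr_config"
  )
}

#' Number of one-day occasions in a configured window
#' @param config An [scr_config()].
#' @return Integer K.
#' @export
n_occasions <- function(config) {
  as.integer(config$occasion_end - config$occasion_start) + 1L
}

#' Map calendar dates to occasion numbers
#'
#' Occasion 1 is `occasion_start`; dates outside the window map to `NA`.
#'
#' @param dates A `Date` vector (or coercible).
#' @param config An [scr_config()].
#' @return Integer vector of occasion indices, `NA` outside the window.
#' @export
occasion_of <- function(dates, config) {
  dates <- as.Date(dates)
  k <- as.integer(dates - config$occasion_start) + 1L
  k[k < 1L | k > n_occasions(config)] <- NA_integer_
  k
}

#' Read an analysis configuration from a YAML file
#'
#' The file holds the fields of [scr_config()] at top level and the
#' [mcmc_config()] fields under an `mcmc:` key; absent fields take the
#' constructor defaults.
#'
#' @param path Path to a YAML file.
#' @return An `scr_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  mc <- do.call(mcmc_config, raw$mcmc %||% list())
  args <- raw[setdiff(names(raw), "mcmc")]
  args$mcmc <- mc
  do.call(scr_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
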