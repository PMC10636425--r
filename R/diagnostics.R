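#' Gelman-Rubin convergence diagnostic
#'
#' The potential scale reduction factor for m parallel chains of length
#' n: with `W` the mean within-chain variance and `B = n * var(chain
#' means)` the between-chain variance, the point estimate is
#' `sqrt(((n - 1) / n * W + B / n) / W)`, and the 95% upper bound follows
#' the Brooks-Gelman construction, replacing the between-chain
#' contribution by its 97.5% sampling quantile from an F distribution
#' with `m - 1` and `2 W^2 / var(s_i^2)` degrees of freedom. Chains that
#' have not mixed have upper bounds well above 1; the conventional rule
#' declares convergence when the 95% upper bound is below 1.1.
#'
#' @param chains Numeric matrix (iterations x chains) or list of equal
#'   length numeric vectors, m >= 2 chains of n >= 2 draws.
#' @param split Also split each chain in half (detects trends within
#'   chains; doubles m and halves n) before computing the statistic.
#' @return Named numeric vector `c(point, upper95)`.
#' @export
#' @examples
#' gelman_rubin(cbind(rnorm(500), rnorm(500)))
gelman_rubin <- function(chains, split = FALSE) {
  if (is.list(chains)) {
    len <- lengths(chains)
    if (length(unique(len)) != 1) stop("chains must have equal length")
    chains <- do.call(cbind, chains)
  }
  chains <- as.matrix(chains)
  if (split) {
    half <- floor(nrow(chains) / 2)
    chains <- cbind(chains[seq_len(half), , drop = FALSE],
                    chains[nrow(chains) - half + seq_len(half), , drop = FALSE])
  }
  m <- ncol(chains)
  n <- nrow(chains)
  if (m < 2) stop("at least two chains are required")
  if (n < 2) stop("chains must hold at least two draws")
  s2 <- apply(chains, 2, var)
  xbar <- colMeans(chains)
  W <- mean(s2)
  B <- n * var(xbar)
  if (W == 0) {
    if (B == 0) {
      warning("all chains constant and equal; R-hat = 1 by convention")
      return(c(point = 1, upper95 = 1))
    }
    return(c(point = sqrt(.Machine$double.xmax), # disjoint degenerate chains
             upper95 = sqrt(.Machine$double.xmax)))
  }
  R2_fixed <- (n - 1) / n
  R2_random <- (B / n) / W
  point <- sqrt(R2_fixed + R2_random)
  var_w <- var(s2) / m
  upper <- if (B == 0) {
    point
  } else {
    W_df <- if (var_w > 0) 2 * W^2 / var_w else Inf
    sqrt(R2_fixed + stats::qf(0.975, m - 1, W_df) * R2_random)
  }
  c(point = point, upper95 = min(upper, sqrt(.Machine$double.xmax)))
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval of the empirical distribution
#' containing at least the requested posterior mass: among windows of
#' `ceiling(mass * n)` consecutive order statistics, the narrowest is
#' returned, ties broken by the lowest start.
#'
#' @param samples Numeric vector, at least 20 draws.
#' @param mass Probability mass in (0, 1); default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' hpd_interval(rnorm(5000))
hpd_interval <- function(samples, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop("`mass` must lie strictly in (0, 1)")
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 20) stop("at least 20 samples are required for an HPD interval")
  x <- sort(samples)
  k <- ceiling(mass * n)
  starts <- seq_len(n - k + 1)
  widths <- x[starts + k - 1] - x[starts]
  i <- which.min(widths)  # which.min takes the first minimum: lowest start
  c(lower = x[i], upper = x[i + k - 1])
}

#' Coefficient of variation of a posterior sample
#'
#' Posterior SD divided by posterior mean — the standard precision metric
#' for density estimates. A CV at or below 0.20 is conventionally read as
#' high precision.
#'
#' @param samples Numeric vector with non-zero mean.
#' @return The CV (sample SD, n-1 denominator, over the mean).
#' @export
#' @examples
#' coefficient_of_variation(c(1, 2, 3))
coefficient_of_variation <- function(samples) {
  m <- mean(samples)
  if (m == 0) stop("CV undefined: sample mean is zero")
  sd(samples) / m
}

#' Precision label for a CV
#' @param cv Coefficient of variation.
#' @param threshold High-precision boundary (default 0.20).
#' @return `"high"` when `cv <= threshold`, else `"moderate-low"`.
#' @export
cv_precision <- function(cv, threshold = 0.20) {
  ifelse(cv <= threshold, "high", "moderate-low")
}

#' Convergence report for a fitted SCR model
#'
#' Gelman-Rubin point estimates and 95% upper bounds for every monitored
#' scalar parameter; the fit converged when all upper bounds fall below
#' 1.1. Non-convergence is flagged, never suppressed.
#'
#' @param fit An `scr_fit`.
#' @param params Parameters to monitor (columns of the chains).
#' @param split Use split chains (see [gelman_rubin()]).
#' @return Tibble of class `scr_convergence`: `term`, `rhat`,
#'   `rhat_upper95`, `converged` (per term, upper bound < 1.1), with a
#'   `"converged"` attribute for the whole fit.
#' @export
convergence_report <- function(fit, params = c("g0", "sigma", "psi", "N", "D"),
                               split = FALSE) {
  rows <- purrr::map(params, function(p) {
    gr <- gelman_rubin(purrr::map(fit$chains, p), split = split)
    tibble::tibble(term = p, rhat = gr[["point"]],
                   rhat_upper95 = gr[["upper95"]],
                   converged = gr[["upper95"]] < 1.1)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, converged = all(out$converged),
            class = c("scr_convergence", class(out)))
}

#' Posterior density estimate with precision metrics
#'
#' Summarises the realized-density chain (pooled across chains, post
#' burn-in): posterior mean, 95% HPD interval and CV, in individuals per
#' 100 km^2.
#'
#' @param fit An `scr_fit`.
#' @param mass HPD mass (default 0.95).
#' @return One-row tibble of class `scr_density_estimate`: `mean_density`,
#'   `hpd_lower`, `hpd_upper`, `cv`, `precision`, `mean_N`, `area_km2`.
#' @export
density_estimate <- function(fit, mass = 0.95) {
  D <- unlist(purrr::map(fit$chains, "D"), use.names = FALSE)
  hpd <- hpd_interval(D, mass)
  cv <- coefficient_of_variation(D)
  out <- tibble::tibble(
    mean_density = mean(D),
    hpd_lower = hpd[["lower"]],
    hpd_upper = hpd[["upper"]],
    cv = cv,
    precision = cv_precision(cv),
    mean_N = mean(unlist(purrr::map(fit$chains, "N"), use.names = FALSE)),
    area_km2 = fit$area_km2
  )
  structure(out, class = c("scr_density_estimate", class(out)))
}
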