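#' Tidy posterior summaries of a fitted SCR model
#'
#' One row per monitored parameter with posterior mean, SD, 95% HPD
#' bounds and the Gelman-Rubin diagnostic, pooling chains post burn-in.
#'
#' @param x An `scr_fit`.
#' @param mass HPD mass.
#' @param ... Unused.
#' @return Tibble: `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`, `rhat`, `rhat_upper95`.
#' @method tidy scr_fit
#' @export
tidy.scr_fit <- function(x, mass = 0.95, ...) {
  params <- c("g0", "sigma", "psi", "N", "D")
  purrr::map_dfr(params, function(p) {
    draws <- unlist(purrr::map(x$chains, p), use.names = FALSE)
    hpd <- hpd_interval(draws, mass)
    gr <- gelman_rubin(purrr::map(x$chains, p))
    tibble::tibble(term = p, estimate = mean(draws), std.error = sd(draws),
                   conf.low = hpd[["lower"]], conf.high = hpd[["upper"]],
                   rhat = gr[["point"]], rhat_upper95 = gr[["upper95"]])
  })
}

#' One-row summary of a fitted SCR model
#'
#' @param x An `scr_fit`.
#' @param ... Unused.
#' @return Tibble: `n_individuals`, `M`, `area_km2`, `n_chains`,
#'   `n_retained`, `converged`, `rhat_upper_max`, `mean_density`, `cv`.
#' @method glance scr_fit
#' @export
glance.scr_fit <- function(x, ...) {
  conv <- convergence_report(x)
  est <- density_estimate(x)
  tibble::tibble(
    n_individuals = x$n, M = x$M, area_km2 = x$area_km2,
    n_chains = length(x$chains), n_retained = nrow(x$chains[[1]]),
    converged = attr(conv, "converged"),
    rhat_upper_max = max(conv$rhat_upper95),
    mean_density = est$mean_density, cv = est$cv
  )
}

#' Pool MCMC chains into one long tibble
#' @param fit An `scr_fit`.
#' @return Tibble with `chain`, `iter` and one column per parameter.
#' @export
chains_long <- function(fit) {
  purrr::imap_dfr(fit$chains, function(ch, i) {
    dplyr::mutate(ch, chain = factor(i), .before = 1)
  })
}

#' Trace plots for a fitted SCR model
#'
#' @param object An `scr_fit`.
#' @param params Parameters to show.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot scr_fit
#' @export
autoplot.scr_fit <- function(object, params = c("g0", "sigma", "N", "D"),
                             ...) {
  long <- chains_long(object) |>
    tidyr::pivot_longer(dplyr::all_of(params), names_to = "term") |>
    dplyr::mutate(term = factor(.data$term, levels = params))
  ggplot2::ggplot(long, ggplot2::aes(.data$iter, .data$value,
                                     colour = .data$chain)) +
    ggplot2::geom_line(alpha = 0.7, linewidth = 0.2) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL, colour = "chain",
                  title = "Posterior traces (post burn-in)") +
    ggplot2::theme_minimal()
}

#' Map a realized activity-centre density raster
#'
#' @param object An `scr_raster`.
#' @param traps Optional trap table to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot scr_raster
#' @export
autoplot.scr_raster <- function(object, traps = NULL, ...) {
  p <- ggplot2::ggplot(tidy(object),
                       ggplot2::aes(.data$x_km, .data$y_km,
                                    fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "individuals / pixel") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)",
                  title = "Posterior density of realized activity centres") +
    ggplot2::theme_minimal()
  if (!is.null(traps)) {
    p <- p + ggplot2::geom_point(
      data = tibble::as_tibble(traps),
      ggplot2::aes(.data$x_km, .data$y_km), inherit.aes = FALSE,
      shape = 3, size = 1, colour = "white")
  }
  p
}

#' Plot the posterior density estimate against its HPD interval
#'
#' @param fit An `scr_fit`.
#' @param mass HPD mass.
#' @return A ggplot of the pooled realized-density posterior.
#' @export
plot_density_posterior <- function(fit, mass = 0.95) {
  D <- unlist(purrr::map(fit$chains, "D"), use.names = FALSE)
  est <- density_estimate(fit, mass)
  ggplot2::ggplot(tibble::tibble(D = D), ggplot2::aes(.data$D)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey35") +
    ggplot2::geom_vline(xintercept = est$mean_density, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = c(est$hpd_lower, est$hpd_upper),
                        linetype = 2, colour = "firebrick") +
    ggplot2::labs(x = "realized density (individuals / 100 km^2)",
                  y = "posterior draws",
                  title = sprintf("Density %.2f (HPD %.2f-%.2f), CV %.2f",
                                  est$mean_density, est$hpd_lower,
                                  est$hpd_upper, est$cv)) +
    ggplot2::theme_minimal()
}
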