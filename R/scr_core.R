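#' Half-normal detection probability
#'
#' Per-occasion probability of detecting an individual at a trap a
#' distance `d` from its activity centre:
#' `p(d) = g0 * exp(-d^2 / (2 * sigma^2))`.
#' `g0` is the baseline detection probability at the centre itself and
#' `sigma` (km) the spatial scale over which detectability decays — the
#' two detection parameters of the SCR observation model.
#'
#' @param g0 Baseline detection probability in `[0, 1]`.
#' @param sigma Detection-function scale in km, `> 0`.
#' @param d Trap-to-centre distance(s) in km, `>= 0`. Vectorised.
#' @return Probabilities in `[0, g0]`, non-increasing in `d`.
#' @export
#' @examples
#' detection_prob(0.1, 2, c(0, 2, 10))
detection_prob <- function(g0, sigma, d) {
  if (any(sigma <= 0)) stop("`sigma` must be positive")
  if (any(g0 < 0 | g0 > 1)) stop("`g0` must lie in [0, 1]")
  if (any(d < 0)) stop("distances must be non-negative")
  g0 * exp(-d^2 / (2 * sigma^2))
}

#' Build the rectangular state space
#'
#' The state space S is the region over which activity centres are
#' assumed distributed: the bounding box of the trap array expanded by a
#' buffer on every side. The buffer should be wide enough (two to three
#' detection scales, in practice) that individuals centred beyond it have
#' negligible detection probability; realized density is reported
#' relative to the area of S.
#'
#' @param traps An `scr_traps` table (or any data frame with `x_km`,
#'   `y_km`).
#' @param buffer_km Buffer width in km, `> 0`.
#' @return A `state_space` object: list with `xlim`, `ylim` (km) and
#'   `area_km2`.
#' @export
#' @examples
#' tr <- as_scr_traps(data.frame(site_id = c("a", "b"),
#'                               x_km = c(0, 10), y_km = c(0, 10)))
#' make_state_space(tr, 5)
make_state_space <- function(traps, buffer_km) {
  if (nrow(traps) < 1) stop("at least one trap is required")
  buffer_km <- as.numeric(buffer_km)
  if (!is.finite(buffer_km) || buffer_km <= 0) {
    stop("`buffer_km` must be a positive number")
  }
  xlim <- range(traps$x_km) + c(-1, 1) * buffer_km
  ylim <- range(traps$y_km) + c(-1, 1) * buffer_km
  structure(
    list(xlim = xlim, ylim = ylim,
         area_km2 = diff(xlim) * diff(ylim)),
    class = "state_space"
  )
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("State space: [%.2f, %.2f] x [%.2f, %.2f] km, area %.1f km^2\n",
              x$xlim[1], x$xlim[2], x$ylim[1], x$ylim[2], x$area_km2))
  invisible(x)
}

#' Suggest a state-space buffer width from capture-location spread
#'
#' A movement-scale heuristic for surveys without telemetry: the root
#' pooled spatial variance (RPSV) of capture locations about each
#' individual's mean capture location estimates the detection scale
#' sigma, and the suggested buffer is `4 * RPSV` — comfortably beyond the
#' two-to-three sigma rule of thumb. With capture location `(x, y)` and
#' individual centroids `(xbar_i, ybar_i)`,
#' `RPSV^2 = sum_i sum_captures ((x - xbar_i)^2 + (y - ybar_i)^2) /
#'           (2 * sum_i (m_i - 1))`
#' where `m_i` is individual i's capture count. Individuals captured once
#' carry no movement information and drop out; if no individual was
#' captured at two distinct sites the heuristic has nothing to work with
#' and a buffer must be set manually.
#'
#' @param history A `capture_history`.
#' @return List with `buffer_km` and `rpsv_km`.
#' @export
suggest_buffer <- function(history) {
  long <- capture_history_long(history)
  xy <- history$traps[match(long$site_id, history$traps$site_id),
                      c("x_km", "y_km")]
  long$x <- xy$x_km
  long$y <- xy$y_km
  per <- long |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(
      m = dplyr::n(),
      ss = sum((.data$x - mean(.data$x))^2 + (.data$y - mean(.data$y))^2),
      n_sites = dplyr::n_distinct(.data$site_id),
      .groups = "drop"
    )
  if (all(per$n_sites < 2)) {
    stop("no spatial recaptures: capture locations carry no movement ",
         "information; set `buffer_km` manually")
  }
  denom <- 2 * sum(per$m - 1)
  rpsv <- sqrt(sum(per$ss) / denom)
  list(buffer_km = 4 * rpsv, rpsv_km = rpsv)
}

#' Log-likelihood of the augmented M0 SCR model
#'
#' Joint log-probability of the capture history given the model state,
#' conditional on the activity centres. Under data augmentation the n
#' observed individuals are embedded in M rows; row i has latent
#' membership `z_i ~ Bernoulli(psi)` and activity centre `s_i`, and each
#' site-occasion outcome is
#' `y[i, j, k] | z_i, s_i ~ Bernoulli(z_i * usage[j, k] * p_ij)` with
#' `p_ij = detection_prob(g0, sigma, ||s_i - x_j||)`. Occasions being
#' exchangeable under M0, the per-occasion Bernoulli product collapses
#' exactly to a binomial with the site's usage-weighted effort as the
#' number of trials; partial effort enters through the exponent, so the
#' aggregation is exact, not an approximation.
#'
#' @param history A `capture_history` (its detected rows occupy the first
#'   n rows of the augmented model).
#' @param params List with `g0`, `sigma`, `psi`, `z` (length M), `s`
#'   (M x 2 matrix of centres, km).
#' @param state_space A `state_space`; all `s` must lie inside it.
#' @param conditional_only If `TRUE`, return only the detection
#'   log-likelihood of the n observed rows, without the augmented rows
#'   and the psi-z membership term.
#' @return A finite log-probability, or `-Inf` where the state has
#'   probability zero (never an error).
#' @export
scr_loglik <- function(history, params, state_space,
                       conditional_only = FALSE) {
  agg <- aggregate_history(history)
  M <- length(params$z)
  n <- nrow(agg$ycount)
  if (M < n) stop("augmented size M is smaller than the number detected")
  s <- params$s
  if (any(s[, 1] < state_space$xlim[1] | s[, 1] > state_space$xlim[2] |
          s[, 2] < state_space$ylim[1] | s[, 2] > state_space$ylim[2])) {
    return(-Inf)
  }
  d2 <- dist2_matrix(s, agg$trap_xy)
  P <- params$g0 * exp(-d2 / (2 * params$sigma^2))
  y_aug <- matrix(0, nrow = M, ncol = ncol(agg$ycount))
  y_aug[seq_len(n), ] <- agg$ycount
  ll_rows <- row_loglik(y_aug, P, agg$eff)
  if (conditional_only) {
    return(sum(ll_rows[seq_len(n)]))
  }
  z <- params$z
  if (any(z[seq_len(n)] == 0) && any(agg$ycount[z[seq_len(n)] == 0, ] > 0)) {
    return(-Inf)  # a detected individual cannot have z = 0
  }
  det_ll <- sum(ll_rows[z == 1])
  psi <- params$psi
  memb_ll <- sum(z) * log(psi) + (M - sum(z)) * log1p(-psi)
  det_ll + memb_ll
}

# counts y_ij = sum_k y[i,j,k] and effort eff_j = sum_k usage[j,k];
# exact under the Bernoulli model because detections only occur on used
# site-days (enforced at capture-history construction)
aggregate_history <- function(history) {
  list(
    ycount = apply(history$y, c(1, 2), sum),
    eff = rowSums(history$usage),
    trap_xy = as.matrix(history$traps[, c("x_km", "y_km")])
  )
}

dist2_matrix <- function(s, trap_xy) {
  outer(s[, 1], trap_xy[, 1], "-")^2 + outer(s[, 2], trap_xy[, 2], "-")^2
}

# per-row binomial log-likelihood without the (constant-free) Bernoulli
# choose term: sum_j [ y log p + (eff - y) log(1 - p) ], with 0*log(0)
# treated as 0 and impossible configurations yielding -Inf
row_loglik <- function(ycount, P, eff) {
  if (nrow(P) == 0) return(numeric(0))
  effm <- matrix(eff, nrow = nrow(P), ncol = length(eff), byrow = TRUE)
  t1 <- ycount * log(P)
  t1[ycount == 0] <- 0
  t2 <- (effm - ycount) * log1p(-P)
  t2[effm == ycount] <- 0
  rowSums(t1 + t2)
}

# log probability of an all-zero history for each row of P (used by the
# z full conditional): sum_j eff_j * log(1 - p_ij)
row_logp0 <- function(P, eff) {
  lq <- log1p(-P)
  if (any(eff == 0)) lq[, eff == 0] <- 0  # zero effort contributes nothing
  as.vector(lq %*% eff)
}
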