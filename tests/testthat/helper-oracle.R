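# Brute-force cell-by-cell log-likelihood of the augmented model:
# a plain triple loop over individuals, sites and occasions, evaluating
# each Bernoulli term separately. Deliberately naive and independent of
# the package's aggregated implementation.
brute_force_loglik <- function(history, params, state_space,
                               conditional_only = FALSE) {
  y <- history$y
  usage <- history$usage
  tr <- as.matrix(history$traps[, c("x_km", "y_km")])
  n <- dim(y)[1]; J <- dim(y)[2]; K <- dim(y)[3]
  M <- length(params$z)
  in_box <- function(s) {
    s[1] >= state_space$xlim[1] && s[1] <= state_space$xlim[2] &&
      s[2] >= state_space$ylim[1] && s[2] <= state_space$ylim[2]
  }
  rows <- if (conditional_only) seq_len(n) else seq_len(M)
  ll <- 0
  for (i in rows) {
    if (!in_box(params$s[i, ])) return(-Inf)
    zi <- if (conditional_only) 1 else params$z[i]
    for (j in seq_len(J)) {
      d <- sqrt(sum((params$s[i, ] - tr[j, ])^2))
      p0 <- params$g0 * exp(-d^2 / (2 * params$sigma^2))
      for (k in seq_len(K)) {
        p <- zi * usage[j, k] * p0
        yijk <- if (i <= n) y[i, j, k] else 0
        term <- if (yijk == 1) log(p) else log(1 - p)
        ll <- ll + term
      }
    }
  }
  if (!conditional_only) {
    ll <- ll + sum(params$z) * log(params$psi) +
      (M - sum(params$z)) * log(1 - params$psi)
  }
  unname(ll)
}

# Assemble a capture_history directly from its parts (hand fixtures)
make_history <- function(y, traps, usage = NULL,
                         start = as.Date("2020-11-01")) {
  traps <- as_scr_traps(traps)
  K <- dim(y)[3]
  if (is.null(usage)) {
    usage <- matrix(1L, nrow = nrow(traps), ncol = K,
                    dimnames = list(traps$site_id, NULL))
  }
  n <- dim(y)[1]
  inds <- if (!is.null(dimnames(y)[[1]])) dimnames(y)[[1]] else
    sprintf("A%02d", seq_len(n))
  dimnames(y) <- list(inds, traps$site_id, NULL)
  structure(
    list(y = y, usage = usage, traps = tibble::as_tibble(traps),
         individuals = inds, sites = traps$site_id, K = K,
         window = c(start = start, end = start + K - 1),
         exclusion_log = list()),
    class = "capture_history"
  )
}

grid_traps <- function(J, spacing = 2.5, ncol_grid = ceiling(sqrt(J))) {
  idx <- seq_len(J) - 1
  as_scr_traps(tibble::tibble(
    site_id = sprintf("S%03d", seq_len(J)),
    x_km = (idx %% ncol_grid) * spacing,
    y_km = (idx %/% ncol_grid) * spacing
  ))
}
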