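#' Fit the M0 spatial capture-recapture model by MCMC
#'
#' Samples the posterior of the data-augmented M0 SCR model with a
#' Metropolis-within-Gibbs sampler. The model: M augmented individuals
#' carry latent membership `z_i ~ Bernoulli(psi)` and activity centres
#' `s_i ~ Uniform(S)`; detections follow the half-normal Bernoulli
#' observation model of [scr_loglik()]. Priors are the vague defaults of
#' the Bayesian SCR literature: `g0 ~ Uniform(0, 1)`,
#' `sigma ~ Uniform(0, half the longer state-space side)`,
#' `psi ~ Uniform(0, 1)`.
#'
#' One sweep updates, in order: every activity centre by random-walk
#' Metropolis with reflection at the state-space boundary (rows are
#' conditionally independent, so all M proposals are evaluated at once;
#' rows with `z = 0` have unit likelihood and follow their uniform
#' prior); `g0` on the logit scale and `sigma` on the log scale by
#' Metropolis with the Jacobian terms their transforms require; `z` for
#' the undetected rows from its Bernoulli full conditional; and `psi`
#' from its conjugate `Beta(1 + sum(z), 1 + M - sum(z))`. Proposal scales
#' adapt toward acceptance 0.44 (scalars) / 0.25 (bivariate centres)
#' during burn-in only, so the retained draws form a valid Markov chain.
#' Realized abundance `N = sum(z)` and realized density
#' `D = N / area * 100` (individuals per 100 km^2) are recorded at every
#' retained iteration. Chains use independent seed-derived RNG streams;
#' the same seed reproduces every draw exactly.
#'
#' @param history A `capture_history`.
#' @param state_space A `state_space`; must contain all traps.
#' @param M Augmented population size, `> n` detected individuals.
#' @param mcmc An [mcmc_config()].
#' @param seed Integer seed.
#' @return An `scr_fit`: list with `chains` (list of per-chain tibbles
#'   `iter, g0, sigma, psi, N, D`, post burn-in), `ac_draws` (thinned
#'   realized activity-centre draws: `chain, iter, ind, x, y, z`),
#'   `n_ac_draws` (number of thinned draws the realized centres came
#'   from), `acceptance` (post burn-in Metropolis acceptance rates),
#'   `n`, `M`, `area_km2`, `state_space`, `history`, `mcmc`, `seed`.
#' @export
fit_scr <- function(history, state_space, M, mcmc = mcmc_config(),
                    seed = 1L) {
  agg <- aggregate_history(history)
  n <- nrow(agg$ycount)
  J <- ncol(agg$ycount)
  if (M <= n) stop("`M` must exceed the number of detected individuals (", n, ")")
  if (all(agg$eff == 0)) stop("usage mask is all zero: no effort in the survey")
  tr <- agg$trap_xy
  if (any(tr[, 1] < state_space$xlim[1] | tr[, 1] > state_space$xlim[2] |
          tr[, 2] < state_space$ylim[1] | tr[, 2] > state_space$ylim[2])) {
    stop("state space does not contain all traps")
  }
  sigma_max <- max(diff(state_space$xlim), diff(state_space$ylim)) / 2
  rpsv <- tryCatch(suggest_buffer(history)$rpsv_km, error = function(e) NULL)

  chains <- vector("list", mcmc$n_chains)
  ac_parts <- vector("list", mcmc$n_chains)
  acc_rows <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    res <- run_one_chain(agg, n, J, M, state_space, sigma_max, rpsv, mcmc,
                         seed = chain_seed(seed, ch))
    res$samples$chain <- NULL
    chains[[ch]] <- res$samples
    if (nrow(res$ac) > 0) res$ac$chain <- ch
    ac_parts[[ch]] <- res$ac
    acc_rows[[ch]] <- tibble::tibble(chain = ch,
                                     param = c("s", "g0", "sigma"),
                                     rate = res$acc)
  }
  ac_draws <- dplyr::bind_rows(ac_parts)
  ac_draws <- ac_draws[, c("chain", "iter", "ind", "x", "y", "z")]
  ac_span <- if (identical(mcmc$ac_from, "all")) mcmc$n_iter else
    mcmc$n_iter - mcmc$burn_in
  n_ac_draws <- mcmc$n_chains * floor(ac_span / mcmc$thin_ac)
  structure(
    list(chains = chains, ac_draws = ac_draws, n_ac_draws = n_ac_draws,
         acceptance = dplyr::bind_rows(acc_rows), n = n, M = M,
         area_km2 = state_space$area_km2, state_space = state_space,
         history = history, mcmc = mcmc, seed = as.integer(seed)),
    class = "scr_fit"
  )
}

# deterministic, well-separated per-chain stream seeds; double arithmetic
# avoids 32-bit overflow for large user seeds, result kept < 2^31
chain_seed <- function(seed, chain) {
  as.integer((as.numeric(seed) * 1009 + 97 * as.numeric(chain)) %% 2147483647)
}

run_one_chain <- function(agg, n, J, M, ss, sigma_max, rpsv, mcmc, seed) {
  set.seed(seed)
  eff <- agg$eff
  ycount <- rbind(agg$ycount, matrix(0, nrow = M - n, ncol = J))
  tr <- agg$trap_xy
  xlim <- ss$xlim
  ylim <- ss$ylim
  area <- ss$area_km2

  # data-informed but jittered starting values
  sigma <- (if (is.null(rpsv)) 0.15 * sigma_max else rpsv) * runif(1, 0.8, 1.25)
  sigma <- min(sigma, 0.9 * sigma_max)
  g0 <- runif(1, 0.02, 0.2)
  psi <- runif(1, n / M, min(0.9, n / M + 0.3))
  z <- c(rep(1L, n), rbinom(M - n, 1, psi))
  s <- cbind(runif(M, xlim[1], xlim[2]), runif(M, ylim[1], ylim[2]))
  if (n > 0) {
    centroid <- (ycount[seq_len(n), , drop = FALSE] %*% tr) /
      pmax(rowSums(ycount[seq_len(n), , drop = FALSE]), 1)
    s[seq_len(n), ] <- reflect(centroid + matrix(rnorm(2 * n, 0, 0.5), ncol = 2),
                               xlim, ylim)
  }

  ls_s <- log(mcmc$prop_s)
  ls_g0 <- log(mcmc$prop_g0)
  ls_sig <- log(mcmc$prop_sigma)

  D2 <- dist2_matrix(s, tr)
  E <- exp(-D2 / (2 * sigma^2))
  ll_rows <- row_loglik(ycount, g0 * E, eff)

  ac_all <- identical(mcmc$ac_from, "all")
  n_ret <- mcmc$n_iter - mcmc$burn_in
  out <- matrix(NA_real_, nrow = n_ret, ncol = 5,
                dimnames = list(NULL, c("g0", "sigma", "psi", "N", "D")))
  ac_list <- list()
  acc_post <- c(s = 0, g0 = 0, sigma = 0)
  batch <- c(s = 0, g0 = 0, sigma = 0)
  batch_n <- 0L
  batch_no <- 0L

  detected <- seq_len(n)
  for (it in seq_len(mcmc$n_iter)) {
    ## --- activity centres: joint per-row random walk with reflection
    s_prop <- reflect(s + matrix(rnorm(2 * M, 0, exp(ls_s)), ncol = 2),
                      xlim, ylim)
    D2p <- dist2_matrix(s_prop, tr)
    llp <- row_loglik(ycount, g0 * exp(-D2p / (2 * sigma^2)), eff)
    logr <- llp - ll_rows
    logr[z == 0] <- 0              # unit likelihood: prior (uniform) move
    acc <- log(runif(M)) < logr
    if (any(acc)) {
      s[acc, ] <- s_prop[acc, , drop = FALSE]
      D2[acc, ] <- D2p[acc, , drop = FALSE]
      ll_rows[acc] <- llp[acc]
      E[acc, ] <- exp(-D2[acc, , drop = FALSE] / (2 * sigma^2))
    }
    s_rate <- mean(acc[detected])
    batch[["s"]] <- batch[["s"]] + s_rate
    if (it > mcmc$burn_in) acc_post[["s"]] <- acc_post[["s"]] + s_rate

    ## --- g0 on the logit scale (Uniform(0,1) prior + Jacobian)
    lg <- stats::qlogis(g0) + rnorm(1, 0, exp(ls_g0))
    g0p <- stats::plogis(lg)
    live <- z == 1
    llp_rows <- row_loglik(ycount[live, , drop = FALSE],
                           g0p * E[live, , drop = FALSE], eff)
    logr <- sum(llp_rows) - sum(ll_rows[live]) +
      log(g0p) + log1p(-g0p) - log(g0) - log1p(-g0)
    if (is.finite(logr) && log(runif(1)) < logr) {
      g0 <- g0p
      ll_rows[live] <- llp_rows
      ll_rows[!live] <- row_loglik(ycount[!live, , drop = FALSE],
                                   g0 * E[!live, , drop = FALSE], eff)
      batch[["g0"]] <- batch[["g0"]] + 1
      if (it > mcmc$burn_in) acc_post[["g0"]] <- acc_post[["g0"]] + 1
    }

    ## --- sigma on the log scale (Uniform(0, sigma_max) prior + Jacobian)
    sigp <- sigma * exp(rnorm(1, 0, exp(ls_sig)))
    if (sigp < sigma_max) {
      Ep <- exp(-D2[live, , drop = FALSE] / (2 * sigp^2))
      llp_rows <- row_loglik(ycount[live, , drop = FALSE], g0 * Ep, eff)
      logr <- sum(llp_rows) - sum(ll_rows[live]) + log(sigp) - log(sigma)
      if (is.finite(logr) && log(runif(1)) < logr) {
        sigma <- sigp
        E <- exp(-D2 / (2 * sigma^2))
        ll_rows[live] <- llp_rows
        ll_rows[!live] <- row_loglik(ycount[!live, , drop = FALSE],
                                     g0 * E[!live, , drop = FALSE], eff)
        batch[["sigma"]] <- batch[["sigma"]] + 1
        if (it > mcmc$burn_in) acc_post[["sigma"]] <- acc_post[["sigma"]] + 1
      }
    }

    ## --- z: Bernoulli full conditional for the undetected rows
    if (M > n) {
      und <- (n + 1L):M
      lp0 <- row_logp0(g0 * E[und, , drop = FALSE], eff)
      z[und] <- rbinom(M - n, 1, prob_z1(lp0, psi))
    }

    ## --- psi: conjugate Beta update
    Nz <- sum(z)
    psi <- draw_psi(z, M)

    ## --- adaptation (burn-in only), batches of 50 sweeps
    batch_n <- batch_n + 1L
    if (mcmc$adapt && it <= mcmc$burn_in && batch_n == 50L) {
      batch_no <- batch_no + 1L
      delta <- min(0.05, 1 / sqrt(batch_no))
      ls_s <- ls_s + delta * sign(batch[["s"]] / 50 - 0.25)
      ls_g0 <- ls_g0 + delta * sign(batch[["g0"]] / 50 - 0.44)
      ls_sig <- ls_sig + delta * sign(batch[["sigma"]] / 50 - 0.44)
      batch[] <- 0
      batch_n <- 0L
    } else if (batch_n == 50L) {
      batch[] <- 0
      batch_n <- 0L
    }

    ## --- record
    if (it > mcmc$burn_in) {
      out[it - mcmc$burn_in, ] <- c(g0, sigma, psi, Nz, Nz / area * 100)
    }
    ac_clock <- if (ac_all) it else it - mcmc$burn_in
    if (ac_clock > 0L && ac_clock %% mcmc$thin_ac == 0L) {
      keep <- which(z == 1L)
      ac_list[[length(ac_list) + 1L]] <- data.frame(
        iter = it, ind = keep, x = s[keep, 1], y = s[keep, 2], z = 1L)
    }
  }

  samples <- tibble::as_tibble(as.data.frame(out))
  samples$iter <- mcmc$burn_in + seq_len(n_ret)
  samples <- samples[, c("iter", "g0", "sigma", "psi", "N", "D")]
  ac <- if (length(ac_list) > 0) {
    tibble::as_tibble(do.call(rbind, ac_list))
  } else {
    tibble::tibble(iter = integer(), ind = integer(), x = numeric(),
                   y = numeric(), z = integer())
  }
  list(samples = samples, ac = ac,
       acc = acc_post / (mcmc$n_iter - mcmc$burn_in))
}

# full conditional P(z_i = 1 | ...) for an undetected row: posterior odds
# psi * p0_i / (1 - psi), with p0_i the all-zero-history probability
prob_z1 <- function(lp0, psi) {
  stats::plogis(stats::qlogis(psi) + lp0)
}

# conjugate Beta full conditional of the inclusion probability
draw_psi <- function(z, M) {
  rbeta(1, 1 + sum(z), 1 + M - sum(z))
}

# fold a point back into [lo, hi] by repeated reflection at the edges
reflect <- function(s, xlim, ylim) {
  s[, 1] <- fold(s[, 1], xlim[1], xlim[2])
  s[, 2] <- fold(s[, 2], ylim[1], ylim[2])
  s
}

fold <- function(x, lo, hi) {
  w <- hi - lo
  x <- (x - lo) %% (2 * w)
  lo + pmin(x, 2 * w - x)
}

#' @export
print.scr_fit <- function(x, ...) {
  cat("Bayesian SCR fit (M0, half-normal detection)\n")
  cat("  detected n =", x$n, "| augmented M =", x$M,
      "| state-space area =", round(x$area_km2, 1), "km^2\n")
  cat("  chains:", length(x$chains), "x", nrow(x$chains[[1]]),
      "retained iterations\n")
  print(tidy(x))
  invisible(x)
}
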