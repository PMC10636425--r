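test_that("half-normal detection function matches its closed form", {
  expect_equal(detection_prob(0.1, 2, 0), 0.1)
  expect_equal(detection_prob(0.1, 2, 2), 0.1 * exp(-0.5))
  expect_equal(detection_prob(0, 3, c(0, 1, 5)), c(0, 0, 0))
  expect_error(detection_prob(0.1, 0, 1), "sigma")
  expect_error(detection_prob(1.2, 1, 1), "g0")

  # non-increasing in distance and in 1/sigma
  d <- seq(0, 20, by = 0.25)
  for (sigma in c(0.5, 2, 5)) {
    p <- detection_prob(0.3, sigma, d)
    expect_true(all(diff(p) <= 0))
    expect_true(all(p <= 0.3 & p >= 0))
  }
  for (dd in c(1, 4, 9)) {
    p <- detection_prob(0.3, c(0.5, 1, 2, 4, 8), dd)
    expect_true(all(diff(p) >= 0))  # larger sigma, flatter decay
  }
})

test_that("state space is the buffered trap bounding box", {
  traps <- as_scr_traps(tibble::tibble(
    site_id = c("a", "b"), x_km = c(0, 10), y_km = c(0, 10)))
  ss <- make_state_space(traps, 5)
  expect_equal(ss$xlim, c(-5, 15))
  expect_equal(ss$ylim, c(-5, 15))
  expect_equal(ss$area_km2, 400)

  one <- as_scr_traps(tibble::tibble(site_id = "o", x_km = 0, y_km = 0))
  ss13 <- make_state_space(one, 13)
  expect_equal(ss13$area_km2, 26 * 26)
  expect_error(make_state_space(one, 0), "positive")
})

test_that("RPSV buffer suggestion matches the hand-computed case", {
  traps <- as_scr_traps(tibble::tibble(
    site_id = c("a", "b", "c"), x_km = c(0, 2, 50), y_km = c(0, 0, 0)))
  y <- array(0L, dim = c(1, 3, 2))
  y[1, 1, 1] <- 1L
  y[1, 2, 2] <- 1L          # one individual, two sites 2 km apart
  hist <- make_history(y, traps)
  sb <- suggest_buffer(hist)
  expect_equal(sb$rpsv_km, 1)
  expect_equal(sb$buffer_km, 4)

  # all captures at one site: no movement information
  y2 <- array(0L, dim = c(2, 3, 2))
  y2[1, 1, 1] <- 1L; y2[1, 1, 2] <- 1L; y2[2, 2, 1] <- 1L
  expect_error(suggest_buffer(make_history(y2, traps)),
               "no spatial recaptures")
})

test_that("RPSV recovers the detection scale under heavy sampling", {
  # dense array, strong detection: capture locations scatter ~ N(s, sigma^2)
  sigma_true <- 2.5
  traps <- grid_traps(29 * 29, spacing = 1, ncol_grid = 29)
  set.seed(5)
  centres <- tibble::tibble(
    individual_id = sprintf("i%02d", 1:25),
    x_km = runif(25, 8, 20), y_km = runif(25, 8, 20))
  cfg <- sim_config(g0 = 0.5, sigma = sigma_true, K = 30,
                    n_cells_x = 4, n_cells_y = 4, buffer_km = 8)
  obs <- simulate_detections(centres, traps, cfg)
  window <- scr_config(cfg$start, cfg$start + cfg$K - 1, buffer_km = 8)
  hist <- build_capture_history(obs$detections, traps, window)
  rpsv <- suggest_buffer(hist)$rpsv_km
  expect_lt(abs(rpsv - sigma_true) / sigma_true, 0.2)
})

test_that("aggregated likelihood equals the brute-force Bernoulli oracle", {
  ss <- structure(list(xlim = c(-5, 10), ylim = c(-5, 10),
                       area_km2 = 225), class = "state_space")
  set.seed(42)
  for (case in 1:12) {
    n <- sample(1:3, 1); J <- sample(1:3, 1); K <- sample(1:3, 1)
    M <- n + sample(1:3, 1)
    traps <- grid_traps(J, spacing = 2)
    usage <- matrix(rbinom(J * K, 1, 0.8), nrow = J,
                    dimnames = list(traps$site_id, NULL))
    y <- array(0L, dim = c(n, J, K))
    for (j in 1:J) for (k in 1:K) {
      if (usage[j, k] == 1) y[, j, k] <- rbinom(n, 1, 0.4)
    }
    hist <- make_history(y, traps, usage)
    params <- list(
      g0 = runif(1, 0.05, 0.9), sigma = runif(1, 0.5, 4),
      psi = runif(1, 0.2, 0.8),
      z = c(rep(1L, n), rbinom(M - n, 1, 0.5)),
      s = cbind(runif(M, -4, 9), runif(M, -4, 9)))
    expect_equal(scr_loglik(hist, params, ss),
                 brute_force_loglik(hist, params, ss), tolerance = 1e-10)
    expect_equal(scr_loglik(hist, params, ss, conditional_only = TRUE),
                 brute_force_loglik(hist, params, ss, conditional_only = TRUE),
                 tolerance = 1e-10)
  }
})

test_that("likelihood closed-form cases and degenerate inputs behave", {
  traps <- as_scr_traps(tibble::tibble(site_id = "t", x_km = 0, y_km = 0))
  ss <- structure(list(xlim = c(-5, 5), ylim = c(-5, 5), area_km2 = 100),
                  class = "state_space")
  y1 <- array(1L, dim = c(1, 1, 1))
  hist1 <- make_history(y1, traps)
  p_at <- list(g0 = 0.2, sigma = 1, psi = 0.5, z = 1L,
               s = matrix(c(0, 0), ncol = 2))
  expect_equal(scr_loglik(hist1, p_at, ss, conditional_only = TRUE), log(0.2))

  # all-zero history with g0 = 0 has probability one
  y0 <- array(0L, dim = c(1, 1, 3))
  hist0 <- make_history(y0, traps)
  p0 <- list(g0 = 0, sigma = 1, psi = 0.5, z = 1L,
             s = matrix(c(0, 0), ncol = 2))
  expect_equal(scr_loglik(hist0, p0, ss, conditional_only = TRUE), 0)

  # certain detection against an observed zero: -Inf, not an error
  p1 <- list(g0 = 1, sigma = 1, psi = 0.5, z = 1L,
             s = matrix(c(0, 0), ncol = 2))
  expect_identical(scr_loglik(hist0, p1, ss, conditional_only = TRUE), -Inf)
})

test_that("sites with zero usage contribute nothing to the likelihood", {
  traps <- grid_traps(3, spacing = 2)
  ss <- structure(list(xlim = c(-5, 10), ylim = c(-5, 10), area_km2 = 225),
                  class = "state_space")
  set.seed(8)
  K <- 3
  y <- array(0L, dim = c(2, 3, K))
  y[1, 1, 1] <- 1L; y[2, 2, 3] <- 1L
  usage <- matrix(1L, 3, K, dimnames = list(traps$site_id, NULL))
  usage[3, ] <- 0L                       # site 3 never operated
  hist_masked <- make_history(y, traps, usage)
  hist_dropped <- make_history(y[, 1:2, , drop = FALSE], traps[1:2, ],
                               usage[1:2, , drop = FALSE])
  params <- list(g0 = 0.4, sigma = 1.5, psi = 0.5, z = c(1L, 1L, 1L),
                 s = cbind(runif(3, 0, 4), runif(3, 0, 4)))
  expect_equal(scr_loglik(hist_masked, params, ss),
               scr_loglik(hist_dropped, params, ss))
})

test_that("sampler respects constraints and is reproducible", {
  qf <- quick_fit(seed = 21, n_iter = 400, burn_in = 100)
  fit <- qf$fit
  n <- fit$n
  for (ch in fit$chains) {
    expect_true(all(ch$N >= n))                       # N >= n at every draw
    expect_equal(ch$D, ch$N / fit$area_km2 * 100)     # exact transform
    expect_true(all(ch$g0 > 0 & ch$g0 < 1))
    expect_true(all(ch$sigma > 0))
  }
  # activity-centre draws stay inside the state space, z = 1 only
  expect_true(all(fit$ac_draws$x >= fit$state_space$xlim[1] &
                  fit$ac_draws$x <= fit$state_space$xlim[2]))
  expect_true(all(fit$ac_draws$z == 1L))
  # detected individuals are present (z = 1) in every thinned draw
  per_draw <- fit$ac_draws |>
    dplyr::filter(ind <= n) |>
    dplyr::count(chain, iter)
  expect_true(all(per_draw$n == n))
  expect_equal(nrow(per_draw), fit$n_ac_draws)

  fit2 <- fit_scr(qf$history, qf$ss, M = 60, mcmc = qf$cfg$mcmc, seed = 21)
  expect_identical(fit$chains, fit2$chains)
  expect_identical(fit$ac_draws, fit2$ac_draws)
})

test_that("psi full conditional is the conjugate Beta and z follows its odds", {
  set.seed(77)
  M <- 100
  z <- c(rep(1L, 17), rbinom(M - 17, 1, 0.3))
  draws <- replicate(3000, scrcamtrap:::draw_psi(z, M))
  ks <- suppressWarnings(
    stats::ks.test(draws, stats::pbeta, 1 + sum(z), 1 + M - sum(z)))
  expect_gt(ks$p.value, 0.01)

  # membership probability equals the posterior odds expression
  lp0 <- log(runif(50))
  psi <- 0.37
  expect_equal(scrcamtrap:::prob_z1(lp0, psi),
               psi * exp(lp0) / (psi * exp(lp0) + 1 - psi))
})

test_that("Metropolis acceptance rates settle in a workable band", {
  qf <- quick_fit(seed = 13, n_iter = 1200, burn_in = 600)
  rates <- qf$fit$acceptance$rate
  expect_true(all(rates > 0.1 & rates < 0.6))
})

test_that("the sampler rejects impossible setups", {
  qf <- quick_fit(seed = 3, n_iter = 300, burn_in = 100)
  expect_error(fit_scr(qf$history, qf$ss, M = qf$fit$n,
                       mcmc = qf$cfg$mcmc), "exceed")
  hist0 <- qf$history
  hist0$usage[] <- 0L
  expect_error(fit_scr(hist0, qf$ss, M = 60, mcmc = qf$cfg$mcmc),
               "all zero")
})
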