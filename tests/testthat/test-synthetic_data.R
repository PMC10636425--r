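test_that("checkerboard trap arrays have the right counts and spacing", {
  t44 <- simulate_traps(sim_config(n_cells_x = 4, n_cells_y = 4))
  expect_equal(nrow(t44), 8)

  t10 <- simulate_traps(sim_config(n_cells_x = 10, n_cells_y = 10))
  expect_equal(nrow(t10), 50)
  # nearest neighbours sit on the other parity: 2.5 * sqrt(2) apart
  xy <- as.matrix(t10[, c("x_km", "y_km")])
  dmat <- as.matrix(dist(xy))
  diag(dmat) <- Inf
  expect_equal(unname(apply(dmat, 1, min)), rep(2.5 * sqrt(2), 50))

  full <- simulate_traps(sim_config(n_cells_x = 4, n_cells_y = 4,
                                    checkerboard = FALSE))
  expect_equal(nrow(full), 16)
})

test_that("camera losses zero usage from the loss day", {
  cfg <- sim_config(n_cells_x = 4, n_cells_y = 4, K = 30, n_lost = 2,
                    loss_day = 11)
  traps <- simulate_traps(cfg)
  usage <- build_usage(traps, list(occasion_start = cfg$start,
                                   occasion_end = cfg$start + 29))
  expect_equal(sum(usage), 8 * 30 - 2 * 20)
  expect_true(all(usage[1:2, 11:30] == 0L))
})

test_that("population size follows the Poisson of density times area", {
  cfg <- sim_config(D = 1.0, n_cells_x = 8, n_cells_y = 8, buffer_km = 11.25)
  traps <- simulate_traps(cfg)
  ss <- make_state_space(traps, cfg$buffer_km)
  expect_equal(ss$area_km2, 40 * 40)   # 17.5 km span + 2 * 11.25
  lambda <- cfg$D * ss$area_km2 / 100  # = 16

  set.seed(19)
  Ns <- replicate(5000, nrow(simulate_population(cfg, traps)$centres))
  se <- sqrt(lambda / 5000)
  expect_lt(abs(mean(Ns) - lambda), 2 * se)

  expect_equal(nrow(simulate_population(sim_config(D = 0), traps)$centres), 0)
  cfg22 <- sim_config(fixed_n = 22, n_cells_x = 8, n_cells_y = 8)
  expect_equal(nrow(simulate_population(cfg22, traps)$centres), 22)
})

test_that("per-individual detection probability matches the closed form", {
  # one individual sitting on a trap; the other traps are too far to matter
  traps <- as_scr_traps(tibble::tibble(
    site_id = c("t0", "f1", "f2", "f3"),
    x_km = c(0, 500, 500, 500), y_km = c(0, 0, 500, 250)))
  centre <- tibble::tibble(individual_id = "i1", x_km = 0, y_km = 0)
  cfg <- sim_config(g0 = 0.05, sigma = 2.5, K = 120)
  set.seed(23)
  hits <- replicate(2000, {
    sum(simulate_detections(centre, traps, cfg)$truth$detected)
  })
  p_true <- 1 - (1 - 0.05)^120
  se <- sqrt(p_true * (1 - p_true) / 2000)
  expect_lt(abs(mean(hits) - p_true), 3 * se)

  cfg0 <- sim_config(g0 = 0, K = 30)
  expect_equal(nrow(simulate_detections(centre, traps, cfg0)$detections), 0)
})

test_that("no detections occur on unused site-days", {
  cfg <- sim_config(D = 5, g0 = 0.3, sigma = 3, n_cells_x = 4, n_cells_y = 4,
                    K = 40, n_lost = 3, loss_day = 6)
  sim <- simulate_survey(cfg, seed = 29)
  lost_sites <- sim$traps$site_id[1:3]
  bad <- sim$detections$site_id %in% lost_sites &
    sim$detections$date >= cfg$start + 5
  expect_equal(sum(bad), 0)
  expect_gt(nrow(sim$detections), 0)
})

test_that("per-trap detection frequencies fit the half-normal model", {
  # one fixed individual, moderate trap fan: chi-square GOF on per-trap
  # detection counts against Binomial(K * reps, p_j)
  traps <- as_scr_traps(tibble::tibble(
    site_id = sprintf("t%d", 1:6),
    x_km = c(0, 1, 2, 3, 4, 6), y_km = 0))
  centre <- tibble::tibble(individual_id = "i1", x_km = 0, y_km = 0)
  cfg <- sim_config(g0 = 0.4, sigma = 2, K = 100)
  set.seed(37)
  reps <- 40
  counts <- rep(0, 6)
  for (r in seq_len(reps)) {
    det <- simulate_detections(centre, traps, cfg)$detections
    counts <- counts + as.vector(table(factor(det$site_id,
                                              levels = traps$site_id)))
  }
  d <- sqrt(traps$x_km^2 + traps$y_km^2)
  p <- detection_prob(cfg$g0, cfg$sigma, d)
  trials <- cfg$K * reps
  chi2 <- sum((counts - trials * p)^2 / (trials * p * (1 - p)))
  pval <- stats::pchisq(chi2, df = 6, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("identical seeds reproduce the survey; presets match their designs", {
  cfg <- sim_config(g0 = 0.1, K = 30, n_cells_x = 4, n_cells_y = 4)
  s1 <- simulate_survey(cfg, seed = 101)
  s2 <- simulate_survey(cfg, seed = 101)
  expect_identical(s1$truth, s2$truth)
  expect_identical(tibble::as_tibble(s1$detections),
                   tibble::as_tibble(s2$detections))

  ps <- preset_scenarios()
  expect_setequal(names(ps), c("mountain-park", "exclusion-zone",
                               "lowland-forest"))
  ez <- ps[["exclusion-zone"]]
  expect_equal(nrow(simulate_traps(ez$sim)), 65)
  expect_equal(ez$sim$K, 112L)
  expect_equal(ez$M, 300L)
  mp <- ps[["mountain-park"]]
  expect_equal(nrow(simulate_traps(mp$sim)), 35)
  expect_equal(mp$sim$K, 90L)
  expect_equal(mp$M, 100L)
  lf <- ps[["lowland-forest"]]
  expect_equal(nrow(simulate_traps(lf$sim)), 50)
  expect_equal(lf$sim$K, 120L)
})

test_that("written surveys reload through the standard readers", {
  sim <- simulate_survey(sim_config(g0 = 0.15, K = 20, n_cells_x = 4,
                                    n_cells_y = 4), seed = 43)
  dir <- withr::local_tempdir()
  write_survey(sim, dir)
  traps <- read_traps(file.path(dir, "traps.csv"))
  det <- read_detections(file.path(dir, "detections.csv"), traps)
  expect_equal(tibble::as_tibble(traps), tibble::as_tibble(sim$traps))
  expect_equal(tibble::as_tibble(det), tibble::as_tibble(sim$detections))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$parameters$g0, 0.15)
  expect_equal(nrow(truth$activity_centres), nrow(sim$truth))
})
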