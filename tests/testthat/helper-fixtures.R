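# Hand-built survey fixtures realizing the per-individual recapture
# breakdowns of three contrasting camera-trap surveys (a small mountain
# park, a large exclusion zone, a large lowland forest), so the survey
# summary can be checked against known margins exactly. Each individual
# is specified as (number of detections, number of distinct sites); the
# builder spreads detections over distinct days at fully-active sites,
# and trims a few trailing sites' deployments so the effective
# trap-night total comes out at the stated value.
survey_fixture_spec <- function(area) {
  switch(area,
    mountain_park = list(
      J = 35, K = 90, start = as.Date("2020-12-01"), M = 100,
      inds = list(c(6, 4), c(6, 3), c(6, 3), c(5, 2), c(4, 3)),
      short_sites = 6, short_days = 20,
      expected = list(n = 5, recaptures = 22, spatial = 10, nights = 2730)),
    exclusion_zone = list(
      J = 65, K = 112, start = as.Date("2020-11-09"), M = 300,
      inds = c(list(c(9, 7), c(8, 8), c(4, 3)),
               rep(list(c(2, 2)), 4), rep(list(c(2, 1)), 2),
               rep(list(c(1, 1)), 13)),
      short_sites = 9, short_days = 9,
      expected = list(n = 22, recaptures = 24, spatial = 19, nights = 6353)),
    lowland_forest = list(
      J = 50, K = 120, start = as.Date("2020-11-01"), M = 100,
      inds = list(c(19, 4), c(13, 3), c(10, 3), c(10, 2), c(9, 2),
                  c(6, 2), c(3, 2), c(2, 2), c(2, 2), c(1, 1), c(1, 1),
                  c(1, 1), c(1, 1), c(1, 1)),
      short_sites = 5, short_days = 70,
      expected = list(n = 14, recaptures = 65, spatial = 13, nights = 5750))
  )
}

build_survey_fixture <- function(area) {
  sp <- survey_fixture_spec(area)
  end <- sp$start + sp$K - 1
  idx <- seq_len(sp$J) - 1
  traps <- tibble::tibble(
    site_id = sprintf("T%03d", seq_len(sp$J)),
    x_km = (idx %% 8) * 2.5,
    y_km = (idx %/% 8) * 2.5,
    active_from = sp$start,
    active_to = end
  )
  # trailing sites lose their cameras early; detections only use the
  # fully-active leading sites
  short <- sp$J - seq_len(sp$short_sites) + 1
  traps$active_to[short] <- sp$start + sp$short_days - 1
  traps <- as_scr_traps(traps)

  full_pool <- traps$site_id[seq_len(sp$J - sp$short_sites)]
  recs <- list()
  offset <- 0
  for (i in seq_along(sp$inds)) {
    m <- sp$inds[[i]][1]
    nsites <- sp$inds[[i]][2]
    sites_i <- full_pool[(offset + seq_len(nsites) - 1) %% length(full_pool) + 1]
    offset <- offset + nsites
    site_seq <- c(sites_i, rep(sites_i[1], m - nsites))
    recs[[i]] <- tibble::tibble(
      individual_id = sprintf("%s_ind%02d", area, i),
      site_id = site_seq,
      date = sp$start + seq_len(m) - 1,
      flank = "both",
      age_class = "independent",
      mother_id = NA_character_
    )
  }
  records <- as_scr_detections(dplyr::bind_rows(recs), traps)
  config <- scr_config(sp$start, end, buffer_km = 15, M = sp$M,
                       mcmc = mcmc_config(n_iter = 200, burn_in = 50))
  list(traps = traps, records = records, config = config,
       expected = sp$expected, K = sp$K, J = sp$J)
}

# A small, quick synthetic survey + fit used by several tests
quick_fit <- function(seed = 11, n_iter = 800, burn_in = 200,
                      n_chains = 2, D = 1.5, g0 = 0.08, sigma = 2.5,
                      K = 40) {
  sim <- simulate_survey(
    sim_config(D = D, g0 = g0, sigma = sigma, n_cells_x = 6, n_cells_y = 6,
               K = K, buffer_km = 3 * sigma),
    seed = seed
  )
  cfg <- scr_config(sim$config$start, sim$config$start + K - 1,
                    buffer_km = 3 * sigma, M = 60,
                    mcmc = mcmc_config(n_chains = n_chains, n_iter = n_iter,
                                       burn_in = burn_in),
                    seed = seed)
  filtered <- apply_exclusions(sim$detections)
  history <- build_capture_history(filtered, sim$traps, cfg)
  ss <- make_state_space(sim$traps, 3 * sigma)
  fit <- fit_scr(history, ss, M = 60, mcmc = cfg$mcmc, seed = seed)
  list(sim = sim, cfg = cfg, history = history, ss = ss, fit = fit)
}
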