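traps4 <- function() grid_traps(4, spacing = 1, ncol_grid = 2)

rec <- function(id, site, date, flank = "both", age = "independent",
                mother = NA_character_) {
  tibble::tibble(individual_id = id, site_id = site, date = as.Date(date),
                 flank = flank, age_class = age, mother_id = mother)
}

test_that("exclusion rules: unknowns counted, juveniles merged, single flanks dropped", {
  traps <- traps4()
  records <- dplyr::bind_rows(
    rec("F1", "S001", "2020-11-01"),
    rec("J1", "S002", "2020-11-02", age = "juvenile", mother = "F1"),
    rec("J2", "S003", "2020-11-03", age = "juvenile"),      # mother unknown
    rec("LO", "S001", "2020-11-04", flank = "left"),        # left only
    rec("RO", "S002", "2020-11-05", flank = "right"),       # right only
    rec("BB", "S004", "2020-11-06", flank = "left"),
    rec("BB", "S004", "2020-11-07", flank = "right"),       # both flanks seen
    dplyr::bind_rows(purrr::map(1:10, function(i)
      rec("unknown", "S001", as.Date("2020-11-01") + i, age = "unknown")))
  )
  records <- as_scr_detections(records, traps)
  out <- apply_exclusions(records)
  log <- exclusion_log(out)

  expect_equal(log$unidentified_events, 10)
  expect_equal(log$juveniles_merged, 1)
  expect_equal(log$juvenile_unknown_mother_individuals, 1)
  expect_equal(log$single_flank_individuals, 2)
  # J1 re-assigned to F1; J2, LO, RO gone; BB kept through flank matching
  expect_setequal(unique(out$individual_id), c("F1", "BB"))
  expect_equal(sum(out$individual_id == "F1"), 2)
})

test_that("keep-left / keep-right flank policies retain one catalogue", {
  traps <- traps4()
  records <- as_scr_detections(dplyr::bind_rows(
    rec("LO", "S001", "2020-11-01", flank = "left"),
    rec("RO", "S002", "2020-11-02", flank = "right")
  ), traps)
  expect_setequal(apply_exclusions(records, "keep-left")$individual_id, "LO")
  expect_setequal(apply_exclusions(records, "keep-right")$individual_id, "RO")
  expect_equal(nrow(apply_exclusions(records, "drop-single-flank")), 0)
})

test_that("capture history collapses same-day repeats and respects the mask", {
  traps <- traps4()
  cfg <- scr_config("2020-11-01", "2020-11-02", buffer_km = 5)
  records <- as_scr_detections(dplyr::bind_rows(
    rec("A", "S003", "2020-11-01"),
    rec("A", "S003", "2020-11-01"),            # same site, same day
    rec("A", "S001", "2020-11-02"),
    rec("B", "S002", "2020-11-02"),
    rec("B", "S002", "2020-11-05")             # outside window
  ), traps)
  hist <- build_capture_history(records, traps, cfg)
  expect_equal(dim(hist$y), c(2, 4, 2))
  expect_equal(sum(hist$y), 3)
  expect_equal(hist$y["A", "S003", 1], 1L)
  expect_equal(hist$y["A", "S001", 2], 1L)
  expect_equal(hist$y["B", "S002", 2], 1L)
  expect_equal(hist$exclusion_log$outside_window_events, 1)

  # hand fixture: exact expected tensor
  expected <- array(0L, dim = c(2, 4, 2),
                    dimnames = list(c("A", "B"), traps$site_id, NULL))
  expected["A", "S003", 1] <- 1L
  expected["A", "S001", 2] <- 1L
  expected["B", "S002", 2] <- 1L
  expect_identical(hist$y, expected)
})

test_that("detections on inactive site-days are dropped and logged", {
  traps <- traps4()
  traps$active_to <- c(as.Date("2020-11-01"), rep(as.Date("2020-11-03"), 3))
  traps <- as_scr_traps(traps)
  cfg <- scr_config("2020-11-01", "2020-11-03", buffer_km = 5)
  records <- as_scr_detections(dplyr::bind_rows(
    rec("A", "S001", "2020-11-01"),
    rec("A", "S001", "2020-11-02")   # site S001 lost after day 1
  ), traps)
  hist <- build_capture_history(records, traps, cfg)
  expect_equal(sum(hist$y), 1)
  expect_equal(hist$exclusion_log$inactive_siteday_events, 1)
  # y == 1 implies usage == 1 everywhere
  idx <- which(hist$y == 1L, arr.ind = TRUE)
  expect_true(all(hist$usage[idx[, 2:3, drop = FALSE]] == 1L))
})

test_that("an empty filtered record set refuses to build a history", {
  traps <- traps4()
  cfg <- scr_config("2020-11-01", "2020-11-03", buffer_km = 5)
  records <- as_scr_detections(rec("A", "S001", "2020-12-25"), traps)
  expect_error(build_capture_history(records, traps, cfg),
               "no capture histories")
})

test_that("survey summary reproduces hand-computable recapture margins", {
  for (area in c("mountain_park", "exclusion_zone", "lowland_forest")) {
    fx <- build_survey_fixture(area)
    hist <- build_capture_history(fx$records, fx$traps, fx$config)
    smry <- summarize_survey(hist)
    expect_equal(smry$n_individuals, fx$expected$n)
    expect_equal(smry$total_recaptures, fx$expected$recaptures)
    expect_equal(smry$spatial_recaptures, fx$expected$spatial)
    expect_equal(smry$effective_trap_nights, fx$expected$nights)
    expect_equal(smry$n_sites, fx$J)
    expect_equal(smry$n_occasions, fx$K)
    expect_lte(smry$spatial_recaptures, smry$total_recaptures)
    expect_equal(smry$total_detections,
                 smry$n_individuals + smry$total_recaptures)
  }
})

test_that("a single detection yields zero recaptures of either kind", {
  traps <- traps4()
  cfg <- scr_config("2020-11-01", "2020-11-03", buffer_km = 5)
  records <- as_scr_detections(rec("A", "S001", "2020-11-02"), traps)
  smry <- summarize_survey(build_capture_history(records, traps, cfg))
  expect_equal(smry$total_recaptures, 0)
  expect_equal(smry$spatial_recaptures, 0)
})

test_that("summary is invariant to record order and counts match the tensor", {
  fx <- build_survey_fixture("lowland_forest")
  hist1 <- build_capture_history(fx$records, fx$traps, fx$config)
  set.seed(1)
  for (rep in 1:3) {
    shuffled <- fx$records[sample(nrow(fx$records)), ]
    hist2 <- build_capture_history(shuffled, fx$traps, fx$config)
    expect_identical(hist2$y, hist1$y)
    expect_equal(summarize_survey(hist2), summarize_survey(hist1))
  }
  # sum over the tensor equals unique (individual, site, day) events
  events <- dplyr::distinct(tibble::as_tibble(fx$records),
                            individual_id, site_id, date)
  expect_equal(sum(hist1$y), nrow(events))
})

test_that("spatial recaptures agree when computed from the long export", {
  fx <- build_survey_fixture("exclusion_zone")
  hist <- build_capture_history(fx$records, fx$traps, fx$config)
  long <- capture_history_long(hist)
  alt <- long |>
    dplyr::group_by(individual_id) |>
    dplyr::summarise(k = dplyr::n_distinct(site_id) - 1,
                     .groups = "drop")
  expect_equal(sum(alt$k), summarize_survey(hist)$spatial_recaptures)
})
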