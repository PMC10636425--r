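#' Apply individual-identification exclusion rules
#'
#' Applies, in order, the standard photographic-identification rules for
#' patterned felids before a capture history is built:
#'
#' 1. events whose individual could not be identified (overexposure, coat
#'    pattern not visible) are removed and counted;
#' 2. juveniles (< 1 year) are not independent demographic units: their
#'    detections are re-assigned to the mother when she is known, which
#'    adds recaptures; juvenile records whose mother is unknown are
#'    removed and counted;
#' 3. individuals photographed on a single flank only, whose left/right
#'    catalogues cannot be matched, are removed under the default policy
#'    (counting one animal as two is the risk being avoided). The
#'    alternative policies keep one flank's catalogue for sensitivity
#'    runs: `"keep-left"` drops right-only individuals and `"keep-right"`
#'    drops left-only ones; records showing both flanks always count for
#'    both catalogues.
#'
#' @param records An `scr_detections` tibble.
#' @param flank_policy One of `"drop-single-flank"` (default),
#'   `"keep-left"`, `"keep-right"`.
#' @return The filtered `scr_detections`, with an `"exclusion_log"`
#'   attribute (named list of counts; see [exclusion_log()]).
#' @export
apply_exclusions <- function(records,
                             flank_policy = c("drop-single-flank",
                                              "keep-left", "keep-right")) {
  flank_policy <- match.arg(flank_policy)
  rec <- tibble::as_tibble(records)
  if (!"unidentified" %in% names(rec)) {
    rec$unidentified <- is.na(rec$individual_id) |
      rec$individual_id %in% c("", "unknown", "unidentified", "NA")
  }

  n_unident <- sum(rec$unidentified)
  rec <- rec[!rec$unidentified, , drop = FALSE]

  juv <- rec$age_class == "juvenile"
  merge_ok <- juv & !is.na(rec$mother_id)
  merged_ids <- unique(rec$individual_id[merge_ok])
  rec$individual_id[merge_ok] <- rec$mother_id[merge_ok]
  orphan <- juv & is.na(rec$mother_id)
  n_orphan_events <- sum(orphan)
  orphan_ids <- setdiff(unique(rec$individual_id[orphan]),
                        unique(rec$individual_id[!orphan]))
  rec <- rec[!orphan, , drop = FALSE]

  flank_sets <- rec |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(
      left = any(.data$flank %in% c("left", "both")),
      right = any(.data$flank %in% c("right", "both")),
      .groups = "drop"
    )
  drop_ids <- switch(flank_policy,
    "drop-single-flank" = flank_sets$individual_id[xor(flank_sets$left,
                                                       flank_sets$right)],
    "keep-left" = flank_sets$individual_id[flank_sets$right & !flank_sets$left],
    "keep-right" = flank_sets$individual_id[flank_sets$left & !flank_sets$right]
  )
  n_flank_events <- sum(rec$individual_id %in% drop_ids)
  rec <- rec[!rec$individual_id %in% drop_ids, , drop = FALSE]

  log <- list(
    unidentified_events = n_unident,
    juveniles_merged = length(merged_ids),
    juvenile_unknown_mother_events = n_orphan_events,
    juvenile_unknown_mother_individuals = length(orphan_ids),
    single_flank_individuals = length(drop_ids),
    single_flank_events = n_flank_events,
    flank_policy = flank_policy
  )
  out <- structure(rec, class = c("scr_detections", class(tibble::tibble())))
  attr(out, "exclusion_log") <- log
  out
}

#' Retrieve the exclusion log of a filtered record set or capture history
#' @param x Output of [apply_exclusions()] or [build_capture_history()].
#' @return Named list of exclusion/drop counts.
#' @export
exclusion_log <- function(x) {
  if (inherits(x, "capture_history")) x$exclusion_log else attr(x, "exclusion_log")
}

#' Build the binary capture-history tensor
#'
#' Turns filtered detection records into the n x J x K binary array `y`
#' used by the SCR likelihood, under one-day occasions with at most one
#' detection per individual, site and occasion (repeat photographs on the
#' same day collapse to a single 1; the Bernoulli observation model makes
#' this cap exact, and it limits temporal autocorrelation). Detections
#' dated outside the configured window, or falling on site-days where the
#' camera was not operational, are dropped and counted.
#'
#' @param records Filtered `scr_detections` (normally from
#'   [apply_exclusions()]).
#' @param traps An `scr_traps` table; every record must reference one of
#'   its sites.
#' @param config An [scr_config()] fixing the window.
#' @return A `capture_history` object: list with `y` (n x J x K integer
#'   array, dimnames individuals/sites), `usage` (J x K mask), `traps`,
#'   `individuals`, `sites`, `K`, `window`, and `exclusion_log` (the
#'   record-level log extended with window/inactive drop counts).
#' @export
build_capture_history <- function(records, traps, config) {
  rec <- tibble::as_tibble(records)
  unknown <- setdiff(unique(rec$site_id), traps$site_id)
  if (length(unknown) > 0) {
    stop("detection records reference unknown site_id: ",
         paste(unknown, collapse = ", "))
  }
  usage <- build_usage(traps, config)
  K <- n_occasions(config)

  k <- occasion_of(rec$date, config)
  outside <- is.na(k)
  n_outside <- sum(outside)
  rec <- rec[!outside, , drop = FALSE]
  k <- k[!outside]

  j <- match(rec$site_id, traps$site_id)
  inactive <- usage[cbind(j, k)] == 0L
  n_inactive <- sum(inactive)
  rec <- rec[!inactive, , drop = FALSE]
  j <- j[!inactive]
  k <- k[!inactive]

  individuals <- sort(unique(rec$individual_id))
  if (length(individuals) == 0) {
    stop("no capture histories: no identified detections inside the survey window")
  }
  y <- array(0L, dim = c(length(individuals), nrow(traps), K),
             dimnames = list(individuals, traps$site_id, NULL))
  i <- match(rec$individual_id, individuals)
  y[cbind(i, j, k)] <- 1L  # duplicates collapse to a single 1

  log <- attr(records, "exclusion_log") %||% list()
  log$outside_window_events <- n_outside
  log$inactive_siteday_events <- n_inactive

  structure(
    list(y = y, usage = usage, traps = tibble::as_tibble(traps),
         individuals = individuals, sites = traps$site_id, K = K,
         window = c(start = config$occasion_start, end = config$occasion_end),
         exclusion_log = log),
    class = "capture_history"
  )
}

#' @export
print.capture_history <- function(x, ...) {
  cat("Capture history:", length(x$individuals), "individuals x",
      length(x$sites), "sites x", x$K, "occasions\n")
  cat("  detections:", sum(x$y),
      "| effective trap-nights:", sum(x$usage), "\n")
  invisible(x)
}

#' Export a capture history in long format
#'
#' @param history A `capture_history`.
#' @return Tibble with one row per detection: `individual_id`, `site_id`,
#'   `occasion`.
#' @export
capture_history_long <- function(history) {
  idx <- which(history$y == 1L, arr.ind = TRUE)
  tibble::tibble(
    individual_id = history$individuals[idx[, 1]],
    site_id = history$sites[idx[, 2]],
    occasion = as.integer(idx[, 3])
  ) |>
    dplyr::arrange(.data$individual_id, .data$occasion, .data$site_id)
}

#' Summarise a survey in the standard reporting format
#'
#' Computes the survey-report quantities used to judge how informative a
#' camera-trap data set is for SCR: the number of individuals, recaptures
#' (detection events beyond each individual's first), spatial recaptures
#' (distinct sites beyond each individual's first; these carry the
#' movement information that identifies the detection scale), the
#' per-individual recapture breakdown whose skewness flags
#' unevenly-distributed sampling, and the effective trap-nights actually
#' achieved after camera losses.
#'
#' @param history A `capture_history`.
#' @return One-row tibble of class `scr_survey_summary`: `n_individuals`,
#'   `total_detections`, `total_recaptures`, `spatial_recaptures`,
#'   `effective_trap_nights`, `n_sites`, `n_occasions`, `survey_start`,
#'   `survey_end`, plus a `recaptures` list-column holding the
#'   per-individual recapture counts (named, decreasing).
#' @export
summarize_survey <- function(history) {
  if (!inherits(history, "capture_history")) {
    stop("`history` must be a capture_history")
  }
  if (sum(history$y) == 0) stop("empty capture history: nothing to summarise")
  det_i <- apply(history$y, 1, sum)
  sites_i <- apply(history$y, 1, function(m) {
    sum(rowSums(matrix(m, nrow = dim(history$y)[2])) > 0)
  })
  recaps <- sort(det_i - 1L, decreasing = TRUE)
  out <- tibble::tibble(
    n_individuals = length(history$individuals),
    total_detections = sum(det_i),
    total_recaptures = sum(det_i - 1L),
    spatial_recaptures = sum(sites_i - 1L),
    effective_trap_nights = sum(history$usage),
    n_sites = length(history$sites),
    n_occasions = history$K,
    survey_start = history$window[["start"]],
    survey_end = history$window[["end"]],
    recaptures = list(recaps)
  )
  structure(out, class = c("scr_survey_summary", class(out)))
}

#' @export
print.scr_survey_summary <- function(x, ...) {
  cat("Survey summary\n")
  cat("  individuals:", x$n_individuals,
      "| recaptures:", x$total_recaptures,
      "(", x$spatial_recaptures, "spatial )\n")
  cat("  sites:", x$n_sites, "| occasions:", x$n_occasions,
      "| effective trap-nights:", x$effective_trap_nights, "\n")
  br <- table(x$recaptures[[1]])
  br <- rev(br)
  cat("  per-individual recaptures:",
      paste(sprintf("%s (%s)", br, names(br)), collapse = "; "), "\n")
  invisible(x)
}
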