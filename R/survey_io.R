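#' Read a trap-deployment table
#'
#' Reads the camera-trap site table: one row per site with planar
#' coordinates in km (a metric projection is assumed upstream; the package
#' never reprojects). A pair of cameras at one location is a single site.
#' Deployment effort is carried either as `active_from`/`active_to` dates
#' (absent or empty values mean "whole survey window") or as an explicit
#' per-day status table supplied via `usage`; sites whose cameras were
#' stolen or destroyed are represented by effort ending at the loss date.
#'
#' @param path CSV with columns `site_id`, `x_km`, `y_km` and optional
#'   `active_from`, `active_to` (ISO-8601).
#' @param usage Optional path to a long-format per-day status CSV with
#'   columns `site_id`, `date`, `active` (0/1); where present it overrides
#'   the date-range columns for the listed site-days.
#' @return A tibble of class `scr_traps` with columns `site_id`, `x_km`,
#'   `y_km`, `active_from`, `active_to`, carrying any per-day table as the
#'   `"usage_table"` attribute. Expand to a J x K matrix with
#'   [build_usage()].
#' @export
read_traps <- function(path, usage = NULL) {
  if (!file.exists(path)) stop("trap file not found: ", path)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(site_id = "c", .default = "c"))
  need <- c("site_id", "x_km", "y_km")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop("trap file lacks required column(s): ", paste(missing, collapse = ", "))
  }
  x <- suppressWarnings(as.numeric(raw$x_km))
  y <- suppressWarnings(as.numeric(raw$y_km))
  bad <- which(!is.finite(x) | !is.finite(y))
  if (length(bad) > 0) {
    stop("non-numeric or non-finite coordinates in trap file, row(s): ",
         paste(bad, collapse = ", "))
  }
  dup <- unique(raw$site_id[duplicated(raw$site_id)])
  if (length(dup) > 0) {
    stop("duplicate site_id in trap file: ", paste(dup, collapse = ", "))
  }
  parse_date_col <- function(nm) {
    if (!nm %in% names(raw)) return(as.Date(rep(NA, nrow(raw))))
    as.Date(dplyr::na_if(trimws(raw[[nm]]), ""))
  }
  traps <- tibble::tibble(
    site_id = raw$site_id, x_km = x, y_km = y,
    active_from = parse_date_col("active_from"),
    active_to = parse_date_col("active_to")
  )
  usage_tbl <- NULL
  if (!is.null(usage)) {
    usage_tbl <- readr::read_csv(usage, show_col_types = FALSE, progress = FALSE,
                                 col_types = readr::cols(site_id = "c",
                                                         date = readr::col_date(),
                                                         active = "i"))
    unknown <- setdiff(unique(usage_tbl$site_id), traps$site_id)
    if (length(unknown) > 0) {
      stop("usage table references unknown site_id: ",
           paste(unknown, collapse = ", "))
    }
  }
  new_scr_traps(traps, usage_tbl)
}

new_scr_traps <- function(traps, usage_tbl = NULL) {
  structure(traps, usage_table = usage_tbl,
            class = c("scr_traps", class(tibble::as_tibble(traps))))
}

#' Coerce a plain data frame of sites to `scr_traps`
#'
#' @param x Data frame with `site_id`, `x_km`, `y_km` and optionally
#'   `active_from`, `active_to`.
#' @param usage_table Optional long per-day status table
#'   (`site_id`, `date`, `active`).
#' @return An `scr_traps` tibble.
#' @export
as_scr_traps <- function(x, usage_table = NULL) {
  x <- tibble::as_tibble(x)
  stopifnot(all(c("site_id", "x_km", "y_km") %in% names(x)))
  if (anyDuplicated(x$site_id)) stop("duplicate site_id")
  if (!all(is.finite(x$x_km)) || !all(is.finite(x$y_km))) {
    stop("trap coordinates must be finite")
  }
  if (!"active_from" %in% names(x)) x$active_from <- as.Date(NA)
  if (!"active_to" %in% names(x)) x$active_to <- as.Date(NA)
  x$site_id <- as.character(x$site_id)
  new_scr_traps(x, usage_table)
}

#' Expand trap deployments to a site-by-occasion usage mask
#'
#' @param traps An `scr_traps` table.
#' @param config An [scr_config()] fixing the survey window.
#' @return Integer J x K matrix, `usage[j, k] = 1` when site j was
#'   operational on occasion k; rownames are site ids.
#' @export
build_usage <- function(traps, config) {
  K <- n_occasions(config)
  days <- seq(config$occasion_start, config$occasion_end, by = "day")
  from <- traps$active_from
  to <- traps$active_to
  from[is.na(from)] <- config$occasion_start
  to[is.na(to)] <- config$occasion_end
  usage <- matrix(0L, nrow = nrow(traps), ncol = K,
                  dimnames = list(traps$site_id, NULL))
  for (j in seq_len(nrow(traps))) {
    usage[j, days >= from[j] & days <= to[j]] <- 1L
  }
  utab <- attr(traps, "usage_table")
  if (!is.null(utab)) {
    k <- occasion_of(utab$date, config)
    keep <- !is.na(k)
    usage[cbind(match(utab$site_id[keep], traps$site_id), k[keep])] <-
      as.integer(utab$active[keep])
  }
  usage
}

#' Write a trap-deployment table
#'
#' Inverse of [read_traps()]: `read_traps(write_traps(x, f))` reproduces
#' `x` exactly, including any per-day usage table (written next to `path`
#' with suffix `_usage.csv`).
#'
#' @param traps An `scr_traps` table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traps <- function(traps, path) {
  readr::write_csv(tibble::as_tibble(traps), path, progress = FALSE)
  utab <- attr(traps, "usage_table")
  if (!is.null(utab)) {
    readr::write_csv(utab, usage_path_for(path), progress = FALSE)
  }
  invisible(path)
}

usage_path_for <- function(path) {
  sub("\\.csv$", "_usage.csv", path)
}

#' Read a detection-record table
#'
#' One row per detection event: an identified (or unidentified) individual
#' at a site on a date, with the photographed flank and age class.
#' Records dated outside the survey window are kept at ingest and filtered
#' when the capture history is built; records with `individual_id`
#' `"unknown"` (or empty) are kept and flagged so the exclusion step can
#' count them.
#'
#' @param path CSV with columns `individual_id`, `site_id`, `date`,
#'   `flank` (`left`/`right`/`both`), `age_class`
#'   (`independent`/`juvenile`/`unknown`) and optional `mother_id`.
#' @param traps Optional `scr_traps`; when given, every `site_id` must
#'   reference a known site.
#' @return A tibble of class `scr_detections` with the columns above plus
#'   logical `unidentified`.
#' @export
read_detections <- function(path, traps = NULL) {
  if (!file.exists(path)) stop("detection file not found: ", path)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  need <- c("individual_id", "site_id", "date", "flank", "age_class")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop("detection file lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!"mother_id" %in% names(raw)) raw$mother_id <- NA_character_
  det <- tibble::tibble(
    individual_id = raw$individual_id,
    site_id = raw$site_id,
    date = as.Date(raw$date),
    flank = raw$flank,
    age_class = raw$age_class,
    mother_id = dplyr::na_if(trimws(raw$mother_id), "")
  )
  as_scr_detections(det, traps)
}

#' Validate and classify detection records
#'
#' @param x Data frame of detection records (columns of
#'   [read_detections()]).
#' @param traps Optional `scr_traps` for site referential checks.
#' @return An `scr_detections` tibble.
#' @export
as_scr_detections <- function(x, traps = NULL) {
  x <- tibble::as_tibble(x)
  stopifnot(all(c("individual_id", "site_id", "date", "flank", "age_class")
                %in% names(x)))
  if (!"mother_id" %in% names(x)) x$mother_id <- NA_character_
  x$date <- as.Date(x$date)
  if (anyNA(x$date)) {
    stop("unparseable date in detection record row(s): ",
         paste(which(is.na(x$date)), collapse = ", "))
  }
  bad_flank <- !x$flank %in% c("left", "right", "both")
  if (any(bad_flank)) {
    stop("invalid flank value in row(s): ",
         paste(which(bad_flank), collapse = ", "))
  }
  bad_age <- !x$age_class %in% c("independent", "juvenile", "unknown")
  if (any(bad_age)) {
    stop("invalid age_class value in row(s): ",
         paste(which(bad_age), collapse = ", "))
  }
  if (!is.null(traps)) {
    unknown <- !x$site_id %in% traps$site_id
    if (any(unknown)) {
      stop("detection row(s) ", paste(which(unknown), collapse = ", "),
           " reference unknown site_id: ",
           paste(unique(x$site_id[unknown]), collapse = ", "))
    }
  }
  x$unidentified <- is.na(x$individual_id) | x$individual_id %in%
    c("", "unknown", "unidentified", "NA")
  x <- x[, c("individual_id", "site_id", "date", "flank", "age_class",
             "mother_id", "unidentified")]
  structure(x, class = c("scr_detections", class(tibble::as_tibble(x))))
}

#' Write a detection-record table
#'
#' @param detections An `scr_detections` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  out <- tibble::as_tibble(detections)
  out$unidentified <- NULL
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
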