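#' Preprocess visibility (visual-range) records
#'
#' Optical visual-range instruments saturate, so measurements are truncated to
#' a maximum distance (default 16.093 km, i.e. 10 miles), and days whose
#' weather flags include heavy fog, dust, or precipitation are removed before
#' annual averaging, since on those days visual range reflects weather rather
#' than particulate haze.
#'
#' @param records A data frame of daily visibility records with columns
#'   `site_id`, `date`, `value` (km) and optionally `flags` (semicolon-joined
#'   strings among `"fog"`, `"dust"`, `"precipitation"`; `NA` or `""` means
#'   no flags).
#' @param cap_km Truncation distance in km; values above it are set to it.
#' @return A tibble with the same columns, flagged rows removed and values
#'   capped; row order of survivors is preserved.
#' @export
preprocess_visibility <- function(records, cap_km = 16.093) {
  if (!is.numeric(cap_km) || length(cap_km) != 1 || is.na(cap_km) || cap_km <= 0) {
    stop_pm("`cap_km` must be a single positive number.", "pm_invalid_parameter")
  }
  check_cols(records, c("site_id", "date", "value"), "visibility records")
  records <- as_tibble(records)
  if (!"flags" %in% names(records)) records$flags <- NA_character_
  bad <- c("fog", "dust", "precipitation")
  flagged <- purrr::map_lgl(
    strsplit(ifelse(is.na(records$flags), "", records$flags), ";", fixed = TRUE),
    function(f) any(trimws(f) %in% bad)
  )
  records |>
    filter(!flagged) |>
    mutate(value = pmin(.data$value, cap_km))
}

# scheduled sampling dates (as day-of-year integers) for one site-year
scheduled_doys <- function(cadence, year, custom_dates = NULL) {
  nd <- days_in_year(year)
  switch(cadence,
    "daily" = seq_len(nd),
    "1-in-3" = seq(1L, nd, by = 3L),
    "1-in-6" = seq(1L, nd, by = 6L),
    "custom" = {
      if (is.null(custom_dates)) {
        stop_pm("custom cadence requires scheduled dates", "pm_invalid_parameter")
      }
      doy <- as.integer(format(as.Date(custom_dates), "%j"))
      sort(unique(doy[doy >= 1 & doy <= nd]))
    },
    stop_pm(paste0("unknown cadence: ", cadence), "pm_invalid_parameter")
  )
}

# longest run of consecutive calendar days with no valid sample, including
# runs at the year's boundaries ("full-year") or interior runs only
max_gap_days <- function(sample_doys, year, gap_mode = c("full-year", "interior")) {
  gap_mode <- match.arg(gap_mode)
  nd <- days_in_year(year)
  sample_doys <- sort(unique(sample_doys))
  if (length(sample_doys) == 0) return(as.integer(nd))
  if (gap_mode == "full-year") {
    bounds <- c(0L, sample_doys, nd + 1L)
  } else {
    bounds <- sample_doys
  }
  max(as.integer(diff(bounds)) - 1L, 0L)
}

#' Annual average with completeness and gap inclusion criteria
#'
#' Aggregates one site's daily records for one year into an annual mean and
#' applies the inclusion rule: at least two-thirds of scheduled sampling dates
#' observed, and fewer than 45 consecutive calendar days without a valid
#' sample (strictly: the longest gap must be at most 44 days). Gaps are
#' counted in calendar days regardless of the sampling cadence; by default
#' the unsampled spans before the first and after the last sample of the
#' year also count as gaps.
#'
#' @param records Data frame of daily records for a single site and year,
#'   columns `site_id`, `date`, `value` (non-negative). May have zero rows.
#' @param year Calendar year being aggregated.
#' @param cadence Sampling cadence: `"daily"`, `"1-in-3"`, `"1-in-6"` or
#'   `"custom"`.
#' @param custom_dates For `cadence = "custom"`, the scheduled dates.
#' @param min_completeness Minimum fraction of scheduled dates with a valid
#'   sample (default 2/3).
#' @param max_gap Largest admissible run of consecutive unsampled calendar
#'   days (default 44, i.e. "< 45").
#' @param gap_mode `"full-year"` counts boundary runs as gaps; `"interior"`
#'   counts only runs between samples.
#' @return A one-row tibble with columns `site_id`, `year`, `value`,
#'   `n_valid`, `n_scheduled`, `max_gap_days`, `included`. With zero valid
#'   records the row is returned with `included = FALSE` and `value = NA`.
#' @export
compute_annual_average <- function(records, year,
                                   cadence = "daily", custom_dates = NULL,
                                   min_completeness = 2 / 3, max_gap = 44L,
                                   gap_mode = c("full-year", "interior")) {
  gap_mode <- match.arg(gap_mode)
  check_cols(records, c("site_id", "date", "value"), "daily records")
  records <- as_tibble(records)
  site <- if (nrow(records) > 0) records$site_id[[1]] else NA_character_
  dates <- as.Date(records$date)
  yr <- as.integer(format(dates, "%Y"))
  if (nrow(records) > 0 && (length(unique(records$site_id)) > 1 || any(yr != year))) {
    stop_pm("records must belong to a single site and the given year",
            "pm_invalid_parameter")
  }
  ok <- !is.na(records$value)
  doys <- as.integer(format(dates[ok], "%j"))
  sched <- scheduled_doys(cadence, year, custom_dates)
  n_valid <- length(intersect(doys, sched))
  gap <- max_gap_days(doys, year, gap_mode)
  included <- n_valid > 0 &&
    n_valid / length(sched) >= min_completeness &&
    gap <= max_gap
  tibble(
    site_id = site, year = as.integer(year),
    value = if (n_valid > 0) mean(records$value[ok]) else NA_real_,
    n_valid = as.integer(n_valid), n_scheduled = length(sched),
    max_gap_days = as.integer(gap), included = included
  )
}

#' QC a table of daily records into annual averages
#'
#' Vectorized wrapper around [compute_annual_average()]: splits a daily table
#' by site and calendar year, looks up each site's sampling cadence, and
#' returns one QC'd row per site-year.
#'
#' @param daily Data frame with columns `site_id`, `date`, `value`.
#' @param schedules Optional data frame `site_id`, `cadence`; sites not
#'   listed default to `"daily"`.
#' @inheritParams compute_annual_average
#' @return A tibble, one row per site-year (see [compute_annual_average()]).
#' @export
qc_annual <- function(daily, schedules = NULL,
                      min_completeness = 2 / 3, max_gap = 44L,
                      gap_mode = c("full-year", "interior")) {
  gap_mode <- match.arg(gap_mode)
  check_cols(daily, c("site_id", "date", "value"), "daily table")
  daily <- as_tibble(daily) |>
    mutate(.year = as.integer(format(as.Date(.data$date), "%Y")))
  cad <- function(s) {
    if (!is.null(schedules) && s %in% schedules$site_id) {
      schedules$cadence[match(s, schedules$site_id)]
    } else "daily"
  }
  daily |>
    dplyr::group_split(.data$site_id, .data$.year) |>
    purrr::map(function(g) {
      compute_annual_average(
        g[setdiff(names(g), ".year")], year = g$.year[[1]],
        cadence = cad(g$site_id[[1]]),
        min_completeness = min_completeness, max_gap = max_gap,
        gap_mode = gap_mode
      )
    }) |>
    dplyr::bind_rows()
}

#' Pass through already-annual observations as QC'd records
#'
#' Proxy networks often publish annual aggregates directly; these bypass the
#' daily inclusion criteria. Provenance fields are left `NA` and `included`
#' is set to `TRUE`.
#'
#' @param annual Data frame with columns `site_id`, `year`, `value`.
#' @return A tibble in the [qc_annual()] schema.
#' @export
annual_passthrough <- function(annual) {
  check_cols(annual, c("site_id", "year", "value"), "annual table")
  as_tibble(annual) |>
    mutate(
      year = as.integer(.data$year),
      n_valid = NA_integer_, n_scheduled = NA_integer_,
      max_gap_days = NA_integer_, included = TRUE
    ) |>
    select("site_id", "year", "value", "n_valid", "n_scheduled",
           "max_gap_days", "included")
}

#' Assign regions to monitoring sites
#'
#' Sites are classified into three broad regions (East, Mountain West, West
#' Coast). An explicit lookup table takes precedence; otherwise longitude
#' thresholds are applied: east of `east_of` is East, west of `west_of` is
#' WestCoast, in between is MountainWest.
#'
#' @param sites Data frame with columns `site_id`, `lon`, `lat`.
#' @param lookup Optional data frame `site_id`, `region`.
#' @param east_of,west_of Longitude thresholds in degrees (defaults -100
#'   and -115).
#' @return `sites` as a tibble with a `region` column filled in.
#' @export
assign_region <- function(sites, lookup = NULL, east_of = -100, west_of = -115) {
  check_cols(sites, c("site_id", "lon", "lat"), "sites table")
  sites <- as_tibble(sites)
  region <- rep(NA_character_, nrow(sites))
  if (!is.null(lookup)) {
    check_cols(lookup, c("site_id", "region"), "region lookup")
    idx <- match(sites$site_id, lookup$site_id)
    region[!is.na(idx)] <- lookup$region[idx[!is.na(idx)]]
  }
  use_thr <- is.na(region)
  if (!is.null(east_of) && !is.null(west_of)) {
    region[use_thr & sites$lon > east_of] <- "East"
    region[use_thr & sites$lon <= west_of] <- "WestCoast"
    region[use_thr & is.na(region)] <- "MountainWest"
  }
  if (anyNA(region)) {
    stop_pm(
      paste0("no region rule matched site(s): ",
             paste(sites$site_id[is.na(region)], collapse = ", ")),
      "pm_unassigned_region"
    )
  }
  sites$region <- region
  sites
}
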