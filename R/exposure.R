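#' Residence-time-weighted long-term average exposure
#'
#' For each person, averages the per-location annual predictions over a
#' multi-year window, weighting each location-year by the exact number of
#' calendar days the person lived there (leap years included). Intervals are
#' clipped to the window; days not covered by any address are excluded from
#' both numerator and denominator, and the covered fraction of the window is
#' reported so callers can filter on completeness.
#'
#' @param residences Data frame `person_id`, `location_id`, `start`, `end`
#'   (dates; `end` exclusive is NOT assumed — both bounds are inclusive
#'   days). A person's intervals must not overlap.
#' @param annual_predictions Data frame `location_id` (or `site_id`), `year`,
#'   and a prediction column `pred_ugm3` (or `predicted`).
#' @param window_start,window_end Window bounds (dates, inclusive).
#' @return A tibble `person_id`, `weighted_avg`, `coverage_fraction`,
#'   `n_addresses`, `moved_flag`.
#' @export
weighted_longterm_average <- function(residences, annual_predictions,
                                      window_start, window_end) {
  check_cols(residences, c("person_id", "location_id", "start", "end"),
             "residence table")
  if ("site_id" %in% names(annual_predictions) &&
      !"location_id" %in% names(annual_predictions)) {
    annual_predictions <- rename(annual_predictions, location_id = "site_id")
  }
  pc <- intersect(c("pred_ugm3", "predicted", "value"),
                  names(annual_predictions))[1]
  check_cols(annual_predictions, c("location_id", "year"), "prediction table")
  if (is.na(pc)) stop_pm("no prediction column found", "pm_schema_error")
  ws <- as.Date(window_start); we <- as.Date(window_end)
  if (ws >= we) stop_pm("window_start must precede window_end",
                        "pm_invalid_parameter")
  res <- as_tibble(residences) |>
    mutate(start = pmax(as.Date(.data$start), ws),
           end = pmin(as.Date(.data$end), we)) |>
    filter(.data$start <= .data$end)
  if (nrow(res) > 0) {
    ovl <- res |> group_by(.data$person_id) |> arrange(.data$start) |>
      summarise(bad = any(diff(as.numeric(.data$start)) <= 0) ||
                  any(utils::head(.data$end, -1) >= utils::tail(.data$start, -1)),
                .groups = "drop")
    if (any(ovl$bad & table(res$person_id)[ovl$person_id] > 1)) {
      stop_pm("overlapping residence intervals for a person",
              "pm_invalid_parameter")
    }
  }
  window_days <- as.numeric(we - ws) + 1
  # split each clipped interval into per-year day counts
  pieces <- res |>
    mutate(y0 = as.integer(format(.data$start, "%Y")),
           y1 = as.integer(format(.data$end, "%Y"))) |>
    purrr::pmap(function(person_id, location_id, start, end, y0, y1, ...) {
      yrs <- y0:y1
      tibble(
        person_id = person_id, location_id = location_id, year = yrs,
        days = purrr::map_dbl(yrs, function(y) {
          a <- max(start, as.Date(sprintf("%d-01-01", y)))
          b <- min(end, as.Date(sprintf("%d-12-31", y)))
          as.numeric(b - a) + 1
        })
      )
    }) |> dplyr::bind_rows()
  if (nrow(pieces) == 0) {
    stop_pm("no residence days fall inside the window", "pm_no_coverage")
  }
  joined <- left_join(pieces,
                      annual_predictions |>
                        select("location_id", "year", pred = dplyr::all_of(pc)),
                      by = c("location_id", "year"))
  if (anyNA(joined$pred)) {
    miss <- joined |> filter(is.na(.data$pred)) |>
      distinct(.data$location_id, .data$year)
    stop_pm(paste0("missing predictions for ", nrow(miss),
                   " location-year(s), e.g. ", miss$location_id[1], "/",
                   miss$year[1]), "pm_schema_error")
  }
  joined |>
    group_by(.data$person_id) |>
    summarise(
      weighted_avg = sum(.data$days * .data$pred) / sum(.data$days),
      coverage_fraction = sum(.data$days) / window_days,
      n_addresses = length(unique(.data$location_id)),
      moved_flag = length(unique(.data$location_id)) > 1,
      .groups = "drop"
    )
}

#' Compare long-term averages with a single reference-year prediction
#'
#' Pearson correlation, the OLS line of the long-term average on the
#' reference-year value, and the paired table (optionally grouped, e.g.
#' movers vs nonmovers).
#'
#' @param longterm Tibble `person_id`, `weighted_avg` (from
#'   [weighted_longterm_average()]); extra columns (e.g. `moved_flag`) are
#'   carried through.
#' @param single_year Tibble `person_id` and a prediction column for the
#'   reference year.
#' @param group Optional column name in `longterm` to group by.
#' @return A list with `paired` (the joined table), `overall`
#'   (`correlation`, `intercept`, `slope`) and, when grouped, `by_group`.
#' @export
compare_periods <- function(longterm, single_year, group = NULL) {
  pc <- intersect(c("pred_ugm3", "predicted", "weighted_avg", "value"),
                  setdiff(names(single_year), "person_id"))[1]
  paired <- inner_join(as_tibble(longterm),
                       single_year |>
                         select("person_id", single_year = dplyr::all_of(pc)),
                       by = "person_id")
  if (nrow(paired) < 3) stop_pm("need 3 or more persons", "pm_invalid_parameter")
  stats_one <- function(d) {
    if (stats::sd(d$weighted_avg) < 1e-12 || stats::sd(d$single_year) < 1e-12) {
      stop_pm("constant exposure vector; correlation undefined",
              "pm_undefined_correlation")
    }
    cl <- calibration_line(d$single_year, d$weighted_avg)
    tibble(n = nrow(d),
           correlation = stats::cor(d$weighted_avg, d$single_year),
           intercept = cl[["intercept"]], slope = cl[["slope"]])
  }
  out <- list(paired = paired, overall = stats_one(paired))
  if (!is.null(group)) {
    out$by_group <- paired |> group_by(.data[[group]]) |>
      dplyr::group_modify(~ stats_one(.x)) |> ungroup()
  }
  out
}
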