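#' MSE-based R-squared
#'
#' `1 - MSE / Var(obs)` with the population variance (mean squared deviation
#' about the observed mean). Unlike a squared correlation it penalizes bias
#' and scale error, and it can be negative when predictions do worse than
#' the observed mean; negative values are preserved (clamp for display with
#' [format_r2()]).
#'
#' @param observed,predicted Aligned numeric vectors.
#' @return A single number, at most 1.
#' @export
mse_r2 <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  if (length(observed) < 2) {
    stop_pm("need at least 2 observations", "pm_invalid_parameter")
  }
  v <- mean((observed - mean(observed))^2)
  if (v <= 0) {
    stop_pm("observed values are constant; R2 undefined", "pm_undefined_r2")
  }
  1 - mean((observed - predicted)^2) / v
}

#' Display formatting for MSE-based R-squared
#'
#' Negative values are clamped to zero, matching how evaluation tables
#' conventionally print a predictor doing worse than the mean.
#' @param r2 Numeric.
#' @param digits Decimal places (default 2).
#' @return Character vector like `"0.00"`.
#' @export
format_r2 <- function(r2, digits = 2) {
  formatC(pmax(r2, 0), format = "f", digits = digits)
}

#' Root mean square error
#' @param observed,predicted Aligned numeric vectors.
#' @return RMSE in the units of the inputs.
#' @export
rmse <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  sqrt(mean((observed - predicted)^2))
}

#' Calibration line: regression of predictions on observations
#'
#' OLS of `predicted` on `observed`. Slopes below 1 indicate predictions
#' attenuated toward their mean.
#'
#' @param observed,predicted Aligned numeric vectors, length 3 or more.
#' @return Named vector `c(intercept, slope)`.
#' @export
calibration_line <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  if (length(observed) < 3) {
    stop_pm("need at least 3 points for a calibration line",
            "pm_invalid_parameter")
  }
  if (stats::sd(observed) < 1e-12) {
    stop_pm("observed values are constant; calibration undefined",
            "pm_collinearity")
  }
  cf <- stats::lm.fit(cbind(1, observed), predicted)$coefficients
  c(intercept = unname(cf[1]), slope = unname(cf[2]))
}

#' Assign sites to cross-validation folds
#'
#' Site-level folds (all of a site's years travel together) so held-out
#' predictions are spatially out-of-sample. Fold sizes differ by at most one,
#' per region when stratified; the assignment is deterministic given the
#' seed.
#'
#' @param sites Site table with `site_id` (and `region` when stratifying).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param stratify_by_region Balance folds within each region.
#' @return A tibble `site_id`, `fold`.
#' @export
make_folds <- function(sites, k = 5, seed = 1, stratify_by_region = FALSE) {
  check_cols(sites, "site_id", "sites table")
  n <- nrow(sites)
  if (k < 2 || k > n) stop_pm("k must be between 2 and the number of sites",
                              "pm_invalid_parameter")
  assign_group <- function(ids, rng_offset) {
    set.seed(seed + rng_offset)
    folds <- rep(seq_len(k), length.out = length(ids))
    tibble(site_id = ids, fold = sample(folds, length(ids)))
  }
  if (stratify_by_region) {
    check_cols(sites, "region", "sites table (stratified folds)")
    regs <- sort(unique(sites$region))
    purrr::imap(regs, function(r, i) {
      assign_group(sort(sites$site_id[sites$region == r]), i)
    }) |> dplyr::bind_rows() |> arrange(.data$site_id)
  } else {
    assign_group(sort(sites$site_id), 0L)
  }
}

# NA-returning variants for stratified tables (small strata are reported,
# not errors; dplyr also probes summarise expressions on empty slices)
safe_r2 <- function(observed, predicted) {
  if (length(observed) < 2 || stats::sd(observed) < 1e-12) return(NA_real_)
  mse_r2(observed, predicted)
}

pred_obs_stats <- function(tbl) {
  tibble(
    n_sites = length(unique(tbl$site_id)),
    n_obs = nrow(tbl),
    r2 = safe_r2(tbl$observed, tbl$predicted),
    rmse = if (nrow(tbl) >= 1) rmse(tbl$observed, tbl$predicted) else NA_real_,
    slope = if (nrow(tbl) >= 3 && stats::sd(tbl$observed) > 1e-12)
      calibration_line(tbl$observed, tbl$predicted)[["slope"]] else NA_real_,
    intercept = if (nrow(tbl) >= 3 && stats::sd(tbl$observed) > 1e-12)
      calibration_line(tbl$observed, tbl$predicted)[["intercept"]] else NA_real_
  )
}

# assemble the full stratified statistic suite from a prediction-observation
# table (concentration scale)
summarise_pred_obs <- function(tbl, min_trend_years = 6) {
  check_cols(tbl, c("site_id", "year", "observed", "predicted"), "pred/obs table")
  overall <- pred_obs_stats(tbl)
  by_year <- tbl |> group_by(.data$year) |>
    dplyr::group_modify(~ pred_obs_stats(.x)) |> ungroup() |>
    arrange(.data$year)
  by_region <- if ("region" %in% names(tbl)) {
    tbl |> group_by(.data$region) |>
      dplyr::group_modify(~ pred_obs_stats(.x)) |> ungroup()
  } else NULL
  site_stats <- tbl |> group_by(.data$site_id) |>
    filter(dplyr::n() > min_trend_years) |>
    summarise(r2 = safe_r2(.data$observed, .data$predicted),
              rmse = if (dplyr::n() >= 1)
                rmse(.data$observed, .data$predicted) else NA_real_,
              .groups = "drop")
  temporal_site_median <- if (nrow(site_stats) > 0) {
    tibble(n_sites = nrow(site_stats),
           r2 = stats::median(site_stats$r2),
           rmse = stats::median(site_stats$rmse))
  } else NULL
  structure(
    list(table = tbl, overall = overall, by_year = by_year,
         by_region = by_region, temporal_site_median = temporal_site_median,
         site_stats = site_stats),
    class = "cv_result"
  )
}

#' Site-based k-fold cross-validation of the full model
#'
#' For each fold the entire pipeline (PLS, mean-field kriging,
#' trend-coefficient regression, residual covariance) is refitted without the
#' held-out sites, and the held-out site-years are predicted with residual
#' kriging driven only by training-site residuals. Statistics are computed on
#' the concentration (µg/m³) scale.
#'
#' @inheritParams fit_st_model
#' @param k Number of folds (default 5).
#' @param seed Seed for fold assignment.
#' @param stratify_by_region Stratify folds by region.
#' @return A `cv_result`: the prediction table plus overall, per-year,
#'   per-region and per-site-median statistics.
#' @export
cross_validate <- function(annual, sites, covariates, trend,
                           fit_years = 1999:2010, k = 5, seed = 1,
                           k_pls = 2, min_trend_years = 6,
                           stratify_by_region = FALSE) {
  annual <- as_tibble(annual)
  if ("included" %in% names(annual)) annual <- filter(annual, .data$included)
  annual <- filter(annual, .data$year %in% fit_years)
  fit_sites <- filter(as_tibble(sites), .data$site_id %in% annual$site_id)
  folds <- make_folds(fit_sites, k = k, seed = seed,
                      stratify_by_region = stratify_by_region)
  out <- purrr::map(sort(unique(folds$fold)), function(fd) {
    held <- folds$site_id[folds$fold == fd]
    train_annual <- filter(annual, !(.data$site_id %in% held))
    model <- tryCatch(
      fit_st_model(train_annual, sites, covariates, trend,
                   fit_years = fit_years, k_pls = k_pls,
                   min_trend_years = min_trend_years),
      error = function(e) {
        stop_pm(paste0("fold ", fd, " could not be fitted: ",
                       conditionMessage(e)), "pm_fold_failure")
      }
    )
    held_locs <- filter(fit_sites, .data$site_id %in% held)
    preds <- predict(model, held_locs, covariates, fit_years)
    obs <- filter(annual, .data$site_id %in% held) |>
      select("site_id", "year", observed = "value")
    inner_join(obs, preds, by = c("site_id", "year")) |>
      mutate(fold = fd, predicted = .data$pred_ugm3)
  }) |> dplyr::bind_rows()
  if ("region" %in% names(fit_sites)) {
    out <- left_join(out,
                     select(fit_sites, "site_id", "region"), by = "site_id")
  }
  summarise_pred_obs(
    select(out, "site_id", "year", dplyr::any_of("region"),
           "observed", "predicted", "fold"),
    min_trend_years = min_trend_years
  )
}

#' Validate a fitted model against an external network
#'
#' Predicts at the external sites and years from the already-fitted model
#' (no refitting) and computes the same statistic suite. External years may
#' precede the fitting period; such years get no residual-kriging component.
#'
#' @param model A fitted `st_model`.
#' @param external_annual QC'd annual table for the external network.
#' @param external_sites Site table for the external network.
#' @param covariates Covariate table covering the external sites.
#' @return A `cv_result`-shaped report.
#' @export
external_validate <- function(model, external_annual, external_sites,
                              covariates) {
  external_annual <- as_tibble(external_annual)
  if ("included" %in% names(external_annual)) {
    external_annual <- filter(external_annual, .data$included)
  }
  yrs <- sort(unique(external_annual$year))
  preds <- predict(model, as_tibble(external_sites), covariates, yrs)
  obs <- select(external_annual, "site_id", "year", observed = "value")
  tbl <- inner_join(obs, preds, by = c("site_id", "year")) |>
    mutate(predicted = .data$pred_ugm3)
  if ("region" %in% names(external_sites)) {
    tbl <- left_join(tbl, select(as_tibble(external_sites),
                                 "site_id", "region"), by = "site_id")
  }
  summarise_pred_obs(
    select(tbl, "site_id", "year", dplyr::any_of("region"),
           "observed", "predicted"),
    min_trend_years = model$min_trend_years
  )
}

#' Spread of predictions across trend approaches
#'
#' Given per-approach prediction tables over the same site-years, computes
#' the per-row max minus min prediction and the per-year median spread — a
#' measure of how much the historical back-extension strategy matters.
#'
#' @param predictions_by_approach Named list of tibbles with `site_id`,
#'   `year`, and a prediction column (`pred_ugm3` or `predicted`).
#' @return A list with `per_row` (site-year spreads) and `per_year` (median
#'   spread by year).
#' @export
trend_spread <- function(predictions_by_approach) {
  if (length(predictions_by_approach) < 2) {
    stop_pm("need at least 2 approaches", "pm_invalid_parameter")
  }
  tbls <- purrr::imap(predictions_by_approach, function(tb, nm) {
    pc <- intersect(c("pred_ugm3", "predicted"), names(tb))[1]
    if (is.na(pc)) stop_pm("no prediction column found", "pm_schema_error")
    tibble(site_id = tb$site_id, year = tb$year,
           approach = nm, pred = tb[[pc]])
  })
  n0 <- nrow(tbls[[1]])
  wide <- dplyr::bind_rows(tbls) |>
    tidyr::pivot_wider(names_from = "approach", values_from = "pred")
  if (nrow(wide) != n0 || anyNA(wide)) {
    stop_pm("approaches do not cover the same site-years", "pm_alignment_error")
  }
  vals <- as.matrix(wide[, setdiff(names(wide), c("site_id", "year"))])
  per_row <- wide |> select("site_id", "year") |>
    mutate(spread = apply(vals, 1, max) - apply(vals, 1, min))
  list(per_row = per_row,
       per_year = per_row |> group_by(.data$year) |>
         summarise(median_spread = stats::median(.data$spread),
                   .groups = "drop"))
}

#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) {
  dplyr::bind_rows(
    x$overall |> mutate(stratum = "overall"),
    x$by_year |> mutate(stratum = paste0("year:", .data$year)) |>
      select(-"year"),
    if (!is.null(x$by_region))
      x$by_region |> mutate(stratum = paste0("region:", .data$region)) |>
        select(-"region")
  ) |> select("stratum", dplyr::everything())
}

#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  out <- x$overall
  if (!is.null(x$temporal_site_median)) {
    out$site_median_r2 <- x$temporal_site_median$r2
    out$site_median_rmse <- x$temporal_site_median$rmse
  }
  out
}

#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "grey40",
                         linetype = 2) +
    ggplot2::labs(
      x = expression(paste("Observed annual average (", mu, "g/", m^3, ")")),
      y = expression(paste("Predicted annual average (", mu, "g/", m^3, ")")),
      title = sprintf("MSE-based R² = %.2f, RMSE = %.2f",
                      object$overall$r2, object$overall$rmse)
    ) +
    ggplot2::theme_minimal()
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Prediction evaluation:", x$overall$n_obs, "site-years at",
      x$overall$n_sites, "sites\n")
  cat(sprintf("  R2 %s, RMSE %.2f, calibration slope %.2f\n",
              format_r2(x$overall$r2), x$overall$rmse, x$overall$slope))
  invisible(x)
}
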