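#' Per-site regression of log annual averages on the trend basis
#'
#' For one site, ordinary least squares of the log annual values on
#' `[1, f(t)]` gives the site's long-term mean (intercept) and trend
#' coefficient (slope).
#'
#' @param y Numeric log annual values.
#' @param f Trend-basis values at the same years.
#' @return Named vector `c(mu_hat, beta_hat)`.
#' @export
site_trend_regression <- function(y, f) {
  if (length(y) != length(f)) {
    stop_pm("y and f must have equal length", "pm_invalid_parameter")
  }
  if (stats::sd(f) < 1e-12) {
    stop_pm("trend basis is constant over the observed years", "pm_collinearity")
  }
  cf <- stats::lm.fit(cbind(1, f), y)$coefficients
  c(mu_hat = unname(cf[1]), beta_hat = unname(cf[2]))
}

#' Fit the full spatio-temporal model
#'
#' Staged estimation on log annual averages over the fitting years:
#' \enumerate{
#'   \item site-level OLS of log values on the trend basis at sites with more
#'     than `min_trend_years` observed years, giving per-site long-term means
#'     and trend coefficients;
#'   \item PLS on the geographic covariates against the long-term means
#'     (`k_pls` components, default 2);
#'   \item universal kriging of the long-term mean field on the PLS scores
#'     (exponential covariance, ML);
#'   \item OLS of the trend coefficients on the same PLS scores, with iid
#'     residual variance only (no spatial structure for the trend
#'     coefficient: zero range and partial sill in the primary
#'     configuration);
#'   \item spatio-temporal residuals at every included site-year (ineligible
#'     sites use their kriged mean and regression trend coefficient), fitted
#'     with one shared exponential covariance across years (simple kriging,
#'     temporal independence).
#' }
#'
#' @param annual QC'd annual table (`site_id`, `year`, `value` in µg/m³,
#'   `included`).
#' @param sites Site table (`site_id`, `lon`, `lat`, optionally `region`).
#' @param covariates Pruned covariate table (`site_id` + variables).
#' @param trend A `trend_basis` tibble covering at least the fitting years.
#' @param fit_years Years used for fitting (default 1999:2010).
#' @param k_pls Number of PLS components (default 2).
#' @param min_trend_years Eligibility: sites need more than this many observed
#'   years (default 6 of a 12-year span).
#' @param method Likelihood flavour for the mean field, `"ml"` or `"reml"`.
#' @param beta_spatial If `TRUE`, also fit an exponential covariance for the
#'   trend-coefficient field (sensitivity analysis; default `FALSE`).
#' @return An object of class `st_model`.
#' @export
fit_st_model <- function(annual, sites, covariates, trend,
                         fit_years = 1999:2010, k_pls = 2,
                         min_trend_years = 6, method = "ml",
                         beta_spatial = FALSE) {
  check_cols(annual, c("site_id", "year", "value"), "annual table")
  check_cols(sites, c("site_id", "lon", "lat"), "sites table")
  annual <- as_tibble(annual)
  if ("included" %in% names(annual)) annual <- filter(annual, .data$included)
  annual <- filter(annual, .data$year %in% fit_years, !is.na(.data$value))
  if (any(annual$value <= 0)) {
    stop_pm("annual values must be strictly positive (log is taken here)",
            "pm_invalid_parameter")
  }
  annual <- annual |>
    mutate(logv = log(.data$value),
           f = trend_values(trend, .data$year)) |>
    arrange(.data$site_id, .data$year)
  sites <- as_tibble(sites) |> arrange(.data$site_id)

  # stage 1: site regressions at eligible sites
  site_fits <- annual |>
    group_by(.data$site_id) |>
    summarise(n_years = dplyr::n(),
              mu_hat = if (dplyr::n() > min_trend_years)
                site_trend_regression(.data$logv, .data$f)[["mu_hat"]] else NA_real_,
              beta_hat = if (dplyr::n() > min_trend_years)
                site_trend_regression(.data$logv, .data$f)[["beta_hat"]] else NA_real_,
              .groups = "drop")
  eligible <- filter(site_fits, !is.na(.data$mu_hat))
  if (nrow(eligible) < 10) {
    stop_pm("fewer than 10 sites eligible for trend regression (stage 1)",
            "pm_insufficient_data")
  }
  el_sites <- inner_join(eligible, sites, by = "site_id") |>
    arrange(.data$site_id)

  # stage 2: PLS against the long-term means
  pls <- fit_pls(covariate_matrix(covariates, el_sites$site_id),
                 el_sites$mu_hat, k = k_pls)
  sc <- project_pls(pls, covariates, el_sites$site_id)
  score_cols <- paste0("pls", seq_len(k_pls))
  X <- cbind(1, as.matrix(sc[, score_cols]))
  colnames(X) <- c("(Intercept)", score_cols)

  # stage 3: universal kriging of the long-term mean field
  coords <- cbind(el_sites$lon, el_sites$lat)
  mean_model <- fit_universal_kriging(el_sites$mu_hat, X, coords,
                                      method = method)

  # stage 4: trend-coefficient regression (nugget-only by default)
  if (beta_spatial) {
    trend_model <- fit_universal_kriging(el_sites$beta_hat, X, coords,
                                         method = method)
    gamma <- trend_model$alpha
    gamma_se <- trend_model$alpha_se
    beta_var <- trend_model$cov$nugget
    beta_fit <- trend_model
  } else {
    bf <- stats::lm(el_sites$beta_hat ~ X - 1)
    gamma <- unname(coef(bf))
    gamma_se <- unname(sqrt(diag(stats::vcov(bf))))
    beta_var <- mean(stats::residuals(bf)^2)
    beta_fit <- NULL
  }

  # stage 5: residuals at all included site-years, then residual covariance.
  # eligible sites use their own stage-1 estimates; other sites use the
  # kriged mean and the regression trend coefficient
  all_ids <- sort(unique(annual$site_id))
  other_ids <- setdiff(all_ids, eligible$site_id)
  mu_map <- setNames(el_sites$mu_hat, el_sites$site_id)
  beta_map <- setNames(el_sites$beta_hat, el_sites$site_id)
  if (length(other_ids) > 0) {
    os <- filter(sites, .data$site_id %in% other_ids) |> arrange(.data$site_id)
    osc <- project_pls(pls, covariates, os$site_id)
    oX <- cbind(1, as.matrix(osc[, score_cols]))
    mu_o <- predict_universal_kriging(mean_model, oX, cbind(os$lon, os$lat))$pred
    beta_o <- drop(oX %*% gamma)
    mu_map <- c(mu_map, setNames(mu_o, os$site_id))
    beta_map <- c(beta_map, setNames(beta_o, os$site_id))
  }
  resid_tbl <- annual |>
    mutate(resid = .data$logv - mu_map[.data$site_id] -
             beta_map[.data$site_id] * .data$f) |>
    select("site_id", "year", "resid")
  residual_model <- fit_residual_model(resid_tbl, sites)

  structure(
    list(pls = pls, trend = trend, mean_model = mean_model,
         gamma = gamma, gamma_se = gamma_se, beta_var = beta_var,
         beta_fit = beta_fit, residual_model = residual_model,
         site_table = el_sites |>
           select("site_id", "lon", "lat", "n_years", "mu_hat", "beta_hat"),
         fit_years = fit_years, k_pls = k_pls,
         min_trend_years = min_trend_years,
         score_cols = score_cols, beta_spatial = beta_spatial),
    class = "st_model"
  )
}

#' Predict annual-average concentrations at new locations
#'
#' Combines the three model components on the log scale and exponentiates:
#' `yhat(s, t) = exp(mu(s) + beta(s) f(t) + e(s, t))`, where `mu` comes from
#' the universal-kriging mean field, `beta` from the trend-coefficient
#' regression on projected PLS scores, and `e` is the simple-kriging
#' interpolation of that year's fitted residuals — zero for years with no
#' fitting data (all pre-fitting history).
#'
#' @param object A fitted `st_model`.
#' @param locations Data frame `site_id` (or `location_id`), `lon`, `lat`.
#' @param covariates Covariate table covering the locations.
#' @param years Integer years to predict (within the trend basis).
#' @param residual_krige Include the kriged residual component for years with
#'   fitting data (default `TRUE`).
#' @param ... Unused.
#' @return A tibble `site_id`, `year`, `pred_log`, `resid_component`,
#'   `pred_ugm3`.
#' @export
predict.st_model <- function(object, locations, covariates, years,
                             residual_krige = TRUE, ...) {
  if ("location_id" %in% names(locations) && !"site_id" %in% names(locations)) {
    locations <- rename(locations, site_id = "location_id")
  }
  check_cols(locations, c("site_id", "lon", "lat"), "locations table")
  years <- as.integer(years)
  trend_f <- trend_values(object$trend, years)  # errors if out of range
  locations <- as_tibble(locations)
  sc <- project_pls(object$pls, covariates, locations$site_id)
  X <- cbind(1, as.matrix(sc[, object$score_cols]))
  coords <- cbind(locations$lon, locations$lat)
  mu <- predict_universal_kriging(object$mean_model, X, coords)$pred
  beta <- if (object$beta_spatial) {
    predict_universal_kriging(object$beta_fit, X, coords)$pred
  } else {
    drop(X %*% object$gamma)
  }
  out <- tidyr::expand_grid(i = seq_len(nrow(locations)), j = seq_along(years))
  eps <- matrix(0, nrow(locations), length(years))
  if (residual_krige) {
    for (j in seq_along(years)) {
      eps[, j] <- krige_residuals(object$residual_model, years[j], coords)
    }
  }
  tibble(
    site_id = locations$site_id[out$i],
    year = years[out$j],
    pred_log = mu[out$i] + beta[out$i] * trend_f[out$j] + eps[cbind(out$i, out$j)],
    resid_component = eps[cbind(out$i, out$j)]
  ) |>
    mutate(pred_ugm3 = exp(.data$pred_log)) |>
    arrange(.data$site_id, .data$year)
}

#' @method tidy st_model
#' @export
tidy.st_model <- function(x, ...) {
  dplyr::bind_rows(
    tidy(x$mean_model) |> mutate(component = "mean_field"),
    tibble(term = paste0("gamma", seq_along(x$gamma) - 1),
           estimate = x$gamma, std.error = x$gamma_se,
           component = "trend_coefficient")
  ) |> select("component", "term", "estimate", "std.error")
}

#' @method glance st_model
#' @export
glance.st_model <- function(x, ...) {
  tibble(
    n_sites = nrow(x$site_table),
    n_years = length(x$fit_years),
    k_pls = x$k_pls,
    mean_range_km = x$mean_model$cov$range_km,
    mean_partial_sill = x$mean_model$cov$partial_sill,
    mean_nugget = x$mean_model$cov$nugget,
    beta_var = x$beta_var,
    resid_range_km = x$residual_model$cov$range_km,
    resid_partial_sill = x$residual_model$cov$partial_sill,
    resid_nugget = x$residual_model$cov$nugget
  )
}

#' @export
print.st_model <- function(x, ...) {
  cat("Spatio-temporal annual-average model\n")
  cat("  fitting years:", min(x$fit_years), "-", max(x$fit_years),
      " sites:", nrow(x$site_table), "\n")
  cat(sprintf("  mean field: range %.0f km, psill %.4g, nugget %.4g\n",
              x$mean_model$cov$range_km, x$mean_model$cov$partial_sill,
              x$mean_model$cov$nugget))
  cat(sprintf("  residuals:  range %.0f km, psill %.4g, nugget %.4g\n",
              x$residual_model$cov$range_km, x$residual_model$cov$partial_sill,
              x$residual_model$cov$nugget))
  invisible(x)
}
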