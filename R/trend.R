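#' Build a site-by-year matrix of log annual averages
#'
#' @param annual QC'd annual table (`site_id`, `year`, `value`, `included`);
#'   only `included` rows with positive values are used.
#' @param years Year range to span (columns); defaults to the observed range.
#' @param min_years Minimum number of non-missing years for a site row to be
#'   eligible for trend estimation. The default keeps sites with more than
#'   half the span observed, matching the "more than 6 of 12 possible years"
#'   rule for a 12-year fitting period.
#' @param log_scale Take logs of `value` (default TRUE).
#' @return A numeric matrix (rownames site ids, colnames years) with
#'   attribute `years`; ineligible rows are dropped.
#' @export
site_year_matrix <- function(annual, years = NULL, min_years = NULL,
                             log_scale = TRUE) {
  check_cols(annual, c("site_id", "year", "value"), "annual table")
  annual <- as_tibble(annual)
  if ("included" %in% names(annual)) annual <- filter(annual, .data$included)
  annual <- filter(annual, !is.na(.data$value))
  if (log_scale) {
    if (any(annual$value <= 0)) {
      stop_pm("log scale requires strictly positive annual values",
              "pm_invalid_parameter")
    }
    annual$value <- log(annual$value)
  }
  years <- years %||% seq(min(annual$year), max(annual$year))
  min_years <- min_years %||% floor(length(years) / 2)
  annual <- filter(annual, .data$year %in% years)
  wide <- tidyr::pivot_wider(
    annual |> select("site_id", "year", "value") |>
      arrange(.data$site_id, .data$year),
    names_from = "year", values_from = "value"
  )
  m <- matrix(NA_real_, nrow(wide), length(years),
              dimnames = list(wide$site_id, years))
  for (y in intersect(names(wide), as.character(years))) m[, y] <- wide[[y]]
  keep <- rowSums(!is.na(m)) > min_years
  m <- m[keep, , drop = FALSE]
  attr(m, "years") <- as.integer(years)
  m
}

#' Estimate the temporal trend by SVD of an incomplete site-year matrix
#'
#' Each site's series is centered on its own mean; missing cells are imputed
#' iteratively by alternating a rank-1 SVD reconstruction with re-imputation
#' until the largest imputed-cell change falls below `tol`. The returned
#' trend is the first right singular vector scaled by its singular value
#' divided by sqrt(number of sites), so it carries the scale of a typical
#' site's centered series; its sign is fixed so the first year is at least
#' as high as the last (the convention for a falling pollutant).
#'
#' @param m Site-by-year matrix from [site_year_matrix()] (missing entries
#'   allowed; every year must be observed at one or more sites).
#' @param max_iter,tol Iteration controls for the imputation loop.
#' @return Numeric trend vector named by year, with attributes `converged`
#'   and `iterations`.
#' @export
estimate_trend_svd <- function(m, max_iter = 200L, tol = 1e-8) {
  if (nrow(m) < 2) stop_pm("need at least 2 eligible sites", "pm_invalid_parameter")
  empty_years <- colnames(m)[colSums(!is.na(m)) == 0]
  if (length(empty_years) > 0) {
    stop_pm(paste0("year(s) with no observations: ",
                   paste(empty_years, collapse = ", ")), "pm_unestimable_year")
  }
  mc <- m - rowMeans(m, na.rm = TRUE)
  if (all(abs(mc) < 1e-14, na.rm = TRUE)) {
    warn("no temporal signal after row-centering; returning zero trend")
    f <- setNames(rep(0, ncol(m)), colnames(m))
    attr(f, "converged") <- TRUE
    attr(f, "iterations") <- 0L
    return(f)
  }
  miss <- is.na(mc)
  x <- mc
  x[miss] <- 0
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    s <- svd(x, nu = 1, nv = 1)
    recon <- s$d[1] * tcrossprod(s$u[, 1], s$v[, 1])
    delta <- if (any(miss)) max(abs(recon[miss] - x[miss])) else 0
    x[miss] <- recon[miss]
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warn(sprintf("trend imputation did not converge in %d iterations", max_iter))
  }
  s <- svd(x, nu = 1, nv = 1)
  f <- s$d[1] * s$v[, 1] / sqrt(nrow(m))
  if (f[1] < f[length(f)]) f <- -f
  f <- setNames(f, colnames(m))
  attr(f, "converged") <- converged
  attr(f, "iterations") <- it
  f
}

trend_basis_tibble <- function(years, f, source, a = NA_real_, b = NA_real_) {
  out <- tibble(year = as.integer(years), f = as.numeric(f),
                source = source, calib_intercept = a, calib_slope = b)
  class(out) <- c("trend_basis", class(out))
  out
}

#' Extend a fitted trend backwards by linear extrapolation
#'
#' Fits an ordinary least-squares line of the trend on calendar year over the
#' fitted span and evaluates it at the target (historical) years. The fitted
#' span keeps its estimated values; only the target years get the line.
#'
#' @param fitted_trend Named numeric vector (names are years), e.g. from
#'   [estimate_trend_svd()].
#' @param target_years Years to extrapolate to (default 1980–1998).
#' @return A `trend_basis` tibble covering target plus fitted years, with
#'   `source = "pm25_extrapolated"`.
#' @export
extend_trend_linear <- function(fitted_trend, target_years = 1980:1998) {
  yrs <- as.integer(names(fitted_trend))
  if (length(yrs) < 3) {
    stop_pm("need at least 3 fitted years to extrapolate", "pm_insufficient_data")
  }
  fit <- stats::lm.fit(cbind(1, yrs), as.numeric(fitted_trend))
  pre <- fit$coefficients[1] + fit$coefficients[2] * target_years
  trend_basis_tibble(
    c(target_years, yrs), c(pre, as.numeric(fitted_trend)),
    "pm25_extrapolated"
  ) |> arrange(.data$year)
}

#' Extend a fitted trend backwards with a proxy network
#'
#' Estimates the proxy network's own temporal trend by [estimate_trend_svd()],
#' calibrates it to the primary trend by OLS over the overlap years
#' (`primary = a + b * proxy`), fills historical years covered by the proxy
#' with the calibrated proxy trend, and linearly extrapolates the calibrated
#' proxy line for years before the proxy starts. Over the primary years the
#' primary trend is kept unchanged.
#'
#' @param fitted_trend Named numeric primary trend (e.g. over 1999–2010).
#' @param proxy_matrix Site-by-year matrix for the proxy network (e.g. log
#'   sulfate or log truncated visual range), from [site_year_matrix()]; or an
#'   already-estimated proxy trend as a year-named numeric vector.
#' @param target_years Historical years to cover (default 1980–1998).
#' @param source Label: `"sulfate_proxy"` or `"visibility_proxy"`.
#' @param ... Passed to [estimate_trend_svd()] for the proxy fit.
#' @return A `trend_basis` tibble over target plus primary years with the
#'   calibration recorded in `calib_intercept` / `calib_slope`.
#' @export
extend_trend_proxy <- function(fitted_trend, proxy_matrix,
                               target_years = 1980:1998,
                               source = "sulfate_proxy", ...) {
  primary_years <- as.integer(names(fitted_trend))
  g <- if (is.matrix(proxy_matrix)) {
    estimate_trend_svd(proxy_matrix, ...)
  } else {
    proxy_matrix
  }
  proxy_years <- as.integer(names(g))
  overlap <- intersect(primary_years, proxy_years)
  if (length(overlap) < 3) {
    stop_pm("proxy and primary trends overlap in fewer than 3 years",
            "pm_insufficient_overlap")
  }
  fo <- as.numeric(fitted_trend[as.character(overlap)])
  go <- as.numeric(g[as.character(overlap)])
  if (stats::sd(go) < 1e-12) {
    stop_pm("proxy trend is constant over the overlap; calibration degenerate",
            "pm_degenerate_calibration")
  }
  cf <- stats::lm.fit(cbind(1, go), fo)$coefficients
  a <- unname(cf[1]); b <- unname(cf[2])
  if (abs(b) < 1e-12) {
    stop_pm("calibration slope is zero; proxy carries no signal",
            "pm_degenerate_calibration")
  }
  calibrated <- a + b * as.numeric(g)
  hist_years <- setdiff(target_years, primary_years)
  covered <- intersect(hist_years, proxy_years)
  before <- setdiff(hist_years, proxy_years)
  f_hist <- setNames(rep(NA_real_, length(hist_years)), hist_years)
  f_hist[as.character(covered)] <- calibrated[match(covered, proxy_years)]
  if (length(before) > 0) {
    # pre-proxy years: line fitted to the full calibrated proxy span
    lf <- stats::lm.fit(cbind(1, proxy_years), calibrated)$coefficients
    f_hist[as.character(before)] <- lf[1] + lf[2] * before
  }
  trend_basis_tibble(
    c(hist_years, primary_years),
    c(as.numeric(f_hist), as.numeric(fitted_trend)),
    source, a, b
  ) |> arrange(.data$year)
}

#' Look up trend-basis values for given years
#' @param trend A `trend_basis` tibble.
#' @param years Integer years.
#' @return Numeric vector of f values.
#' @export
trend_values <- function(trend, years) {
  idx <- match(as.integer(years), trend$year)
  if (anyNA(idx)) {
    stop_pm(paste0("year(s) outside the trend basis: ",
                   paste(years[is.na(idx)], collapse = ", ")),
            "pm_out_of_range")
  }
  trend$f[idx]
}

#' @method autoplot trend_basis
#' @export
autoplot.trend_basis <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$year, y = .data$f)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Year", y = "Trend basis f(t)",
                  title = paste("Temporal trend basis:", object$source[[1]])) +
    ggplot2::theme_minimal()
}
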