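#' Default configuration for the synthetic monitoring world
#'
#' The generated world mimics the data situation the model is built for: a
#' dense primary PM2.5 network observed only in the final 12 years of a
#' 31-year window, a smaller historical PM2.5 network reserved for external
#' validation, and two sparse proxy networks (a sulfate-like series starting
#' partway back and a visibility-like series covering the whole window)
#' whose log annual values are affine in the true trend. Log concentrations
#' follow the model's own decomposition: a long-term mean field linear in
#' two latent spatial factors plus an exponential-covariance Gaussian
#' process, a trend coefficient field linear in the same factors, a single
#' decreasing piecewise-linear trend (steeper before 2000), and
#' spatially-correlated temporally-independent annual residuals.
#'
#' @param ... Overrides for any top-level entry.
#' @return A named list of generator settings.
#' @export
world_config <- function(...) {
  cfg <- list(
    years = 1980:2010,
    n_primary = 400, primary_years = 1999:2010,
    n_hist = 70, hist_years = 1990:1998,
    n_extra = 50,
    n_proxy_a = 100, proxy_a_years = 1987:2010,
    n_proxy_b = 150, proxy_b_years = 1980:2010,
    bbox = c(lon_min = -124, lon_max = -68, lat_min = 26, lat_max = 48),
    p_covariates = 50, covariate_noise_sd = 0.5,
    factor_range_km = 800,
    mu = list(intercept = 2.5, f1 = 0.35, f2 = 0.2,
              range_km = 300, partial_sill = 0.04, nugget = 0.01),
    beta = list(intercept = 1, f1 = 0.12, f2 = 0.08, sd = 0.05),
    resid = list(range_km = 200, partial_sill = 0.006, nugget = 0.003),
    trend = list(shape = "piecewise", f_start = 0.9, f_mid = -0.1,
                 f_end = -0.35, knot = 2000),
    proxy_a = list(slope_mean = 0.8, slope_sd = 0.1,
                   intercept_mean = 0.7, intercept_sd = 0.3, noise_sd = 0.03),
    proxy_b = list(slope_mean = -0.6, slope_sd = 0.08,
                   intercept_mean = 2.2, intercept_sd = 0.2, noise_sd = 0.03),
    noise_scale = 1,
    daily_sites = 0, daily_cadence = "1-in-3"
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) {
    stop_pm(paste0("unknown world config key(s): ", paste(bad, collapse = ", ")),
            "pm_invalid_parameter")
  }
  utils::modifyList(cfg, over)
}

# one draw of a zero-mean GP with exponential covariance at given coords
draw_gp <- function(coords, params, n_draws = 1) {
  S <- exp_cov(dist_km_matrix(coords), params)
  R <- safe_chol(S)
  if (is.null(R)) stop_pm("GP covariance not positive definite", "pm_fit_error")
  z <- matrix(rnorm(nrow(coords) * n_draws), nrow(coords), n_draws)
  crossprod(R, z)
}

true_trend <- function(cfg) {
  yrs <- cfg$years
  tr <- cfg$trend
  if (tr$shape == "linear") {
    f <- tr$f_start + (tr$f_end - tr$f_start) *
      (yrs - min(yrs)) / (max(yrs) - min(yrs))
  } else {
    f <- ifelse(
      yrs <= tr$knot,
      tr$f_start + (tr$f_mid - tr$f_start) * (yrs - min(yrs)) / (tr$knot - min(yrs)),
      tr$f_mid + (tr$f_end - tr$f_mid) * (yrs - tr$knot) / (max(yrs) - tr$knot)
    )
  }
  setNames(f, yrs)
}

#' Generate a synthetic monitoring world
#'
#' See [world_config()] for the structure being emulated and the defaults.
#' Regeneration with the same seed and config is bit-identical, and the
#' generating truth (fields, trend, covariance parameters, noise draws) is
#' retained so recovery tests can compare estimates against it.
#'
#' @param config From [world_config()].
#' @param seed Integer seed.
#' @return An object of class `pm_world`: `sites`, `covariates`, `annual`
#'   (primary + historical networks, µg/m³), `proxy_a_annual`,
#'   `proxy_b_annual`, optional `daily`, and `truth`.
#' @export
generate_world <- function(config = world_config(), seed = 20160624) {
  cfg <- config
  set.seed(seed %% .Machine$integer.max)
  yrs <- cfg$years
  f_star <- true_trend(cfg)

  n_pm <- cfg$n_primary + cfg$n_hist + cfg$n_extra
  mk_sites <- function(n, prefix) {
    tibble(
      site_id = sprintf("%s%04d", prefix, seq_len(n)),
      lon = runif(n, cfg$bbox[["lon_min"]], cfg$bbox[["lon_max"]]),
      lat = runif(n, cfg$bbox[["lat_min"]], cfg$bbox[["lat_max"]])
    )
  }
  pm_sites <- dplyr::bind_rows(
    mk_sites(cfg$n_primary, "P") |> mutate(network = "primary"),
    mk_sites(cfg$n_hist, "H") |> mutate(network = "historical"),
    mk_sites(cfg$n_extra, "X") |> mutate(network = "extra")
  ) |> assign_region()
  coords <- cbind(pm_sites$lon, pm_sites$lat)

  # two latent spatial factors drive both the covariates and the fields
  fac <- draw_gp(coords, cov_params(cfg$factor_range_km, 1, 1e-6), 2)
  loadings <- matrix(rnorm(2 * cfg$p_covariates), 2, cfg$p_covariates)
  covar_noise <- matrix(rnorm(n_pm * cfg$p_covariates, sd = cfg$covariate_noise_sd),
                        n_pm, cfg$p_covariates)
  covm <- fac %*% loadings + covar_noise
  colnames(covm) <- sprintf("gv%03d", seq_len(cfg$p_covariates))
  covariates <- dplyr::bind_cols(tibble(site_id = pm_sites$site_id),
                                 as_tibble(covm))

  mu_gp <- drop(draw_gp(coords, cov_params(cfg$mu$range_km, cfg$mu$partial_sill,
                                           cfg$mu$nugget)))
  mu_reg <- cfg$mu$intercept + cfg$mu$f1 * fac[, 1] + cfg$mu$f2 * fac[, 2]
  mu_star <- mu_reg + mu_gp
  beta_star <- cfg$beta$intercept + cfg$beta$f1 * fac[, 1] +
    cfg$beta$f2 * fac[, 2] + rnorm(n_pm, sd = cfg$beta$sd)

  # annual residual field: one shared Cholesky, independent draws per year
  obs_years <- sort(unique(c(cfg$primary_years, cfg$hist_years)))
  Rres <- safe_chol(exp_cov(dist_km_matrix(coords),
                            cov_params(cfg$resid$range_km,
                                       cfg$resid$partial_sill,
                                       cfg$resid$nugget)))
  resid_draws <- crossprod(Rres, matrix(rnorm(n_pm * length(obs_years)),
                                        n_pm, length(obs_years)))
  colnames(resid_draws) <- obs_years

  obs_tbl <- function(ids, years, network) {
    tidyr::expand_grid(site_id = ids, year = years) |>
      mutate(
        i = match(.data$site_id, pm_sites$site_id),
        signal = mu_star[.data$i] + beta_star[.data$i] * f_star[as.character(.data$year)],
        noise = resid_draws[cbind(.data$i, match(.data$year, obs_years))],
        value = unname(exp(.data$signal + cfg$noise_scale * .data$noise)),
        network = network, included = TRUE
      ) |> select("site_id", "year", "value", "network", "included")
  }
  annual <- dplyr::bind_rows(
    obs_tbl(pm_sites$site_id[pm_sites$network == "primary"],
            cfg$primary_years, "primary"),
    obs_tbl(pm_sites$site_id[pm_sites$network == "historical"],
            cfg$hist_years, "historical")
  )

  mk_proxy <- function(n, prefix, pyears, pcfg) {
    ps <- mk_sites(n, prefix) |> assign_region()
    slope <- rnorm(n, pcfg$slope_mean, pcfg$slope_sd)
    icpt <- rnorm(n, pcfg$intercept_mean, pcfg$intercept_sd)
    tab <- tidyr::expand_grid(site_id = ps$site_id, year = pyears) |>
      mutate(
        i = match(.data$site_id, ps$site_id),
        logv = unname(icpt[.data$i] + slope[.data$i] *
                        f_star[as.character(.data$year)] +
                        rnorm(dplyr::n(), sd = pcfg$noise_sd)),
        value = exp(.data$logv), included = TRUE
      ) |> select("site_id", "year", "value", "included")
    list(sites = ps, annual = tab)
  }
  pa <- mk_proxy(cfg$n_proxy_a, "A", cfg$proxy_a_years, cfg$proxy_a)
  pb <- mk_proxy(cfg$n_proxy_b, "B", cfg$proxy_b_years, cfg$proxy_b)

  daily <- NULL
  if (cfg$daily_sites > 0) {
    dsites <- utils::head(pm_sites$site_id[pm_sites$network == "primary"],
                          cfg$daily_sites)
    daily <- annual |>
      filter(.data$site_id %in% dsites) |>
      purrr::pmap(function(site_id, year, value, ...) {
        doys <- scheduled_doys(cfg$daily_cadence, year)
        tibble(site_id = site_id,
               date = as.Date(sprintf("%d-01-01", year)) + doys - 1,
               value = value)
      }) |> dplyr::bind_rows()
  }

  structure(
    list(
      config = cfg, seed = seed,
      sites = pm_sites,
      covariates = covariates,
      annual = annual,
      proxy_a_sites = pa$sites, proxy_a_annual = pa$annual,
      proxy_b_sites = pb$sites, proxy_b_annual = pb$annual,
      daily = daily,
      truth = list(
        f_star = f_star,
        mu_star = setNames(mu_star, pm_sites$site_id),
        mu_reg = setNames(mu_reg, pm_sites$site_id),
        beta_star = setNames(beta_star, pm_sites$site_id),
        beta_reg = setNames(cfg$beta$intercept + cfg$beta$f1 * fac[, 1] +
                              cfg$beta$f2 * fac[, 2], pm_sites$site_id),
        factors = fac,
        mu_cov = cfg$mu[c("range_km", "partial_sill", "nugget")],
        resid_cov = cfg$resid,
        noise = resid_draws
      ),
      degradations = list()
    ),
    class = "pm_world"
  )
}

#' Degrade a synthetic world
#'
#' Returns a modified copy with the generating truth unchanged and the
#' degradation recorded. Operations:
#' \describe{
#'   \item{drop-sites}{`params = list(network, n)` — keep a seeded random
#'     subset of `n` sites of that network.}
#'   \item{drop-years}{`params = list(network, years_keep)`.}
#'   \item{add-gap}{`params = list(site_id, year, gap_days, start_doy)` —
#'     remove a block of consecutive days from the daily table (requires a
#'     world generated with `daily_sites > 0`).}
#'   \item{inflate-noise}{`params = list(factor)` — observation noise is
#'     multiplied by `1 + factor` (so `factor = 0` is the identity),
#'     recomputed exactly from the stored noise draws.}
#' }
#'
#' @param world A `pm_world`.
#' @param operation One of the operations above.
#' @param params Operation parameters.
#' @param seed Seed for the random subset in `drop-sites`.
#' @return The degraded `pm_world`.
#' @export
degrade_world <- function(world, operation, params = list(), seed = 1) {
  stopifnot(inherits(world, "pm_world"))
  w <- world
  if (operation == "drop-sites") {
    net <- params$network %||% "historical"
    ids <- w$sites$site_id[w$sites$network == net]
    if (is.null(params$n) || params$n < 1 || params$n > length(ids)) {
      stop_pm("drop-sites needs 1 <= n <= network size", "pm_invalid_parameter")
    }
    set.seed(seed)
    keep <- sort(sample(ids, params$n))
    drop <- setdiff(ids, keep)
    w$sites <- filter(w$sites, !(.data$site_id %in% drop))
    w$annual <- filter(w$annual, !(.data$site_id %in% drop))
    w$covariates <- filter(w$covariates, !(.data$site_id %in% drop))
  } else if (operation == "drop-years") {
    net <- params$network %||% "historical"
    ids <- w$sites$site_id[w$sites$network == net]
    w$annual <- filter(w$annual, !(.data$site_id %in% ids) |
                         .data$year %in% params$years_keep)
  } else if (operation == "add-gap") {
    if (is.null(w$daily)) {
      stop_pm("add-gap requires a world generated with daily_sites > 0",
              "pm_invalid_parameter")
    }
    start <- params$start_doy %||% 100L
    span <- start + seq_len(params$gap_days %||% 45L) - 1L
    gap_dates <- as.Date(sprintf("%d-01-01", params$year)) + span - 1
    w$daily <- filter(w$daily, !(.data$site_id == params$site_id &
                                   .data$date %in% gap_dates))
  } else if (operation == "inflate-noise") {
    mult <- 1 + (params$factor %||% 0)
    idx <- match(w$annual$site_id, names(w$truth$mu_star))
    f_star <- w$truth$f_star
    signal <- w$truth$mu_star[idx] +
      w$truth$beta_star[idx] * f_star[as.character(w$annual$year)]
    noise <- w$truth$noise[cbind(idx, match(w$annual$year,
                                            as.integer(colnames(w$truth$noise))))]
    w$annual$value <- unname(exp(signal + w$config$noise_scale * mult * noise))
  } else {
    stop_pm(paste0("unknown degrade operation: ", operation),
            "pm_invalid_parameter")
  }
  if (nrow(w$annual) == 0) stop_pm("degradation removed all data", "pm_empty_world")
  w$degradations <- c(world$degradations,
                      list(list(operation = operation, params = params,
                                seed = seed)))
  w
}

#' Generate synthetic residence histories over a world's extra locations
#'
#' Roughly a third of the cohort moves once at a uniformly drawn date; the
#' rest stay at one address for the whole window. Addresses are drawn from
#' the world's `extra` (unmonitored) locations.
#'
#' @param world A `pm_world`.
#' @param n_people Cohort size.
#' @param window_start,window_end Window bounds (dates).
#' @param move_prob Probability of one move (default 1/3).
#' @param seed Seed.
#' @return A tibble `person_id`, `location_id`, `lon`, `lat`, `start`, `end`.
#' @export
generate_residences <- function(world, n_people = 200,
                                window_start = "1980-01-01",
                                window_end = "2000-12-31",
                                move_prob = 1 / 3, seed = 1) {
  set.seed(seed)
  locs <- filter(world$sites, .data$network == "extra")
  ws <- as.Date(window_start); we <- as.Date(window_end)
  purrr::map(seq_len(n_people), function(i) {
    pid <- sprintf("person%04d", i)
    if (runif(1) < move_prob) {
      ids <- sample(locs$site_id, 2)
      cut <- ws + floor(runif(1, 200, as.numeric(we - ws) - 200))
      tibble(person_id = pid, location_id = ids,
             start = c(ws, cut + 1), end = c(cut, we))
    } else {
      tibble(person_id = pid, location_id = sample(locs$site_id, 1),
             start = ws, end = we)
    }
  }) |>
    dplyr::bind_rows() |>
    left_join(select(locs, "site_id", "lon", "lat"),
              by = c("location_id" = "site_id"))
}

#' @export
print.pm_world <- function(x, ...) {
  cat("Synthetic monitoring world (seed", x$seed, ")\n")
  cat("  PM sites:", sum(x$sites$network == "primary"), "primary /",
      sum(x$sites$network == "historical"), "historical /",
      sum(x$sites$network == "extra"), "extra\n")
  cat("  proxies:", nrow(x$proxy_a_sites), "sulfate-like,",
      nrow(x$proxy_b_sites), "visibility-like\n")
  if (length(x$degradations) > 0) {
    cat("  degradations:",
        paste(purrr::map_chr(x$degradations, "operation"), collapse = ", "), "\n")
  }
  invisible(x)
}
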