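#' Great-circle distance in kilometres
#'
#' Haversine distance with earth radius 6371.0088 km.
#'
#' @param a,b Length-2 numeric vectors `c(lon, lat)` in degrees, or two-column
#'   matrices of coordinates.
#' @return Distance(s) in km.
#' @export
great_circle_km <- function(a, b) {
  geosphere::distHaversine(a, b, r = 6371.0088)
}

# full pairwise distance matrix (km) between two coordinate sets
dist_km_matrix <- function(coords_a, coords_b = NULL) {
  coords_a <- as.matrix(coords_a)
  if (is.null(coords_b)) coords_b <- coords_a
  geosphere::distm(coords_a, as.matrix(coords_b),
                   fun = function(p1, p2) {
                     geosphere::distHaversine(p1, p2, r = 6371.0088)
                   })
}

#' Exponential spatial covariance
#'
#' `C(h) = partial_sill * exp(-h / range_km) + nugget * 1{h == 0}`.
#'
#' @param h Distances in km (vector or matrix).
#' @param params Named list or vector with `range_km`, `partial_sill`,
#'   `nugget`.
#' @return Covariances with the shape of `h`.
#' @export
exp_cov <- function(h, params) {
  p <- as.list(params)
  out <- p$partial_sill * exp(-h / p$range_km)
  out[h == 0] <- out[h == 0] + p$nugget
  out
}

cov_params <- function(range_km, partial_sill, nugget) {
  if (range_km <= 0 || partial_sill < 0 || nugget < 0) {
    stop_pm("covariance parameters out of bounds", "pm_invalid_parameter")
  }
  list(range_km = range_km, partial_sill = partial_sill, nugget = nugget)
}

# negative log-likelihood machinery -------------------------------------

# Cholesky with jitter escalation; returns NULL when hopeless
safe_chol <- function(S) {
  for (jit in c(0, 1e-10, 1e-8, 1e-6)) {
    R <- tryCatch(chol(S + diag(jit * mean(diag(S)), nrow(S))),
                  error = function(e) NULL)
    if (!is.null(R)) return(R)
  }
  NULL
}

# Gaussian negative log-likelihood with GLS-profiled regression coefficients.
# X = NULL means a known zero mean (simple-kriging residual model).
# reml adds the standard restricted-likelihood determinant term.
nll_gauss <- function(theta, y, X, D, reml = FALSE) {
  params <- list(range_km = exp(theta[1]), partial_sill = exp(theta[2]),
                 nugget = exp(theta[3]))
  S <- exp_cov(D, params)
  R <- safe_chol(S)
  if (is.null(R)) return(1e10)
  logdet <- 2 * sum(log(diag(R)))
  if (is.null(X)) {
    z <- backsolve(R, y, transpose = TRUE)
    q <- sum(z^2)
    0.5 * (logdet + q + length(y) * log(2 * pi))
  } else {
    Rz <- backsolve(R, cbind(y, X), transpose = TRUE)
    zy <- Rz[, 1]
    ZX <- Rz[, -1, drop = FALSE]
    XtSiX <- crossprod(ZX)
    alpha <- tryCatch(solve(XtSiX, crossprod(ZX, zy)), error = function(e) NULL)
    if (is.null(alpha)) return(1e10)
    r <- zy - ZX %*% alpha
    val <- 0.5 * (logdet + sum(r^2) + length(y) * log(2 * pi))
    if (reml) val <- val + 0.5 * determinant(XtSiX, logarithm = TRUE)$modulus
    as.numeric(val)
  }
}

# deterministic multistart grid on (log range, log psill, log nugget)
multistarts <- function(D, vy, n_starts = 3L, seed = 1L) {
  dmax <- max(D[D > 0])
  base <- rbind(
    c(log(dmax / 4), log(vy * 0.6), log(vy * 0.4)),
    c(log(dmax / 10), log(vy * 0.9), log(vy * 0.1)),
    c(log(dmax / 2), log(vy * 0.3), log(vy * 0.7))
  )
  base[seq_len(min(n_starts, nrow(base))), , drop = FALSE]
}

optimise_cov <- function(y, X, D, init = NULL, reml = FALSE, n_starts = 3L) {
  vy <- stats::var(as.numeric(y))
  if (vy <= 0) vy <- 1e-6
  starts <- multistarts(D, vy, n_starts)
  if (!is.null(init)) {
    starts <- rbind(log(c(init$range_km, max(init$partial_sill, 1e-8),
                          max(init$nugget, 1e-8))), starts)
  }
  dmax <- max(D[D > 0])
  lower <- c(log(dmax * 1e-4), log(vy * 1e-8), log(vy * 1e-8))
  upper <- c(log(dmax * 100), log(vy * 1e3), log(vy * 1e3))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(pmin(pmax(starts[i, ], lower), upper), nll_gauss,
                   y = y, X = X, D = D, reml = reml,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 300)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-9 ||
        (abs(fit$value - best$value) <= 1e-9 && fit$par[1] < best$par[1])) {
      best <- fit
    }
  }
  if (is.null(best)) {
    stop_pm("covariance optimisation failed from every start", "pm_fit_error")
  }
  list(
    params = canonicalise_cov(
      cov_params(exp(best$par[1]), exp(best$par[2]), exp(best$par[3])), D),
    loglik = -best$value,
    converged = best$convergence == 0
  )
}

# a range far below the smallest inter-site distance makes the spatial
# component observationally equivalent to extra nugget; report it as such
canonicalise_cov <- function(params, D) {
  dmin <- min(D[D > 0])
  if (params$range_km < dmin / 20) {
    params$nugget <- params$nugget + params$partial_sill
    params$partial_sill <- 0
  }
  params
}

#' Fit a universal-kriging model by maximum likelihood
#'
#' Models `values ~ Normal(design %*% alpha, Sigma)` where `Sigma` is the
#' exponential covariance of [exp_cov()] on great-circle distances. The
#' covariance parameters are optimised on the log scale with the regression
#' coefficients profiled out by generalised least squares; three deterministic
#' multistarts guard against local optima (ties broken by likelihood, then
#' smaller range).
#'
#' @param values Numeric response per site.
#' @param design Numeric design matrix (per-site rows; include the intercept
#'   column).
#' @param coords Two-column matrix or data frame of `lon`, `lat`.
#' @param init Optional starting `CovarianceParams` (list with `range_km`,
#'   `partial_sill`, `nugget`).
#' @param method `"ml"` (default) or `"reml"`.
#' @return An object of class `uk_fit`: `alpha`, `alpha_se`, `cov` (the
#'   covariance parameters), `loglik`, `converged`, `method`, plus the
#'   training `values`, `design`, `coords` needed for prediction.
#' @export
fit_universal_kriging <- function(values, design, coords, init = NULL,
                                  method = c("ml", "reml")) {
  method <- match.arg(method)
  design <- as.matrix(design)
  coords <- as.matrix(coords)
  if (qr(design)$rank < ncol(design)) {
    stop_pm("design matrix is rank deficient", "pm_rank_deficiency")
  }
  D <- dist_km_matrix(coords)
  opt <- optimise_cov(values, design, D, init = init, reml = method == "reml")
  S <- exp_cov(D, opt$params)
  R <- safe_chol(S)
  if (is.null(R)) stop_pm("covariance matrix is singular at the optimum", "pm_fit_error")
  Rz <- backsolve(R, cbind(values, design), transpose = TRUE)
  XtSiX <- crossprod(Rz[, -1, drop = FALSE])
  alpha <- solve(XtSiX, crossprod(Rz[, -1, drop = FALSE], Rz[, 1]))
  structure(
    list(alpha = drop(alpha), alpha_se = sqrt(diag(solve(XtSiX))),
         cov = opt$params, loglik = opt$loglik, converged = opt$converged,
         method = method, values = as.numeric(values), design = design,
         coords = coords),
    class = "uk_fit"
  )
}

#' Predict from a universal-kriging fit
#'
#' Standard universal-kriging predictor
#' `x0' alpha + c0' Sigma^{-1} (y - X alpha)` with its prediction variance
#' `C(0) - c0' Sigma^{-1} c0 + d' (X' Sigma^{-1} X)^{-1} d`,
#' `d = x0 - X' Sigma^{-1} c0`. With a zero nugget the predictor interpolates
#' the data exactly at fitted sites.
#'
#' @param model A `uk_fit` (or a list with the same fields and fixed
#'   parameters, for oracle checks).
#' @param new_design Design rows for the prediction locations.
#' @param new_coords `lon`, `lat` rows for the prediction locations.
#' @return A tibble with `pred` and `pred_var` per location.
#' @export
predict_universal_kriging <- function(model, new_design, new_coords) {
  new_design <- as.matrix(new_design)
  new_coords <- as.matrix(new_coords)
  if (ncol(new_design) != length(model$alpha)) {
    stop_pm("new design width does not match coefficient length", "pm_schema_error")
  }
  D <- dist_km_matrix(model$coords)
  S <- exp_cov(D, model$cov)
  R <- safe_chol(S)
  if (is.null(R)) stop_pm("training covariance is singular", "pm_fit_error")
  X <- model$design
  y <- model$values
  # cross-covariances carry no nugget: distance zero to a monitoring site
  # means co-located, not the same measurement error
  D0 <- dist_km_matrix(new_coords, model$coords)
  C0 <- model$cov$partial_sill * exp(-D0 / model$cov$range_km)
  Si_y <- backsolve(R, backsolve(R, y - X %*% model$alpha, transpose = TRUE))
  pred <- drop(new_design %*% model$alpha + C0 %*% Si_y)
  RzX <- backsolve(R, X, transpose = TRUE)
  XtSiX_inv <- solve(crossprod(RzX))
  Zc <- backsolve(R, t(C0), transpose = TRUE)   # n_train x n_new
  c_quad <- colSums(Zc^2)
  dvec <- t(new_design) - crossprod(RzX, Zc)
  d_quad <- colSums(dvec * (XtSiX_inv %*% dvec))
  pv <- pmax(model$cov$partial_sill + model$cov$nugget - c_quad + d_quad, 0)
  tibble(pred = pred, pred_var = pv)
}

#' Fit the shared residual covariance across years
#'
#' Annual spatial residuals are modelled as independent replicates of a
#' zero-mean Gaussian field with one shared exponential covariance; the
#' parameters maximise the sum over years of the per-year log-likelihoods
#' (simple kriging, pooled estimation).
#'
#' @param residuals Data frame with columns `site_id`, `year`, `resid`.
#' @param sites Data frame with `site_id`, `lon`, `lat`.
#' @param init Optional starting parameters.
#' @return An object of class `resid_fit`: `cov`, `loglik`, `converged`,
#'   plus the per-year residual tables used for kriging at prediction time.
#' @export
fit_residual_model <- function(residuals, sites, init = NULL) {
  check_cols(residuals, c("site_id", "year", "resid"), "residual table")
  check_cols(sites, c("site_id", "lon", "lat"), "sites table")
  res <- as_tibble(residuals) |>
    inner_join(select(as_tibble(sites), "site_id", "lon", "lat"), by = "site_id")
  years <- split(res, res$year)
  years <- years[purrr::map_int(years, nrow) >= 2]
  if (length(years) < 1) stop_pm("no year has 2+ residuals", "pm_invalid_parameter")
  # years sharing one site set share a covariance matrix: factor it once
  keys <- purrr::map_chr(years, ~ paste(.x$site_id, collapse = "|"))
  groups <- purrr::map(unique(keys), function(k) {
    yrs <- years[keys == k]
    list(D = dist_km_matrix(cbind(yrs[[1]]$lon, yrs[[1]]$lat)),
         Y = do.call(cbind, purrr::map(yrs, "resid")))
  })
  total_nll <- function(theta) {
    params <- list(range_km = exp(theta[1]), partial_sill = exp(theta[2]),
                   nugget = exp(theta[3]))
    val <- 0
    for (g in groups) {
      R <- safe_chol(exp_cov(g$D, params))
      if (is.null(R)) return(1e10)
      Z <- backsolve(R, g$Y, transpose = TRUE)
      val <- val + ncol(g$Y) * (2 * sum(log(diag(R))) +
                                  nrow(g$Y) * log(2 * pi)) / 2 +
        sum(Z^2) / 2
    }
    val
  }
  ys <- purrr::map(years, "resid")
  vy <- stats::var(unlist(ys))
  if (vy <= 0) vy <- 1e-6
  Dall <- groups[[which.max(purrr::map_int(groups, ~ nrow(.x$D)))]]$D
  starts <- multistarts(Dall, vy)
  if (!is.null(init)) {
    starts <- rbind(log(c(init$range_km, max(init$partial_sill, 1e-8),
                          max(init$nugget, 1e-8))), starts)
  }
  dmax <- max(Dall[Dall > 0])
  lower <- c(log(dmax * 1e-4), log(vy * 1e-8), log(vy * 1e-8))
  upper <- c(log(dmax * 100), log(vy * 1e3), log(vy * 1e3))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(pmin(pmax(starts[i, ], lower), upper), total_nll,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 300)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-9 ||
        (abs(fit$value - best$value) <= 1e-9 && fit$par[1] < best$par[1])) {
      best <- fit
    }
  }
  if (is.null(best)) stop_pm("residual covariance fit failed", "pm_fit_error")
  structure(
    list(cov = canonicalise_cov(
           cov_params(exp(best$par[1]), exp(best$par[2]), exp(best$par[3])),
           Dall),
         loglik = -best$value, converged = best$convergence == 0,
         residuals = res),
    class = "resid_fit"
  )
}

# simple-kriging interpolation of one year's residuals at new coordinates;
# returns zeros when the year has no residual data
krige_residuals <- function(resid_fit, year, new_coords) {
  new_coords <- as.matrix(new_coords)
  ry <- filter(resid_fit$residuals, .data$year == !!year)
  if (nrow(ry) == 0) return(rep(0, nrow(new_coords)))
  coords <- cbind(ry$lon, ry$lat)
  S <- exp_cov(dist_km_matrix(coords), resid_fit$cov)
  R <- safe_chol(S)
  if (is.null(R)) return(rep(0, nrow(new_coords)))
  D0 <- dist_km_matrix(new_coords, coords)
  C0 <- resid_fit$cov$partial_sill * exp(-D0 / resid_fit$cov$range_km)
  drop(C0 %*% backsolve(R, backsolve(R, ry$resid, transpose = TRUE)))
}

#' @method tidy uk_fit
#' @export
tidy.uk_fit <- function(x, ...) {
  tibble(term = paste0("alpha", seq_along(x$alpha) - 1),
         estimate = unname(x$alpha), std.error = unname(x$alpha_se))
}

#' @method glance uk_fit
#' @export
glance.uk_fit <- function(x, ...) {
  tibble(range_km = x$cov$range_km, partial_sill = x$cov$partial_sill,
         nugget = x$cov$nugget, logLik = x$loglik, converged = x$converged,
         n = length(x$values), method = x$method)
}

#' @method glance resid_fit
#' @export
glance.resid_fit <- function(x, ...) {
  tibble(range_km = x$cov$range_km, partial_sill = x$cov$partial_sill,
         nugget = x$cov$nugget, logLik = x$loglik, converged = x$converged,
         n_obs = nrow(x$residuals), n_years = length(unique(x$residuals$year)))
}

#' @export
print.uk_fit <- function(x, ...) {
  cat("Universal kriging fit (", x$method, "), n = ", length(x$values), "\n",
      sep = "")
  cat(sprintf("  range %.1f km, partial sill %.4g, nugget %.4g, logLik %.2f\n",
              x$cov$range_km, x$cov$partial_sill, x$cov$nugget, x$loglik))
  invisible(x)
}
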