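test_that("MSE-based R2 matches its defining examples", {
  obs <- c(1, 2, 3)
  expect_equal(mse_r2(obs, obs), 1.0)
  expect_equal(mse_r2(obs, rep(mean(obs), 3)), 0.0)
  expect_equal(mse_r2(obs, c(1, 2, 4)), 0.5)  # 1 - (1/3)/(2/3)
  expect_error(mse_r2(rep(2, 4), 1:4), class = "pm_undefined_r2")
  # worse-than-mean predictions go negative internally, clamp only on display
  r2 <- mse_r2(obs, c(5, -2, 9))
  expect_lt(r2, 0)
  expect_equal(format_r2(r2), "0.00")
})

test_that("RMSE matches closed-form cases", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(1, 2, 3), c(2, 3, 4)), 1)      # constant offset
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2)) # 3.5355...
})

test_that("calibration line regresses predictions on observations", {
  obs <- c(1, 3, 5, 7)
  expect_equal(calibration_line(obs, obs), c(intercept = 0, slope = 1))
  expect_equal(calibration_line(obs, 0.5 * obs + 2),
               c(intercept = 2, slope = 0.5))
  # shrinkage toward the mean attenuates the slope below 1
  set.seed(31)
  o <- rnorm(100, 10, 3)
  p <- mean(o) + 0.4 * (o - mean(o)) + rnorm(100, sd = 0.5)
  expect_lt(calibration_line(o, p)[["slope"]], 1)
  expect_error(calibration_line(rep(1, 5), rnorm(5)), class = "pm_collinearity")
})

test_that("folds are balanced, site-level and deterministic", {
  sites <- tibble::tibble(site_id = sprintf("S%02d", 1:10))
  f <- make_folds(sites, k = 5, seed = 7)
  expect_equal(sort(as.vector(table(f$fold))), rep(2L, 5))
  sites11 <- tibble::tibble(site_id = sprintf("S%02d", 1:11))
  f11 <- make_folds(sites11, k = 5, seed = 7)
  expect_equal(sort(as.vector(table(f11$fold))), c(2L, 2L, 2L, 2L, 3L))
  expect_identical(make_folds(sites11, k = 5, seed = 7), f11)
  expect_error(make_folds(sites, k = 11), class = "pm_invalid_parameter")
  # region stratification balances within region
  sites$region <- rep(c("East", "WestCoast"), each = 5)
  fs <- make_folds(sites, k = 5, seed = 1, stratify_by_region = TRUE)
  per <- table(merge(fs, sites)$region, merge(fs, sites)$fold)
  expect_true(all(per == 1))
})

test_that("overall MSE is the observation-weighted mean of per-year MSEs", {
  set.seed(33)
  tbl <- tibble::tibble(
    site_id = rep(sprintf("S%02d", 1:20), each = 6),
    year = rep(2000:2005, 20),
    observed = exp(rnorm(120, 2, 0.4)),
    predicted = exp(rnorm(120, 2, 0.4))
  )
  res <- pmhindcast:::summarise_pred_obs(tbl)
  mse_overall <- res$overall$rmse^2
  wmean <- sum(res$by_year$n_obs * res$by_year$rmse^2) / sum(res$by_year$n_obs)
  expect_equal(mse_overall, wmean, tolerance = 1e-12)
  # statistics are invariant to row order
  res2 <- pmhindcast:::summarise_pred_obs(tbl[sample(nrow(tbl)), ])
  expect_equal(res$overall, res2$overall)
})

test_that("cross-validation behaves sensibly in the noiseless limit", {
  w <- small_world()
  cfg <- w$config
  # noiseless limit: shrink every unpredictable component, not just the
  # observation noise — the mean-field nugget and the trend-coefficient
  # scatter are spatially unpredictable by construction
  cfg$noise_scale <- 0.02
  cfg$mu$partial_sill <- 1e-5
  cfg$mu$nugget <- 1e-5
  cfg$beta$sd <- 0.002
  cfg$covariate_noise_sd <- 0.02
  w0 <- generate_world(cfg, seed = 42)
  primary <- dplyr::filter(w0$annual, network == "primary")
  trend <- build_trend_basis(primary, "pm25")
  cv <- cross_validate(primary, w0$sites, w0$covariates, trend, k = 5,
                       seed = 1)
  expect_gte(cv$overall$r2, 0.99)
  # destroying the prediction-observation pairing kills the skill
  shuffled <- cv$table
  set.seed(2)
  shuffled$predicted <- 2 * mean(shuffled$observed) -
    sample(shuffled$predicted)
  expect_lte(mse_r2(shuffled$observed, shuffled$predicted), 0.1)
  # fold bookkeeping: every site appears in exactly one fold
  per_site <- tapply(cv$table$fold, cv$table$site_id,
                     function(x) length(unique(x)))
  expect_true(all(per_site == 1))
})

test_that("leave-one-site-out equals k = n_sites cross-validation", {
  w <- small_world()
  cfg <- w$config
  cfg$n_primary <- 12
  cfg$n_hist <- 0
  cfg$n_proxy_a <- 0
  cfg$n_proxy_b <- 0
  w12 <- generate_world(cfg, seed = 9)
  primary <- dplyr::filter(w12$annual, network == "primary")
  trend <- pmhindcast:::trend_basis_tibble(1980:2010, w12$truth$f_star, "pm25_extrapolated")
  cv_k <- cross_validate(primary, w12$sites, w12$covariates, trend, k = 12,
                         seed = 3, min_trend_years = 6)
  # with k = number of sites each fold holds out exactly one site
  expect_equal(sort(as.vector(table(cv_k$table$fold))), rep(12L, 12))
  expect_equal(length(unique(paste(cv_k$table$site_id, cv_k$table$fold))), 12)
})

test_that("external validation of training data with its own model is honest", {
  w <- small_world()
  primary <- dplyr::filter(w$annual, network == "primary")
  trend <- build_trend_basis(primary, "pm25")
  m <- fit_st_model(primary, w$sites, w$covariates, trend)
  ev <- external_validate(m, primary, dplyr::filter(w$sites,
                                                    network == "primary"),
                          w$covariates)
  # residual kriging interpolates the training years almost exactly
  expect_gte(ev$overall$r2, 0.95)
  # single-site external sets suppress site-level medians but keep overall
  one <- dplyr::filter(w$annual, network == "historical",
                       site_id == w$annual$site_id[w$annual$network ==
                                                     "historical"][1])
  ev1 <- external_validate(m, one,
                           dplyr::filter(w$sites, network == "historical"),
                           w$covariates)
  expect_true(is.numeric(ev1$overall$r2))
})

test_that("trend spread is zero for identical approaches and exact for shifts", {
  p1 <- tibble::tibble(site_id = rep("A", 3), year = 2000:2002,
                       pred_ugm3 = c(10, 11, 12))
  p2 <- dplyr::mutate(p1, pred_ugm3 = pred_ugm3 + 2)
  same <- trend_spread(list(a = p1, b = p1))
  expect_true(all(same$per_row$spread == 0))
  shifted <- trend_spread(list(a = p1, b = p2))
  expect_true(all(shifted$per_row$spread == 2))
  expect_error(trend_spread(list(a = p1, b = p2[1:2, ])),
               class = "pm_alignment_error")
})
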