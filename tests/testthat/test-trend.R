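# rank-1 site-year matrix a_s + b_s * g(t)
rank1_matrix <- function(g, n_sites = 12, seed = 1, b_min = 0.5, b_max = 1.5) {
  set.seed(seed)
  a <- rnorm(n_sites)
  b <- runif(n_sites, b_min, b_max)
  m <- outer(a, rep(1, length(g))) + outer(b, g)
  dimnames(m) <- list(sprintf("S%02d", 1:n_sites), names(g))
  m
}

years_12 <- setNames(1999:2010, 1999:2010)

test_that("SVD trend recovers an exact rank-1 temporal pattern", {
  g <- setNames(2 - 0.1 * (1999:2010 - 1999) + sin(1:12), 1999:2010)
  m <- rank1_matrix(g)
  f <- estimate_trend_svd(m)
  expect_equal(abs(cor(as.numeric(f), as.numeric(g))), 1, tolerance = 1e-10)
})

test_that("SVD trend survives missing cells and noise", {
  g <- setNames(seq(1, -0.5, length.out = 12) + 0.2 * cos(1:12), 1999:2010)
  m <- rank1_matrix(g, n_sites = 30, seed = 2)
  set.seed(3)
  m <- m + matrix(rnorm(length(m), sd = 0.01), nrow(m))
  holes <- sample(length(m), round(0.2 * length(m)))
  # keep every year observed somewhere
  m2 <- m
  m2[holes] <- NA
  m2 <- m2[, colSums(!is.na(m2)) > 0, drop = FALSE]
  f <- estimate_trend_svd(m2)
  expect_gte(abs(cor(as.numeric(f), g[colnames(m2)])), 0.99)
})

test_that("identical rows give a degenerate zero trend with a warning", {
  m <- rank1_matrix(setNames(rep(1, 12), 1999:2010), b_min = 0, b_max = 0)
  expect_warning(f <- estimate_trend_svd(m), "no temporal signal")
  expect_equal(unname(as.numeric(f)), rep(0, 12))
})

test_that("trend estimation ignores site-specific level shifts", {
  g <- setNames(seq(0.8, -0.4, length.out = 12), 1999:2010)
  m <- rank1_matrix(g, n_sites = 15, seed = 4)
  m2 <- m + rnorm(nrow(m), sd = 5)  # add a constant to each row
  expect_equal(as.numeric(estimate_trend_svd(m)),
               as.numeric(estimate_trend_svd(m2)), tolerance = 1e-8)
})

test_that("linear extension evaluates the fitted line at historical years", {
  f <- setNames(2 - 0.1 * (1999:2010 - 1999), 1999:2010)
  tb <- extend_trend_linear(f, 1980:1998)
  expect_equal(tb$f[tb$year == 1980], 2 - 0.1 * (1980 - 1999))  # 3.9
  expect_equal(tb$f[tb$year == 1980], 3.9)
  # fitted span kept as estimated
  expect_equal(tb$f[tb$year %in% 1999:2010], unname(f))
  # constant trend extrapolates flat
  fc <- setNames(rep(1.3, 12), 1999:2010)
  expect_equal(extend_trend_linear(fc)$f, rep(1.3, 31), tolerance = 1e-12)
  expect_error(extend_trend_linear(f[1:2]), class = "pm_insufficient_data")
})

test_that("proxy calibration inverts a constructed affine map", {
  f <- setNames(seq(1, -0.6, length.out = 12) + 0.15 * sin(1:12), 1999:2010)
  g_full <- setNames(c(seq(1.8, 1.05, length.out = 12),
                       (as.numeric(f) - 1) / 2), c(1987:1998, 1999:2010))
  tb <- extend_trend_proxy(f, g_full, target_years = 1987:1998)
  expect_equal(tb$calib_intercept[1], 1, tolerance = 1e-10)
  expect_equal(tb$calib_slope[1], 2, tolerance = 1e-10)
  # historical years carry the calibrated proxy values
  expect_equal(tb$f[tb$year %in% 1987:1998],
               1 + 2 * g_full[as.character(1987:1998)], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("a proxy identical to the primary trend calibrates to identity", {
  f <- setNames(seq(0.9, -0.5, length.out = 12) + 0.1 * cos(1:12), 1999:2010)
  g_full <- setNames(c(seq(1.6, 1.0, length.out = 12), as.numeric(f)),
                     c(1987:1998, 1999:2010))
  tb <- extend_trend_proxy(f, g_full, target_years = 1987:1998)
  expect_equal(tb$calib_intercept[1], 0, tolerance = 1e-10)
  expect_equal(tb$calib_slope[1], 1, tolerance = 1e-10)
  expect_equal(tb$f[tb$year %in% 1999:2010], unname(f))
  # a proxy SVD-estimated from matrix data recovers the same historical
  # shape up to the calibration (correlation 1 with the generating series)
  proxy <- rank1_matrix(g_full, n_sites = 8, seed = 6)
  tb2 <- extend_trend_proxy(f, proxy, target_years = 1987:1998)
  expect_gte(cor(tb2$f[tb2$year < 1999], g_full[as.character(1987:1998)]),
             1 - 1e-8)
})

test_that("pre-proxy years lie on the calibrated proxy line", {
  f <- setNames(2 - 0.05 * (0:11), 1999:2010)
  g_full <- setNames(3 - 0.05 * (0:23), 1987:2010)  # exactly linear proxy
  proxy <- rank1_matrix(g_full, n_sites = 6, seed = 7, b_min = 1, b_max = 1)
  tb <- extend_trend_proxy(f, proxy, target_years = 1980:1998)
  # closed form: calibrated proxy is linear, so 1980-1986 continue the line
  slope <- (tb$f[tb$year == 1998] - tb$f[tb$year == 1987]) / 11
  expected_1980 <- tb$f[tb$year == 1987] - 7 * slope
  expect_equal(tb$f[tb$year == 1980], expected_1980, tolerance = 1e-8)
})

test_that("insufficient overlap and degenerate proxies raise classed errors", {
  f <- setNames(seq(1, 0, length.out = 12), 1999:2010)
  proxy_short <- rank1_matrix(setNames(1:5 / 5, 1996:2000), n_sites = 5)
  expect_error(extend_trend_proxy(f, proxy_short),
               class = "pm_insufficient_overlap")
  proxy_flat <- rank1_matrix(setNames(rep(1, 24), 1987:2010), n_sites = 5,
                             b_min = 0, b_max = 0)
  expect_warning(
    expect_error(extend_trend_proxy(f, proxy_flat),
                 class = "pm_degenerate_calibration")
  )
})

test_that("all approaches share the primary trend over the fitting years", {
  w <- small_world()
  primary <- dplyr::filter(w$annual, network == "primary")
  t1 <- build_trend_basis(primary, "pm25")
  t2 <- build_trend_basis(primary, "sulfate", w$proxy_a_annual)
  t3 <- build_trend_basis(primary, "visibility", w$proxy_b_annual)
  expect_equal(t1$f[t1$year >= 1999], t2$f[t2$year >= 1999])
  expect_equal(t1$f[t1$year >= 1999], t3$f[t3$year >= 1999])
})

test_that("site-year matrix applies the more-than-half-years eligibility rule", {
  annual <- tidyr::expand_grid(site_id = c("A", "B"), year = 1999:2010) |>
    dplyr::mutate(value = 10, included = TRUE)
  annual <- annual[!(annual$site_id == "B" & annual$year > 2004), ]  # B: 6 years
  m <- site_year_matrix(annual, years = 1999:2010)
  expect_equal(rownames(m), "A")
  expect_error(trend_values(pmhindcast:::trend_basis_tibble(1999:2010, rep(1, 12), "x"),
                            1980),
               class = "pm_out_of_range")
})
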