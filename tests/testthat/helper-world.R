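# shared fixtures built in code; small_world() memoises a reduced synthetic
# world so unit tests stay fast, while acceptance tests build the full
# default world themselves
.fixture_env <- new.env(parent = emptyenv())

small_world <- function() {
  if (is.null(.fixture_env$world)) {
    .fixture_env$world <- generate_world(
      world_config(n_primary = 60, n_hist = 20, n_extra = 10,
                   n_proxy_a = 25, n_proxy_b = 30, p_covariates = 20),
      seed = 42
    )
  }
  .fixture_env$world
}

world_a <- function() {
  if (is.null(.fixture_env$world_a)) {
    .fixture_env$world_a <- generate_world(seed = 20160624)
  }
  .fixture_env$world_a
}

# daily records for one site covering the given day-of-year set
make_daily <- function(doys, year, value = 10, site = "S1") {
  tibble::tibble(
    site_id = site,
    date = as.Date(sprintf("%d-01-01", year)) + doys - 1,
    value = value
  )
}

# brute-force longest run of unsampled calendar days (oracle for QC tests)
gap_oracle <- function(doys, year) {
  nd <- ifelse((year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0, 366, 365)
  sampled <- rep(FALSE, nd)
  sampled[doys] <- TRUE
  best <- 0; run <- 0
  for (d in seq_len(nd)) {
    if (!sampled[d]) run <- run + 1 else run <- 0
    best <- max(best, run)
  }
  best
}

trend_a <- function() {
  if (is.null(.fixture_env$trend_a)) {
    primary <- dplyr::filter(world_a()$annual, network == "primary")
    .fixture_env$trend_a <- build_trend_basis(primary, "pm25")
  }
  .fixture_env$trend_a
}

model_a <- function() {
  if (is.null(.fixture_env$model_a)) {
    w <- world_a()
    primary <- dplyr::filter(w$annual, network == "primary")
    .fixture_env$model_a <- fit_st_model(primary, w$sites, w$covariates,
                                         trend_a())
  }
  .fixture_env$model_a
}
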