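#' Build a full-window trend basis from annual tables
#'
#' Convenience wrapper tying the trend module together: estimates the primary
#' trend by SVD from the fitting-period annual data, then extends it to the
#' historical years by the chosen approach.
#'
#' @param annual QC'd primary annual table (µg/m³).
#' @param approach `"pm25"` (linear extrapolation), `"sulfate"` or
#'   `"visibility"` (proxy calibration).
#' @param proxy_annual Proxy annual table (required for proxy approaches).
#' @param primary_years Fitting years (default 1999:2010).
#' @param target_years Historical years (default 1980:1998).
#' @param min_years Site eligibility threshold for the primary matrix
#'   (default: more than half the span).
#' @return A `trend_basis` tibble over `c(target_years, primary_years)`.
#' @export
build_trend_basis <- function(annual, approach = c("pm25", "sulfate", "visibility"),
                              proxy_annual = NULL, primary_years = 1999:2010,
                              target_years = 1980:1998, min_years = NULL) {
  approach <- match.arg(approach)
  m <- site_year_matrix(annual, years = primary_years, min_years = min_years)
  f <- estimate_trend_svd(m)
  if (approach == "pm25") {
    return(extend_trend_linear(f, target_years))
  }
  if (is.null(proxy_annual)) {
    stop_pm("proxy approaches need `proxy_annual`", "pm_invalid_parameter")
  }
  pm <- site_year_matrix(proxy_annual)
  extend_trend_proxy(f, pm, target_years,
                     source = paste0(approach, "_proxy"))
}

stage_signature <- function(files) {
  files <- files[file.exists(files)]
  sums <- tools::md5sum(files)
  paste(basename(files), unname(sums), sep = "=", collapse = ";")
}

#' Run the simulate/trend/fit/predict pipeline
#'
#' Executes the requested stages in dependency order, communicating through
#' CSV/JSON files in `out_dir`, and writes a manifest recording the config,
#' package version, input checksums and per-stage status. A stage whose
#' outputs already exist and whose input checksums are unchanged from the
#' recorded manifest is skipped; corrupting an intermediate file invalidates
#' exactly the stages downstream of it.
#'
#' @param config Named list (or path to a YAML file) with entries:
#'   `out_dir`; `seed`; `world` (overrides for [world_config()]);
#'   `trend_approach` (`"pm25"`, `"sulfate"`, `"visibility"`);
#'   `predict_years` (default 1980:2010); `predict_network` (which simulated
#'   network to predict at, default `"extra"`); `stages` (default
#'   `c("simulate", "trend", "fit", "predict")`, `"crossvalidate"` optional);
#'   `cv_k`, `cv_seed`.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(seed = 20160624, world = list(), trend_approach = "pm25",
                   predict_years = 1980:2010, predict_network = "extra",
                   stages = c("simulate", "trend", "fit", "predict"),
                   cv_k = 5, cv_seed = 1)
  config <- utils::modifyList(defaults, config)
  if (is.null(config$out_dir)) {
    stop_pm("config must name an `out_dir`", "pm_invalid_parameter")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(config$out_dir, ...)
  cfg_path <- pth("config.json")
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null"), cfg_path)

  manifest_path <- pth("manifest.json")
  old_manifest <- if (file.exists(manifest_path)) {
    tryCatch(jsonlite::fromJSON(readLines(manifest_path, warn = FALSE),
                                simplifyVector = FALSE),
             error = function(e) NULL)
  } else NULL
  manifest <- list(package_version = as.character(utils::packageVersion("pmhindcast")),
                   config = config, stages = list())

  stage_files <- list(
    simulate = list(
      inputs = cfg_path,
      outputs = pth(c("sites.csv", "annual.csv", "covariates.csv",
                      "proxy_a_annual.csv", "proxy_b_annual.csv", "truth.json"))
    ),
    trend = list(
      inputs = c(cfg_path, pth(c("annual.csv", "proxy_a_annual.csv",
                                 "proxy_b_annual.csv"))),
      outputs = pth("trend.csv")
    ),
    fit = list(
      inputs = c(cfg_path, pth(c("annual.csv", "sites.csv", "covariates.csv",
                                 "trend.csv"))),
      outputs = pth("model.json")
    ),
    predict = list(
      inputs = c(cfg_path, pth(c("model.json", "sites.csv", "covariates.csv"))),
      outputs = pth("predictions.csv")
    ),
    crossvalidate = list(
      inputs = c(cfg_path, pth(c("annual.csv", "sites.csv", "covariates.csv",
                                 "trend.csv"))),
      outputs = pth(c("cv_table.csv", "cv_summary.csv"))
    )
  )

  run_stage <- function(name, fun) {
    info <- stage_files[[name]]
    sig <- stage_signature(info$inputs)
    old <- old_manifest$stages[[name]]
    if (!is.null(old) && identical(old$signature, sig) &&
        all(file.exists(info$outputs))) {
      manifest$stages[[name]] <<- list(status = "skipped", signature = sig)
      return(invisible(NULL))
    }
    fun()
    manifest$stages[[name]] <<- list(status = "ok",
                                     signature = stage_signature(info$inputs))
  }

  halted <- FALSE
  for (stage in intersect(c("simulate", "trend", "fit", "predict",
                            "crossvalidate"), config$stages)) {
    if (halted) {
      manifest$stages[[stage]] <- list(status = "not-run")
      next
    }
    result <- tryCatch({
      run_stage(stage, switch(stage,
        simulate = function() {
          world <- generate_world(do.call(world_config, config$world),
                                  seed = config$seed)
          write_table_csv(world$sites, pth("sites.csv"))
          write_table_csv(world$annual, pth("annual.csv"))
          write_table_csv(world$covariates, pth("covariates.csv"))
          write_table_csv(world$proxy_a_annual, pth("proxy_a_annual.csv"))
          write_table_csv(world$proxy_b_annual, pth("proxy_b_annual.csv"))
          writeLines(jsonlite::toJSON(list(
            f_star = as.list(world$truth$f_star),
            mu_cov = world$truth$mu_cov, resid_cov = world$truth$resid_cov
          ), auto_unbox = TRUE, digits = NA), pth("truth.json"))
        },
        trend = function() {
          annual <- read_annual_csv(pth("annual.csv"))
          primary <- filter(annual, .data$network == "primary")
          proxy <- switch(config$trend_approach,
                          sulfate = read_annual_csv(pth("proxy_a_annual.csv")),
                          visibility = read_annual_csv(pth("proxy_b_annual.csv")),
                          NULL)
          trend <- build_trend_basis(primary, config$trend_approach, proxy)
          write_table_csv(trend, pth("trend.csv"))
        },
        fit = function() {
          annual <- filter(read_annual_csv(pth("annual.csv")),
                           .data$network == "primary")
          model <- fit_st_model(annual, read_sites_csv(pth("sites.csv")),
                                read_covariates_csv(pth("covariates.csv")),
                                read_trend_csv(pth("trend.csv")))
          write_st_model(model, pth("model.json"))
        },
        predict = function() {
          model <- read_st_model(pth("model.json"))
          sites <- read_sites_csv(pth("sites.csv"))
          locs <- filter(sites, .data$network == config$predict_network)
          preds <- predict(model, locs, read_covariates_csv(pth("covariates.csv")),
                           config$predict_years)
          write_table_csv(preds, pth("predictions.csv"))
        },
        crossvalidate = function() {
          annual <- filter(read_annual_csv(pth("annual.csv")),
                           .data$network == "primary")
          cv <- cross_validate(annual, read_sites_csv(pth("sites.csv")),
                               read_covariates_csv(pth("covariates.csv")),
                               read_trend_csv(pth("trend.csv")),
                               k = config$cv_k, seed = config$cv_seed)
          write_table_csv(cv$table, pth("cv_table.csv"))
          write_table_csv(tidy(cv), pth("cv_summary.csv"))
        }
      ))
      TRUE
    }, error = function(e) {
      manifest$stages[[stage]] <<- list(status = "failed",
                                        error = conditionMessage(e))
      FALSE
    })
    if (!isTRUE(result)) halted <- TRUE
  }
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null"), manifest_path)
  invisible(manifest)
}
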