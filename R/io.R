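#' Read and write the package's delimited-text tables
#'
#' Thin CSV wrappers that validate the expected schema on read. Dates are
#' ISO-8601; tables come back as tibbles.
#'
#' @param path File path.
#' @name pm_io
NULL

#' @rdname pm_io
#' @export
read_annual_csv <- function(path) {
  out <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  check_cols(out, c("site_id", "year", "value"), basename(path))
  out
}

#' @rdname pm_io
#' @export
read_sites_csv <- function(path) {
  out <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  check_cols(out, c("site_id", "lon", "lat"), basename(path))
  out
}

#' @rdname pm_io
#' @export
read_covariates_csv <- function(path) {
  out <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                   check.names = FALSE))
  check_cols(out, "site_id", basename(path))
  out
}

#' @rdname pm_io
#' @export
read_daily_csv <- function(path) {
  out <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  check_cols(out, c("site_id", "date", "value"), basename(path))
  out$date <- as.Date(out$date)
  out
}

#' @rdname pm_io
#' @export
read_trend_csv <- function(path) {
  out <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  check_cols(out, c("year", "f", "source"), basename(path))
  if (!"calib_intercept" %in% names(out)) out$calib_intercept <- NA_real_
  if (!"calib_slope" %in% names(out)) out$calib_slope <- NA_real_
  class(out) <- c("trend_basis", class(out))
  out
}

#' @param x Table to write.
#' @rdname pm_io
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a fitted spatio-temporal model to JSON
#'
#' The whole fitted object (coefficients, covariance parameters, trend
#' basis, PLS rotation, site table, residuals) goes into a single JSON file
#' with a format-version field, at full precision.
#'
#' @param model A fitted `st_model`.
#' @param path Output path.
#' @export
write_st_model <- function(model, path) {
  stopifnot(inherits(model, "st_model"))
  payload <- list(format = "pmhindcast-model-1",
                  model = jsonlite::serializeJSON(model, digits = NA))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE), path)
  invisible(path)
}

#' Read a serialized spatio-temporal model
#' @param path Path written by [write_st_model()].
#' @return The restored `st_model`.
#' @export
read_st_model <- function(path) {
  payload <- jsonlite::fromJSON(readLines(path, warn = FALSE))
  if (!identical(payload$format, "pmhindcast-model-1")) {
    stop_pm("unrecognised model file format", "pm_schema_error")
  }
  model <- jsonlite::unserializeJSON(payload$model)
  stopifnot(inherits(model, "st_model"))
  model
}
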