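#' @importFrom rlang abort warn %||% .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join bind_rows rename n distinct across pull
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map2 pmap imap walk
#' @importFrom stats lm coef optim sd var rnorm runif median setNames
#'   complete.cases cor quantile
#' @importFrom utils head tail write.csv read.csv
NULL

# internal: stop with a classed condition so callers can test error classes
stop_pm <- function(msg, class) {
  rlang::abort(msg, class = c(class, "pmhindcast_error"))
}

check_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_pm(
      paste0(what, " is missing required column(s): ",
             paste(missing, collapse = ", ")),
      "pm_schema_error"
    )
  }
  invisible(df)
}

days_in_year <- function(year) {
  ifelse((year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0, 366L, 365L)
}

#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
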