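#' Prune a geographic-covariate table
#'
#' Drops uninformative variables before dimension reduction: variables with
#' any missing value, variables whose most frequent value occurs in more than
#' `max_mode_freq` of sites, and variables whose standard deviation is below
#' `min_sd`. Retained variables keep their original order.
#'
#' @param covariates Data frame whose first column is `site_id` and whose
#'   remaining columns are numeric geographic variables.
#' @param max_mode_freq Maximum admissible frequency of the modal value
#'   (default 0.85).
#' @param min_sd Minimum admissible standard deviation (default 0, which
#'   drops exactly-constant variables).
#' @return A tibble with `site_id` plus the retained variables.
#' @export
prune_covariates <- function(covariates, max_mode_freq = 0.85, min_sd = 0) {
  check_cols(covariates, "site_id", "covariates table")
  covariates <- as_tibble(covariates)
  vars <- setdiff(names(covariates), "site_id")
  if (length(vars) == 0) stop_pm("no covariate columns found", "pm_empty_covariates")
  keep <- purrr::map_lgl(vars, function(v) {
    x <- covariates[[v]]
    if (anyNA(x)) return(FALSE)
    mode_freq <- max(table(x)) / length(x)
    if (mode_freq > max_mode_freq) return(FALSE)
    s <- stats::sd(x)
    s > min_sd || (min_sd == 0 && s > 0)
  })
  if (!any(keep)) {
    stop_pm("all covariates were pruned; nothing left to model",
            "pm_empty_covariates")
  }
  covariates[, c("site_id", vars[keep])]
}

# covariate matrix (sites x variables) from a site_id-keyed table, aligned to
# the requested site order and variable names
covariate_matrix <- function(covariates, site_ids = NULL, variables = NULL) {
  check_cols(covariates, "site_id", "covariates table")
  vars <- variables %||% setdiff(names(covariates), "site_id")
  missing_vars <- setdiff(vars, names(covariates))
  if (length(missing_vars) > 0) {
    stop_pm(paste0("covariates table lacks variable(s): ",
                   paste(missing_vars, collapse = ", ")), "pm_schema_error")
  }
  ids <- site_ids %||% covariates$site_id
  idx <- match(ids, covariates$site_id)
  if (anyNA(idx)) {
    stop_pm(paste0("covariates table lacks site(s): ",
                   paste(ids[is.na(idx)], collapse = ", ")), "pm_schema_error")
  }
  m <- as.matrix(covariates[idx, vars, drop = FALSE])
  rownames(m) <- ids
  m
}

#' Fit partial least squares against a site-level response
#'
#' Deterministic NIPALS on standardized covariates and a centered univariate
#' response. Each component's weight vector has unit norm and its
#' largest-magnitude entry is made positive so the fit is reproducible
#' across platforms; training scores are mutually orthogonal. The stored
#' `weights` matrix is the composite rotation, so new-site scores are simply
#' `standardized(X) %*% weights`.
#'
#' @param covariates Covariate table (`site_id` + numeric variables) or a
#'   numeric matrix with rownames.
#' @param response Numeric response vector aligned with the covariate rows
#'   (here: estimated site long-term means of log concentration).
#' @param k Number of PLS components (default 2).
#' @return An object of class `pls_fit` with elements `variables`, `center`,
#'   `scale`, `weights` (variables x k rotation), `loadings`,
#'   `response_center`, `scores` (training scores), `k`.
#' @export
fit_pls <- function(covariates, response, k = 2) {
  X <- if (is.matrix(covariates)) covariates else covariate_matrix(covariates)
  if (nrow(X) != length(response)) {
    stop_pm("response length must match the number of covariate rows",
            "pm_invalid_parameter")
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl <= 0)) {
    stop_pm(paste0("zero-variance variable(s): ",
                   paste(colnames(X)[scl <= 0], collapse = ", ")),
            "pm_invalid_parameter")
  }
  Xs <- scale(X, center = ctr, scale = scl)
  y_ctr <- mean(response)
  y <- response - y_ctr

  p <- ncol(Xs)
  W <- matrix(0, p, k); P <- matrix(0, p, k); Tm <- matrix(0, nrow(Xs), k)
  Xd <- Xs
  for (h in seq_len(k)) {
    w <- drop(crossprod(Xd, y))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      stop_pm(paste0("rank deficiency: no covariance left for component ", h),
              "pm_rank_deficiency")
    }
    w <- w / nw
    t_h <- drop(Xd %*% w)
    tt <- sum(t_h^2)
    if (tt < 1e-12) {
      stop_pm(paste0("rank deficiency at component ", h), "pm_rank_deficiency")
    }
    p_h <- drop(crossprod(Xd, t_h)) / tt
    # sign convention: largest-magnitude weight entry positive
    if (w[which.max(abs(w))] < 0) {
      w <- -w; t_h <- -t_h; p_h <- -p_h
    }
    W[, h] <- w; P[, h] <- p_h; Tm[, h] <- t_h
    Xd <- Xd - tcrossprod(t_h, p_h)
    y <- y - t_h * sum(t_h * y) / tt
  }
  rotation <- W %*% solve(crossprod(P, W))
  # rotation reproduces deflated-space scores from undeflated standardized X
  colnames(rotation) <- paste0("pls", seq_len(k))
  rownames(rotation) <- colnames(X)
  colnames(Tm) <- paste0("pls", seq_len(k))
  structure(
    list(variables = colnames(X), center = ctr, scale = scl,
         weights = rotation, loadings = P, response_center = y_ctr,
         scores = Tm, k = k),
    class = "pls_fit"
  )
}

#' Project sites onto fitted PLS components
#'
#' Aligns the covariate table to the model's variables by name, standardizes
#' with the training center/scale, and applies the stored rotation. Applying
#' to the training table reproduces the training scores.
#'
#' @param model A `pls_fit` object.
#' @param covariates Covariate table containing (at least) the model's
#'   variables, or a numeric matrix with matching column names.
#' @param site_ids Optional site order for table input.
#' @return A tibble `site_id`, `pls1`, ..., `plsk`.
#' @export
project_pls <- function(model, covariates, site_ids = NULL) {
  stopifnot(inherits(model, "pls_fit"))
  X <- if (is.matrix(covariates)) {
    missing_vars <- setdiff(model$variables, colnames(covariates))
    if (length(missing_vars) > 0) {
      stop_pm(paste0("missing variable(s): ",
                     paste(missing_vars, collapse = ", ")), "pm_schema_error")
    }
    covariates[, model$variables, drop = FALSE]
  } else {
    covariate_matrix(covariates, site_ids, model$variables)
  }
  Xs <- scale(X, center = model$center, scale = model$scale)
  scores <- Xs %*% model$weights
  tibble(site_id = rownames(X) %||% as.character(seq_len(nrow(X)))) |>
    dplyr::bind_cols(as_tibble(scores))
}

#' @method tidy pls_fit
#' @export
tidy.pls_fit <- function(x, ...) {
  as_tibble(x$weights, rownames = "variable") |>
    tidyr::pivot_longer(-"variable", names_to = "component",
                        values_to = "weight")
}

#' @method glance pls_fit
#' @export
glance.pls_fit <- function(x, ...) {
  tibble(k = x$k, n_variables = length(x$variables),
         n_sites = nrow(x$scores), response_center = x$response_center)
}

#' @export
print.pls_fit <- function(x, ...) {
  cat("PLS fit:", x$k, "component(s),", length(x$variables), "variables,",
      nrow(x$scores), "training sites\n")
  invisible(x)
}
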