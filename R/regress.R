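#' Regress congruence on sociodemographic covariates
#'
#' Fits the ordinary least squares model `congruence ~ covariates` across
#' districts, with classical standard errors, two-sided t-test p-values and
#' adjusted R-squared `1 - (1 - R^2)(n - 1)/(n - k - 1)`, together with
#' standardized coefficients from a companion fit on z-scored variables
#' (sample SD, dependent included; its intercept is 0 up to rounding).
#' No multiple-testing correction is applied (p-values are reported raw).
#' Districts with a missing dependent value (e.g. an undefined congruence
#' index) are dropped listwise and reported.
#'
#' @param data One row per district, containing `dependent` and every
#'   covariate.
#' @param dependent Name of the congruence index column (default
#'   `"kendall_tau"`; `"spearman_rho"` follows the identical path).
#' @param covariates Covariate column names (default: the six
#'   sociodemographic features of [build_features()]).
#' @return An object of class `congruence_ols`; see [tidy()] and
#'   [glance()] methods, and [autoplot.congruence_ols()].
#' @export
fit_congruence_ols <- function(data,
                               dependent = "kendall_tau",
                               covariates = c("birthrate", "education_mean",
                                              "education_sd",
                                              "population_density",
                                              "doctors_per_clinic",
                                              "availability")) {
  missing_cols <- setdiff(c(dependent, covariates), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("`data` lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  keep <- !is.na(data[[dependent]])
  if (any(!keep)) {
    who <- if ("district_id" %in% names(data)) {
      paste(data$district_id[!keep], collapse = ", ")
    } else {
      paste(sum(!keep), "row(s)")
    }
    rlang::inform(paste0("Dropping districts with missing ", dependent, ": ", who))
  }
  df <- data[keep, c(dependent, covariates)]
  n <- nrow(df)
  k <- length(covariates)
  if (n <= k + 1) {
    abort(paste0("Need more districts (", n, ") than covariates + 1 (",
                 k + 1, ") to fit."))
  }

  X <- as.matrix(df[covariates])
  qr_rank <- qr(cbind(1, X))$rank
  if (qr_rank < k + 1) {
    sds <- apply(X, 2, sd)
    suspects <- covariates[sds == 0]
    if (length(suspects) == 0) {
      drop_test <- vapply(covariates, function(v) {
        qr(cbind(1, X[, setdiff(covariates, v), drop = FALSE]))$rank == qr_rank
      }, logical(1))
      suspects <- covariates[drop_test]
    }
    abort(paste0("Design matrix is rank deficient; collinear column(s): ",
                 paste(suspects, collapse = ", ")))
  }

  constant_dependent <- sd(df[[dependent]]) == 0
  if (constant_dependent) {
    warn(paste0("`", dependent, "` has zero variance across districts; ",
                "coefficients are degenerate and standardized ",
                "coefficients undefined."))
  }

  fml <- stats::reformulate(covariates, response = dependent)
  fit <- lm(fml, data = df)
  smry <- summary(fit)

  std_estimates <- if (constant_dependent) {
    setNames(rep(NA_real_, k), covariates)
  } else {
    zdf <- as.data.frame(scale(df))
    std_fit <- lm(fml, data = zdf)
    stats::coef(std_fit)[covariates]
  }

  structure(
    list(fit = fit,
         summary = smry,
         dependent = dependent,
         covariates = covariates,
         std_estimates = std_estimates,
         n_obs = n,
         n_dropped = sum(!keep),
         constant_dependent = constant_dependent),
    class = "congruence_ols"
  )
}

#' Standardized coefficients of a congruence fit
#'
#' Returns the coefficients of the z-scored refit, which satisfy
#' `std_beta_j = beta_j * SD(x_j) / SD(y)` exactly; a 1-SD shift in a
#' covariate moves the predicted congruence by `std_beta_j` SDs.
#'
#' @param object A `congruence_ols` object.
#' @return Named numeric vector (no intercept).
#' @export
standardized_coefficients <- function(object) {
  stopifnot(inherits(object, "congruence_ols"))
  object$std_estimates
}

#' @export
print.congruence_ols <- function(x, ...) {
  cat(sprintf("<congruence_ols> %s ~ %s\n", x$dependent,
              paste(x$covariates, collapse = " + ")))
  cat(sprintf("  n = %d districts (%d dropped), adjusted R-squared = %.3f\n",
              x$n_obs, x$n_dropped, x$summary$adj.r.squared))
  invisible(x)
}

#' Tidy a congruence OLS fit
#'
#' @param x A `congruence_ols` object.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `std_estimate` (`NA` for the intercept).
#' @exportS3Method generics::tidy
tidy.congruence_ols <- function(x, ...) {
  cf <- x$summary$coefficients
  tibble::tibble(
    term = rownames(cf),
    estimate = unname(cf[, "Estimate"]),
    std.error = unname(cf[, "Std. Error"]),
    statistic = unname(cf[, "t value"]),
    p.value = unname(cf[, "Pr(>|t|)"]),
    std_estimate = dplyr::if_else(rownames(cf) == "(Intercept)",
                                  NA_real_,
                                  unname(x$std_estimates[rownames(cf)]))
  )
}

#' Glance at a congruence OLS fit
#'
#' @param x A `congruence_ols` object.
#' @param ... Unused.
#' @return A one-row tibble: `r.squared`, `adj.r.squared`, `sigma`,
#'   `statistic`, `p.value`, `df`, `nobs`, `n_dropped`, `dependent`.
#' @exportS3Method generics::glance
glance.congruence_ols <- function(x, ...) {
  s <- x$summary
  fstat <- s$fstatistic
  tibble::tibble(
    r.squared = s$r.squared,
    adj.r.squared = s$adj.r.squared,
    sigma = s$sigma,
    statistic = if (is.null(fstat)) NA_real_ else unname(fstat[1]),
    p.value = if (is.null(fstat)) {
      NA_real_
    } else {
      stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
    },
    df = length(x$covariates),
    nobs = x$n_obs,
    n_dropped = x$n_dropped,
    dependent = x$dependent
  )
}

#' Pairwise Pearson correlations between covariates
#'
#' Symmetric correlation structure of the district covariates, with
#' two-sided p-values from the t transform `t = r sqrt((n-2)/(1-r^2))`.
#' Zero-variance covariates yield `NA` entries with a warning.
#'
#' @param features Per-district feature tibble.
#' @param vars Columns to correlate (default: the six covariates).
#' @return A tibble in long form: `var1`, `var2`, `r`, `p.value`
#'   (diagonal included with r = 1).
#' @export
correlation_matrix <- function(features,
                               vars = c("birthrate", "education_mean",
                                        "education_sd", "population_density",
                                        "doctors_per_clinic", "availability")) {
  missing_cols <- setdiff(vars, names(features))
  if (length(missing_cols) > 0) {
    abort(paste0("`features` lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(features) < 3) abort("Need at least 3 districts.")
  X <- as.matrix(features[vars])
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    warn(paste0("Zero-variance covariate(s): ",
                paste(vars[sds == 0], collapse = ", "),
                "; correlations set to NA."))
  }
  grid <- tidyr::expand_grid(var1 = vars, var2 = vars)
  res <- purrr::pmap(grid, function(var1, var2) {
    if (sds[var1] == 0 || sds[var2] == 0) {
      return(tibble::tibble(r = NA_real_, p.value = NA_real_))
    }
    if (var1 == var2) return(tibble::tibble(r = 1, p.value = NA_real_))
    ct <- stats::cor.test(X[, var1], X[, var2], method = "pearson")
    tibble::tibble(r = unname(ct$estimate), p.value = ct$p.value)
  }) |> list_rbind()
  dplyr::bind_cols(grid, res)
}
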