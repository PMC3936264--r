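covariate_names <- c("birthrate", "education_mean", "education_sd",
                     "population_density", "doctors_per_clinic",
                     "availability")

make_lm_data <- function(n, beta = NULL, noise_sd = 0, seed = 1) {
  withr::with_seed(seed, {
    X <- as.data.frame(matrix(rnorm(n * 6), n, 6))
    names(X) <- covariate_names
    if (is.null(beta)) beta <- c(0.5, -1, 2, 0, 0.3, -0.7)
    X$kendall_tau <- 0.2 + as.matrix(X[covariate_names]) %*% beta +
      rnorm(n, 0, noise_sd)
    X$kendall_tau <- as.numeric(X$kendall_tau)
    X$district_id <- sprintf("D%03d", seq_len(n))
    tibble::as_tibble(X)
  })
}

test_that("noiseless linear data is recovered exactly", {
  beta <- c(0.5, -1, 2, 0, 0.3, -0.7)
  df <- make_lm_data(30, beta, noise_sd = 0)
  # summary.lm flags the deliberately exact fit; that is the point here
  fit <- suppressWarnings(fit_congruence_ols(df))
  td <- tidy(fit)
  expect_equal(td$estimate[match(covariate_names, td$term)], beta,
               tolerance = 1e-8)
  expect_equal(td$estimate[td$term == "(Intercept)"], 0.2, tolerance = 1e-8)
  expect_equal(glance(fit)$r.squared, 1, tolerance = 1e-10)
})

test_that("standardized coefficients satisfy the SD-ratio identity", {
  df <- make_lm_data(40, noise_sd = 0.5, seed = 3)
  fit <- fit_congruence_ols(df)
  td <- tidy(fit)
  sdy <- sd(df$kendall_tau)
  for (v in covariate_names) {
    raw <- td$estimate[td$term == v]
    expect_equal(td$std_estimate[td$term == v], raw * sd(df[[v]]) / sdy,
                 tolerance = 1e-10)
  }
  # standardized intercept is numerically zero
  zfit <- lm(stats::reformulate(covariate_names, "kendall_tau"),
             data = as.data.frame(scale(df[c("kendall_tau",
                                             covariate_names)])))
  expect_lt(abs(unname(coef(zfit)[1])), 1e-10)
  # a 1-SD covariate shift moves the prediction by std_beta SDs of y
  shift <- predict(fit$fit, df |> dplyr::mutate(
    birthrate = birthrate + sd(birthrate))) - predict(fit$fit, df)
  expect_equal(unique(round(shift / sdy, 10)),
               round(td$std_estimate[td$term == "birthrate"], 10))
})

test_that("adjusted R-squared, residual orthogonality and dropped rows behave", {
  df <- make_lm_data(35, noise_sd = 1, seed = 8)
  df$kendall_tau[c(3, 7)] <- NA
  expect_message(fit <- fit_congruence_ols(df), "Dropping districts")
  g <- glance(fit)
  expect_equal(g$nobs, 33)
  expect_equal(g$n_dropped, 2)
  expect_lte(g$adj.r.squared, g$r.squared)
  expect_equal(g$adj.r.squared,
               1 - (1 - g$r.squared) * (33 - 1) / (33 - 6 - 1),
               tolerance = 1e-12)
  X <- stats::model.matrix(fit$fit)
  expect_lt(max(abs(crossprod(X, stats::resid(fit$fit)))), 1e-8)
})

test_that("rank-deficient designs raise an error naming collinear columns", {
  df <- make_lm_data(25, noise_sd = 0.3, seed = 5)
  df$availability <- 2 * df$birthrate
  expect_error(fit_congruence_ols(df), "collinear")
  df2 <- make_lm_data(25, noise_sd = 0.3, seed = 6)
  df2$education_sd <- 1
  expect_error(fit_congruence_ols(df2), "education_sd")
  expect_error(fit_congruence_ols(make_lm_data(7)), "Need more districts")
})

test_that("fits are invariant under affine rescaling of a covariate", {
  df <- make_lm_data(29, noise_sd = 0.6, seed = 11)
  fit1 <- fit_congruence_ols(df)
  df2 <- df |> dplyr::mutate(population_density = population_density * 1e6)
  fit2 <- fit_congruence_ols(df2)
  t1 <- tidy(fit1)
  t2 <- tidy(fit2)
  expect_equal(t1$p.value, t2$p.value, tolerance = 1e-9)
  expect_equal(t1$std_estimate[-1], t2$std_estimate[-1], tolerance = 1e-9)
  expect_equal(t1$estimate[t1$term == "population_density"],
               t2$estimate[t2$term == "population_density"] * 1e6,
               tolerance = 1e-9)
})

test_that("p-values are calibrated under the null", {
  n <- 29
  withr::with_seed(123, {
    rej <- replicate(1000, {
      df <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * 7), n, 7)))
      names(df) <- c(covariate_names, "kendall_tau")
      fit <- fit_congruence_ols(df)
      td <- tidy(fit)
      td$p.value[td$term == "birthrate"] < 0.05
    })
  })
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(mean(rej) - 0.05), 3 * se)
})

test_that("rho as dependent follows the same path with concordant signs", {
  cfg <- sim_config(n_districts = 150, threads_per_district = 20, seed = 41)
  dat <- sim_congruence_data(cfg)
  ct <- congruence_table(align_rankings(dat$mention_counts, dat$registry))
  md <- dplyr::inner_join(ct, dat$demographics, by = "district_id")
  ft <- fit_congruence_ols(md, dependent = "kendall_tau")
  fr <- fit_congruence_ols(md, dependent = "spearman_rho")
  bt <- tidy(ft)$estimate[tidy(ft)$term == "birthrate"]
  br <- tidy(fr)$estimate[tidy(fr)$term == "birthrate"]
  expect_equal(sign(bt), sign(br))
  expect_lt(bt, 0)
})

test_that("correlation matrices agree with a covariance-based oracle", {
  withr::with_seed(17, {
    feats <- tibble::as_tibble(as.data.frame(matrix(rnorm(29 * 6), 29, 6)))
  })
  names(feats) <- covariate_names
  cm <- correlation_matrix(feats)
  expect_equal(nrow(cm), 36)
  expect_true(all(cm$r[cm$var1 == cm$var2] == 1))
  X <- as.matrix(feats)
  for (i in 1:5) {
    for (j in (i + 1):6) {
      v1 <- covariate_names[i]
      v2 <- covariate_names[j]
      r_oracle <- cov(X[, i], X[, j]) / sqrt(var(X[, i]) * var(X[, j]))
      got <- cm$r[cm$var1 == v1 & cm$var2 == v2]
      expect_equal(got, r_oracle, tolerance = 1e-12)
      expect_equal(got, cm$r[cm$var1 == v2 & cm$var2 == v1])
      # p-value via the t transform
      tt <- r_oracle * sqrt((29 - 2) / (1 - r_oracle^2))
      expect_equal(cm$p.value[cm$var1 == v1 & cm$var2 == v2],
                   2 * pt(-abs(tt), 29 - 2), tolerance = 1e-10)
    }
  }
  # exactly collinear pair
  feats2 <- feats |> dplyr::mutate(availability = -3 * birthrate)
  cm2 <- correlation_matrix(feats2)
  expect_equal(cm2$r[cm2$var1 == "birthrate" & cm2$var2 == "availability"], -1)
  # zero variance -> NA with warning
  feats3 <- feats |> dplyr::mutate(education_sd = 2)
  expect_warning(cm3 <- correlation_matrix(feats3), "Zero-variance")
  expect_true(is.na(cm3$r[cm3$var1 == "education_sd" &
                            cm3$var2 == "birthrate"]))
})
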