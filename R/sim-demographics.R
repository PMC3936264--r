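#' Simulate district demographics
#'
#' Draws the six sociodemographic covariates for each district from normal
#' distributions whose means and SDs default to the summary statistics of
#' the emulated setting (birthrate 1.048 (0.100), mean education of married
#' women 12.390 (0.833) years, education SD 3.496 (0.183) years, population
#' density 0.016 (0.007) persons per square metre, doctors per pediatric
#' clinic 1.641 (0.396), clinic availability 0.060 (0.010) per 1000
#' persons), together with mutually consistent raw fields: the district
#' area is derived from the drawn density and population, the clinic count
#' from the drawn availability, and the doctor count from the drawn
#' doctors-per-clinic target. Covariates implied by rounded counts
#' (`availability`, `doctors_per_clinic`) are recomputed from the raw
#' fields so the tabulated invariants hold exactly.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per district: `district_id`, the raw fields
#'   `population`, `area_km2`, `n_clinics`, `n_doctors`, and the covariates
#'   `birthrate`, `education_mean`, `education_sd`, `population_density`,
#'   `doctors_per_clinic`, `availability`.
#' @export
#' @examples
#' sim_demographics(sim_config(n_districts = 3, seed = 2))
sim_demographics <- function(config) {
  validate_sim_config(config)
  withr::local_seed(stream_seed(config$seed, SIM_STREAMS[["demographics"]]))
  n <- config$n_districts
  mu <- config$covariate_means
  sig <- config$covariate_sds

  birthrate <- pmax(0.1, rnorm(n, mu[["birthrate"]], sig[["birthrate"]]))
  education_mean <- pmin(23, pmax(0, rnorm(n, mu[["education_mean"]],
                                           sig[["education_mean"]])))
  education_sd <- pmax(0, rnorm(n, mu[["education_sd"]], sig[["education_sd"]]))
  density <- pmax(0.001, rnorm(n, mu[["population_density"]],
                               sig[["population_density"]]))
  availability <- pmax(0.005, rnorm(n, mu[["availability"]],
                                    sig[["availability"]]))
  dpc <- pmax(1, rnorm(n, mu[["doctors_per_clinic"]],
                       sig[["doctors_per_clinic"]]))
  population <- round(pmax(5e4, rnorm(n, config$population_mean,
                                      config$population_sd)))

  area_km2 <- population / (density * 1e6)
  n_clinics <- pmax(1L, as.integer(round(availability * population / 1000)))
  n_doctors <- pmax(n_clinics, as.integer(round(dpc * n_clinics)))

  tibble::tibble(
    district_id = sprintf("D%02d", seq_len(n)),
    population = population,
    area_km2 = area_km2,
    n_clinics = n_clinics,
    n_doctors = n_doctors,
    birthrate = birthrate,
    education_mean = education_mean,
    education_sd = education_sd,
    population_density = population / (area_km2 * 1e6),
    doctors_per_clinic = n_doctors / n_clinics,
    availability = 1000 * n_clinics / population
  )
}

#' Per-district perceived-quality noise SD
#'
#' The generative link between geography and congruence: each district's
#' crowd perceives clinic quality through Gaussian noise whose SD is a
#' linear function of its z-scored covariates, truncated at zero. Districts
#' high on covariates with positive coefficients (by default birthrate,
#' education SD, population density, doctors per clinic) perceive quality
#' more noisily and therefore build less congruent crowdsourced rankings.
#'
#' @param demographics Output of [sim_demographics()] (or any tibble with
#'   the six covariate columns).
#' @param config A [sim_config()]; covariates are z-scored with the
#'   configured generative means/SDs so the SD is an exact linear function
#'   of the covariates, not of their sample moments.
#' @return Numeric vector of noise SDs (prescription-rate units), one per row.
#' @export
district_noise_sd <- function(demographics, config) {
  validate_sim_config(config)
  coefs <- config$noise_coefficients
  sd_out <- rep(coefs[["intercept"]], nrow(demographics))
  for (nm in setdiff(names(coefs), "intercept")) {
    if (coefs[[nm]] == 0) next
    if (!nm %in% names(demographics)) {
      abort(paste0("noise coefficient names unknown covariate `", nm, "`"))
    }
    gen_sd <- config$covariate_sds[[nm]]
    z <- if (gen_sd > 0) {
      (demographics[[nm]] - config$covariate_means[[nm]]) / gen_sd
    } else {
      rep(0, nrow(demographics))
    }
    sd_out <- sd_out + coefs[[nm]] * z
  }
  pmax(0, sd_out)
}

#' Simulate census education-category counts
#'
#' Generates per-district counts of married women by highest completed
#' education (the eight categories from no schooling to PhD), multinomially
#' sampled from a base profile centred near the emulated setting's education
#' summary (mean about 12.4 years, SD about 3.7 years). Used to exercise
#' [education_stats()] end to end.
#'
#' @param n_districts Number of districts.
#' @param n_women Women sampled per district.
#' @param profile Base category probabilities (named over
#'   [education_categories()]); must sum to 1.
#' @param seed Integer seed.
#' @return A tibble with `district_id` and one count column per category.
#' @export
sim_census_counts <- function(n_districts,
                              n_women = 30000,
                              profile = c(none = 0.02, elementary = 0.06,
                                          middle = 0.18, high = 0.38,
                                          college2 = 0.10, college4 = 0.19,
                                          master = 0.05, phd = 0.02),
                              seed = 1L) {
  stopifnot(abs(sum(profile) - 1) < 1e-8, all(profile >= 0))
  if (!identical(names(profile), education_categories())) {
    abort("`profile` must be named over education_categories().")
  }
  withr::local_seed(stream_seed(seed, SIM_STREAMS[["census"]]))
  counts <- stats::rmultinom(n_districts, size = n_women, prob = profile)
  out <- tibble::as_tibble(t(counts))
  names(out) <- education_categories()
  dplyr::bind_cols(tibble::tibble(district_id = sprintf("D%02d", seq_len(n_districts))),
                   out)
}
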