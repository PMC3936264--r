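#' Education categories and their years-of-schooling values
#'
#' Highest completed education of married women is recorded in eight
#' categories, converted to years of schooling as 0 (none), 6 (elementary),
#' 9 (middle), 12 (high school), 14 (2-year college), 16 (4-year college),
#' 18 (master's) and 23 (PhD).
#'
#' @return `education_categories()`: the category names in order.
#'   `education_years()`: a named numeric vector mapping category to years.
#' @export
#' @examples
#' education_years()
education_categories <- function() {
  c("none", "elementary", "middle", "high", "college2", "college4",
    "master", "phd")
}

#' @rdname education_categories
#' @export
education_years <- function() {
  setNames(c(0, 6, 9, 12, 14, 16, 18, 23), education_categories())
}

#' Weighted education mean and SD from category counts
#'
#' Computes the mean and standard deviation of years of schooling from
#' per-category head counts, using the population (divide-by-N) SD: at
#' census scale the sample/population distinction is immaterial, and SD 0
#' for a single-category district is the natural convention.
#'
#' @param category_counts Named numeric vector of non-negative counts over
#'   [education_categories()], or a data frame with those columns (one row
#'   per district).
#' @return A tibble with columns `education_mean` and `education_sd` (one
#'   row per input row; a single row for a vector input).
#' @export
#' @examples
#' education_stats(c(none = 0, elementary = 0, middle = 0, high = 50,
#'                   college2 = 0, college4 = 50, master = 0, phd = 0))
education_stats <- function(category_counts) {
  yrs <- education_years()
  cats <- education_categories()
  if (is.data.frame(category_counts)) {
    m <- as.matrix(category_counts[, cats])
  } else {
    if (!all(cats %in% names(category_counts))) {
      abort("`category_counts` must be named over education_categories().")
    }
    m <- matrix(category_counts[cats], nrow = 1,
                dimnames = list(NULL, cats))
  }
  if (any(m < 0)) abort("Education counts must be non-negative.")
  totals <- rowSums(m)
  if (any(totals <= 0)) abort("Education counts must total > 0 in every row.")
  w <- m / totals
  mu <- as.numeric(w %*% yrs)
  second <- as.numeric(w %*% yrs^2)
  tibble::tibble(education_mean = mu,
                 education_sd = sqrt(pmax(0, second - mu^2)))
}

#' Construct district sociodemographic features
#'
#' Builds the regression covariates from raw district inputs:
#' `population_density = population / (area_km2 * 1e6)` (persons per square
#' metre -- the scale on which metropolitan-district densities run about
#' 0.003-0.029), `doctors_per_clinic = n_doctors / n_clinics`, and
#' `availability = 1000 * n_clinics / population` (clinics per 1000
#' persons). Birthrate and the education columns pass through.
#'
#' @param data A data frame with columns `district_id`, `population`,
#'   `area_km2`, `n_clinics`, `n_doctors`, `birthrate`, and either
#'   `education_mean`/`education_sd` or the eight education category count
#'   columns (converted via [education_stats()]).
#' @return A tibble with `district_id` and the six covariates.
#' @export
#' @examples
#' build_features(tibble::tibble(
#'   district_id = "D01", population = 480000, area_km2 = 30,
#'   n_clinics = 29, n_doctors = 48, birthrate = 1.05,
#'   education_mean = 12.4, education_sd = 3.5))
build_features <- function(data) {
  required <- c("district_id", "population", "area_km2", "n_clinics",
                "n_doctors", "birthrate")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("`data` lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  bad <- data$area_km2 <= 0 | data$n_clinics <= 0 | data$population <= 0
  if (any(bad)) {
    abort(paste0("Non-positive area, clinics or population for district(s): ",
                 paste(data$district_id[bad], collapse = ", ")))
  }
  if (!all(c("education_mean", "education_sd") %in% names(data))) {
    data <- dplyr::bind_cols(data, education_stats(data))
  }
  data |>
    transmute(
      district_id = .data$district_id,
      birthrate = .data$birthrate,
      education_mean = .data$education_mean,
      education_sd = .data$education_sd,
      population_density = .data$population / (.data$area_km2 * 1e6),
      doctors_per_clinic = .data$n_doctors / .data$n_clinics,
      availability = 1000 * .data$n_clinics / .data$population
    )
}

#' Aggregate multi-period district tables
#'
#' Collapses a stack of per-period district tables to one row per district,
#' averaging every numeric column by default (e.g. population, area,
#' birthrate, prescription rates over 2009-2012-style windows) and passing
#' single-period columns through unchanged. Columns named in `sum_cols` are
#' summed instead (e.g. mention counts, which accumulate over periods).
#'
#' @param data A data frame with a `district_id` column and one row per
#'   district-period.
#' @param sum_cols Character vector of columns to sum rather than average.
#' @return A tibble with one row per district.
#' @export
#' @examples
#' aggregate_periods(tibble::tibble(district_id = c("D01", "D01"),
#'                                  birthrate = c(1.0, 1.2)))
aggregate_periods <- function(data, sum_cols = character()) {
  if (!"district_id" %in% names(data)) {
    abort("`data` must have a `district_id` column.")
  }
  num_cols <- names(data)[vapply(data, is.numeric, logical(1))]
  data |>
    summarise(
      across(dplyr::all_of(setdiff(num_cols, sum_cols)), mean),
      across(dplyr::all_of(intersect(sum_cols, num_cols)), sum),
      .by = "district_id"
    )
}
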