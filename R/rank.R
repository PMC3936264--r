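#' Count retained mentions per district and clinic
#'
#' Tabulates mention frequency by (district, hospital). Mentions should
#' already be sentiment-filtered ([filter_sentiment()]). Clinics with zero
#' mentions do not appear. Mentions of hospitals absent from the registry
#' (e.g. clinics discussed online but missing from the official data) are
#' dropped with a message reporting the count.
#'
#' @param mentions Mention tibble with `district_id` and `hospital_id`.
#' @param registry Optional registry; when given, unknown hospital ids are
#'   dropped (and reported) rather than counted.
#' @return A tibble `district_id`, `hospital_id`, `mentions`.
#' @export
count_mentions <- function(mentions, registry = NULL) {
  if (!all(c("district_id", "hospital_id") %in% names(mentions))) {
    abort("`mentions` must have `district_id` and `hospital_id` columns.")
  }
  if (!is.null(registry)) {
    known <- mentions$hospital_id %in% registry$hospital_id
    if (any(!known)) {
      rlang::inform(paste0("Dropping ", sum(!known),
                           " mention(s) of hospitals absent from the registry."))
      mentions <- mentions[known, ]
    }
  }
  mentions |>
    count(.data$district_id, .data$hospital_id, name = "mentions") |>
    arrange(.data$district_id, dplyr::desc(.data$mentions), .data$hospital_id)
}

#' Crowd ranking from mention frequencies
#'
#' Ranks clinics within each district by descending mention frequency:
#' the most-mentioned clinic gets rank 1; ties receive average ranks, so
#' every rank vector sums to n(n+1)/2.
#'
#' @param frequencies Output of [count_mentions()] (a `district_id` column
#'   groups the ranking; without one the whole table is ranked together).
#' @return The input with a `crowd_rank` column.
#' @export
#' @examples
#' crowd_ranking(tibble::tibble(hospital_id = c("a", "b", "c", "d"),
#'                              mentions = c(5, 3, 3, 1)))
crowd_ranking <- function(frequencies) {
  if (nrow(frequencies) == 0) abort("`frequencies` must be nonempty.")
  grp <- intersect("district_id", names(frequencies))
  frequencies |>
    mutate(crowd_rank = rank(-.data$mentions, ties.method = "average"),
           .by = dplyr::all_of(grp))
}

#' Government ranking from antibiotic prescription rates
#'
#' Ranks clinics within each district by ascending antibiotic prescription
#' rate -- the official quality orientation: the lowest prescriber gets
#' rank 1. Ties receive average ranks. Optionally restricted to a subset of
#' clinics (e.g. those mentioned online), in which case ranks are computed
#' within the subset only.
#'
#' @param registry Registry tibble (`hospital_id`, `district_id`,
#'   `antibiotic_rate`).
#' @param district Optional district id(s) to restrict to.
#' @param restrict_to Optional hospital-id subset; unknown ids are an error.
#' @return A tibble `district_id`, `hospital_id`, `antibiotic_rate`,
#'   `gov_rank`.
#' @export
government_ranking <- function(registry, district = NULL, restrict_to = NULL) {
  reg <- registry
  if (!is.null(district)) reg <- reg |> filter(.data$district_id %in% district)
  if (!is.null(restrict_to)) {
    unknown <- setdiff(restrict_to, reg$hospital_id)
    if (length(unknown) > 0) {
      abort(paste0("Unknown hospital id(s): ",
                   paste(head(unknown, 5), collapse = ", ")))
    }
    reg <- reg |> filter(.data$hospital_id %in% restrict_to)
  }
  reg |>
    mutate(gov_rank = rank(.data$antibiotic_rate, ties.method = "average"),
           .by = "district_id") |>
    select("district_id", "hospital_id", "antibiotic_rate", "gov_rank")
}

#' Align crowd and government rankings per district
#'
#' Builds, for every district, the pair of rank vectors over the commonly
#' rankable set: clinics with at least one retained mention. Both rankings
#' are (re)computed within that intersection, so restricting then ranking
#' and ranking then restricting agree. Districts with fewer than `min_n`
#' rankable clinics are flagged `excluded` (congruence is not computable on
#' a single clinic), mirroring the exclusion of sparsely covered districts.
#'
#' @param counts Output of [count_mentions()].
#' @param registry Registry tibble.
#' @param min_n Minimum rankable clinics per district (default 2).
#' @return A tibble with one row per (district, mentioned clinic):
#'   `district_id`, `hospital_id`, `mentions`, `antibiotic_rate`,
#'   `crowd_rank`, `gov_rank`, `n`, `excluded`.
#' @export
align_rankings <- function(counts, registry, min_n = 2L) {
  joined <- counts |>
    inner_join(registry |>
                 select("district_id", "hospital_id", "antibiotic_rate"),
               by = c("district_id", "hospital_id"))
  dropped <- nrow(counts) - nrow(joined)
  if (dropped > 0) {
    rlang::inform(paste0("Dropping ", dropped,
                         " mentioned clinic(s) not rankable in their district."))
  }
  joined |>
    mutate(crowd_rank = rank(-.data$mentions, ties.method = "average"),
           gov_rank = rank(.data$antibiotic_rate, ties.method = "average"),
           n = dplyr::n(),
           .by = "district_id") |>
    mutate(excluded = .data$n < min_n) |>
    arrange(.data$district_id, .data$crowd_rank)
}
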