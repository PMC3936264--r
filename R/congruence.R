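#' Classify rank pairs as concordant, discordant or tied
#'
#' Examines every unordered pair of observations and classifies it as
#' concordant (both rankings order the pair the same way), discordant
#' (opposite orders), tied in x only, tied in y only, or tied in both.
#' These pair counts are the building blocks of Kendall's tau.
#'
#' @param x,y Numeric vectors (typically rank vectors) of equal length >= 2.
#' @return A one-row tibble: `concordant`, `discordant`, `tied_x`,
#'   `tied_y`, `tied_both`, `n`. The five counts always total n(n-1)/2.
#' @export
#' @examples
#' count_pairs(c(1, 2, 3), c(3, 2, 1))
count_pairs <- function(x, y) {
  n <- length(x)
  if (length(y) != n) abort("`x` and `y` must have equal length.")
  if (n < 2) abort("Pair counting needs at least 2 observations.")
  if (anyNA(x) || anyNA(y)) abort("`x` and `y` must not contain NA.")
  ut <- upper.tri(matrix(0, n, n))
  dx <- sign(outer(x, x, "-"))[ut]
  dy <- sign(outer(y, y, "-"))[ut]
  tibble::tibble(
    concordant = sum(dx * dy > 0),
    discordant = sum(dx * dy < 0),
    tied_x = sum(dx == 0 & dy != 0),
    tied_y = sum(dy == 0 & dx != 0),
    tied_both = sum(dx == 0 & dy == 0),
    n = n
  )
}

#' Kendall tau rank correlation
#'
#' Computed from first-principles pair counts. The default tau-b corrects
#' the denominator for ties in either ranking,
#' `(C - D) / sqrt((n0 - nx)(n0 - ny))` with `n0 = n(n-1)/2` and `nx`,
#' `ny` the pair counts tied in x resp. y; frequency-based crowd rankings
#' tie often, and the uncorrected tau-a (`(C - D) / n0`, selectable via
#' `variant = "a"`) deflates magnitudes in that case. Both variants
#' coincide on tie-free data. A ranking with all values tied has an
#' undefined tau-b, returned as `NA` with a warning (not 0, so downstream
#' models drop it explicitly).
#'
#' @param x,y Numeric vectors of equal length >= 2; only their orderings
#'   matter.
#' @param variant `"b"` (tie-corrected, default) or `"a"`.
#' @return Kendall tau in `[-1, 1]`, or `NA` when undefined.
#' @export
#' @examples
#' kendall_tau(c(1, 2, 3), c(1, 3, 2))  # (2 - 1) / 3
kendall_tau <- function(x, y, variant = c("b", "a")) {
  variant <- match.arg(variant)
  pc <- count_pairs(x, y)
  n0 <- pc$n * (pc$n - 1) / 2
  num <- pc$concordant - pc$discordant
  if (variant == "a") return(num / n0)
  nx <- pc$tied_x + pc$tied_both
  ny <- pc$tied_y + pc$tied_both
  den <- sqrt((n0 - nx) * (n0 - ny))
  if (den == 0) {
    warn("Kendall tau undefined: a ranking is completely tied; returning NA.")
    return(NA_real_)
  }
  num / den
}

#' Spearman rho rank correlation
#'
#' The Pearson product-moment correlation applied to the rank vectors,
#' with average ranks on ties. Inputs are re-ranked internally (idempotent
#' when already ranks). A constant ranking has zero rank variance and an
#' undefined rho, returned as `NA` with a warning.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Spearman rho in `[-1, 1]`, or `NA` when undefined.
#' @export
#' @examples
#' spearman_rho(1:4, c(1, 2, 4, 3))  # 1 - 6*2/(4*15) = 0.8
spearman_rho <- function(x, y) {
  n <- length(x)
  if (length(y) != n) abort("`x` and `y` must have equal length.")
  if (n < 2) abort("Spearman rho needs at least 2 observations.")
  if (anyNA(x) || anyNA(y)) abort("`x` and `y` must not contain NA.")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  cx <- rx - mean(rx)
  cy <- ry - mean(ry)
  den <- sqrt(sum(cx^2) * sum(cy^2))
  if (den == 0) {
    warn("Spearman rho undefined: a ranking is completely tied; returning NA.")
    return(NA_real_)
  }
  sum(cx * cy) / den
}

#' Per-district congruence table
#'
#' Computes Kendall tau and Spearman rho between the crowd and government
#' rankings of every non-excluded district, plus the descending rank of
#' each index across districts (ties share the smallest rank, the
#' convention of the emulated study's tables). Districts whose indexes are
#' undefined (a fully tied ranking) carry `NA` and no rank.
#'
#' @param ranking_pairs Output of [align_rankings()].
#' @param tau_variant Passed to [kendall_tau()].
#' @return A tibble with one row per analyzed district: `district_id`, `n`,
#'   `kendall_tau`, `tau_rank`, `spearman_rho`, `rho_rank`.
#' @export
congruence_table <- function(ranking_pairs, tau_variant = c("b", "a")) {
  tau_variant <- match.arg(tau_variant)
  pairs <- ranking_pairs
  if ("excluded" %in% names(pairs)) pairs <- pairs |> filter(!.data$excluded)
  out <- pairs |>
    summarise(
      n = dplyr::n(),
      kendall_tau = if (dplyr::n() >= 2) {
        kendall_tau(.data$crowd_rank, .data$gov_rank, variant = tau_variant)
      } else {
        NA_real_
      },
      spearman_rho = if (dplyr::n() >= 2) {
        spearman_rho(.data$crowd_rank, .data$gov_rank)
      } else {
        NA_real_
      },
      .by = "district_id"
    )
  out |>
    mutate(tau_rank = rank(-.data$kendall_tau, ties.method = "min",
                           na.last = "keep"),
           rho_rank = rank(-.data$spearman_rho, ties.method = "min",
                           na.last = "keep")) |>
    select("district_id", "n", "kendall_tau", "tau_rank",
           "spearman_rho", "rho_rank") |>
    arrange(.data$district_id)
}
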