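#' Reference tallies for the emulated Korean pediatric community setting
#'
#' The simulator's defaults are calibrated to the scale of the real setting it
#' emulates: parents' online health communities in six South Korean
#' metropolitan cities discussing pediatric clinics, compared against the
#' government (HIRA) antibiotic-prescription registry. These functions return
#' the calibration tallies as tibbles so that derived quantities
#' (messages per thread, sentiment shares, tagging fraction, registry size)
#' are always recomputed from the raw counts rather than stored rounded.
#'
#' @return `reference_community_tallies()`: a tibble with one row per
#'   metropolitan community (`community`, `threads`, `messages`).
#'   `reference_sentiment_tallies()`: a one-row tibble with the size of the
#'   sentiment-inspected sample (`sampled`), the total message count
#'   (`messages`), counts of positive-or-neutral (`positive_neutral`) and
#'   negative (`negative`) mentions, and the human-tagged evaluation sample
#'   size (`tagged`). `reference_district_clinics()`: a tibble with one row
#'   per analysis district (`district`, `n_mentioned`) giving the number of
#'   clinics mentioned online; the column sums to the 779 registry clinics.
#' @examples
#' reference_community_tallies() |>
#'   dplyr::mutate(messages_per_thread = messages / threads)
#' @name reference_tallies
NULL

#' @rdname reference_tallies
#' @export
reference_community_tallies <- function() {
  tibble::tribble(
    ~community, ~threads, ~messages,
    "Seoul",     10832L,    54392L,
    "Daegu",      8072L,    47419L,
    "Busan",      5965L,    28910L,
    "Daejeon",    3952L,    22475L,
    "Incheon",     775L,     5184L,
    "Gwangju",    2826L,    15368L
  )
}

#' @rdname reference_tallies
#' @export
reference_sentiment_tallies <- function() {
  tibble::tibble(
    messages = 173748L,
    sampled = 32065L,
    positive_neutral = 29511L,
    negative = 2554L,
    tagged = 9450L
  )
}

#' @rdname reference_tallies
#' @export
reference_district_clinics <- function() {
  tibble::tibble(
    district = c(paste0("S", c(1:22, 24:25)),
                 "Gwangju", "Daegu", "Daejeon", "Busan", "Incheon"),
    n_mentioned = c(14L, 21L, 11L, 15L, 15L, 17L, 11L, 5L, 22L, 10L, 11L,
                    12L, 15L, 13L, 11L, 11L, 10L, 26L, 18L, 15L, 8L, 16L,
                    3L, 12L, 57L, 99L, 53L, 155L, 93L)
  )
}
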