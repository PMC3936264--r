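#' Simulate perceived clinic quality
#'
#' True quality is the negative antibiotic prescription rate (any strictly
#' decreasing transform is rank-equivalent); each district's crowd perceives
#' it through additive Gaussian noise whose SD is the district's
#' [district_noise_sd()]. The perceived-quality ordering is the ground-truth
#' crowd ranking that the message stream realizes.
#'
#' @param registry Output of [sim_registry()].
#' @param demographics Output of [sim_demographics()] covering every
#'   registry district.
#' @param config A [sim_config()].
#' @return A tibble with `hospital_id`, `district_id`, `true_quality`,
#'   `perceived_quality`, `noise_sd`.
#' @export
sim_perceived_quality <- function(registry, demographics, config) {
  validate_sim_config(config)
  missing_d <- setdiff(registry$district_id, demographics$district_id)
  if (length(missing_d) > 0) {
    abort(paste0("Registry districts absent from demographics: ",
                 paste(missing_d, collapse = ", ")))
  }
  withr::local_seed(stream_seed(config$seed, SIM_STREAMS[["corpus"]]))
  sd_tbl <- tibble::tibble(district_id = demographics$district_id,
                           noise_sd = district_noise_sd(demographics, config))
  registry |>
    left_join(sd_tbl, by = "district_id") |>
    mutate(true_quality = -.data$antibiotic_rate,
           perceived_quality = .data$true_quality +
             rnorm(dplyr::n(), 0, .data$noise_sd)) |>
    select("hospital_id", "district_id", "true_quality",
           "perceived_quality", "noise_sd")
}

#' Allocate mention counts over a district's clinics
#'
#' Converts perceived qualities into per-clinic mention counts: softmax
#' shares at the configured temperature, largest-remainder rounding of
#' `n_slots` total mentions, a cap of `n_cap` per clinic (each mention must
#' live in a distinct message), and a strict-monotone repair that makes
#' counts strictly decreasing in perceived quality among mentioned clinics.
#' The allocation is deterministic given the perceived qualities, so the
#' crowd ranking read off the message stream reproduces the perceived
#' ordering exactly -- in the noiseless limit the crowd and government
#' rankings then agree identically rather than only asymptotically.
#'
#' @param perceived Numeric vector of perceived qualities.
#' @param n_slots Total mentions to allocate.
#' @param n_cap Maximum mentions per clinic.
#' @param temperature Softmax temperature (quality units).
#' @return Integer vector of counts, same length as `perceived`.
#' @export
allocate_mention_counts <- function(perceived, n_slots, n_cap = Inf,
                                    temperature = 0.2) {
  k <- length(perceived)
  if (k == 0L || n_slots <= 0) return(integer(k))
  z <- perceived / temperature
  p <- exp(z - max(z))
  p <- p / sum(p)
  q <- n_slots * p
  cnt <- floor(q)
  rem <- round(n_slots - sum(cnt))
  if (rem > 0) {
    topup <- order(-(q - cnt), -perceived)[seq_len(rem)]
    cnt[topup] <- cnt[topup] + 1
  }
  cnt <- pmin(cnt, n_cap)
  prev <- Inf
  for (i in order(-perceived)) {
    cnt[i] <- max(0, min(cnt[i], prev - 1))
    prev <- cnt[i]
  }
  as.integer(cnt)
}

#' Simulate a district-segmented community message corpus
#'
#' Generates threads (a request root plus Poisson replies), samples message
#' sentiment from the configured mix, and plants hospital mentions: each
#' district's positive/neutral candidate replies carry mention counts
#' allocated by [allocate_mention_counts()] over perceived quality, and
#' additional negative mentions (targeting the configured negative share of
#' all mentions) are planted in negative replies, so the sentiment filter
#' recovers exactly the designed counts. Mentions are rendered through a
#' uniformly sampled dictionary surface form and corrupted out of dictionary
#' with probability `corruption_rate`. Every planted mention is recorded in
#' the gold standard regardless of corruption.
#'
#' @param registry,aliases,demographics,config Outputs of [sim_registry()],
#'   [sim_aliases()], [sim_demographics()] and the shared [sim_config()].
#' @return A list of class `sim_corpus` with tibbles `threads` (`thread_id`,
#'   `district_id`, `qualifying`), `messages` (`message_id`, `thread_id`,
#'   `district_id`, `is_reply`, `text`, `sentiment`), `gold` (`message_id`,
#'   `hospital_id`, `district_id`, `surface_form`, `corrupted`,
#'   `sentiment`), `perceived` (from [sim_perceived_quality()]) and
#'   `mention_counts` (`district_id`, `hospital_id`, designed non-negative
#'   mention count).
#' @export
sim_corpus <- function(registry, aliases, demographics, config) {
  validate_sim_config(config)
  perceived <- sim_perceived_quality(registry, demographics, config)
  withr::local_seed(stream_seed(config$seed, SIM_STREAMS[["messages"]]))

  districts <- demographics$district_id
  n_threads <- length(districts) * config$threads_per_district

  threads <- tibble::tibble(
    thread_id = sprintf("T%06d", seq_len(n_threads)),
    district_id = rep(districts, each = config$threads_per_district),
    qualifying = runif(n_threads) < config$qualifying_fraction
  )
  n_replies <- rpois(n_threads, max(0, config$messages_per_thread_mean - 1))

  messages <- tibble::tibble(
    thread_idx = c(seq_len(n_threads), rep(seq_len(n_threads), n_replies)),
    is_reply = rep(c(FALSE, TRUE), c(n_threads, sum(n_replies)))
  ) |>
    arrange(.data$thread_idx, .data$is_reply) |>
    mutate(
      message_id = sprintf("M%07d", dplyr::row_number()),
      thread_id = threads$thread_id[.data$thread_idx],
      district_id = threads$district_id[.data$thread_idx],
      qualifying = threads$qualifying[.data$thread_idx],
      sentiment = sample(names(config$sentiment_mix), dplyr::n(),
                         replace = TRUE, prob = config$sentiment_mix)
    )

  mention_rows <- plant_mentions(messages, perceived, config)
  mention_rows <- render_mentions(mention_rows, registry, aliases, config)

  messages$text <- compose_texts(messages, mention_rows)
  gold <- mention_rows |>
    transmute(message_id = messages$message_id[.data$msg_idx],
              hospital_id = .data$hospital_id,
              district_id = .data$district_id,
              surface_form = .data$surface_form,
              corrupted = .data$corrupted,
              sentiment = .data$sentiment)

  counts <- mention_rows |>
    filter(.data$sentiment != "negative") |>
    count(.data$district_id, .data$hospital_id, name = "mentions")

  structure(
    list(threads = threads |> select("thread_id", "district_id", "qualifying"),
         messages = messages |>
           select("message_id", "thread_id", "district_id", "is_reply",
                  "text", "sentiment"),
         gold = gold,
         perceived = perceived,
         mention_counts = counts,
         config = config),
    class = "sim_corpus"
  )
}

#' @export
print.sim_corpus <- function(x, ...) {
  cat(sprintf("<sim_corpus> %d threads, %d messages, %d gold mentions in %d districts\n",
              nrow(x$threads), nrow(x$messages), nrow(x$gold),
              dplyr::n_distinct(x$threads$district_id)))
  invisible(x)
}

# Choose which messages carry which hospital mentions. Returns row indices
# into `messages` plus hospital/district/sentiment columns.
plant_mentions <- function(messages, perceived, config) {
  p_neg <- config$sentiment_mix[["negative"]]
  per_district <- lapply(unique(messages$district_id), function(d) {
    pq <- perceived |> filter(.data$district_id == d)
    cand <- which(messages$district_id == d & messages$is_reply &
                    messages$qualifying)
    good <- cand[messages$sentiment[cand] != "negative"]
    neg <- cand[messages$sentiment[cand] == "negative"]
    n_slots <- round(config$mentions_per_reply * length(good))
    cnt <- allocate_mention_counts(pq$perceived_quality, n_slots,
                                   n_cap = length(good),
                                   temperature = config$softmax_temperature)
    good_rows <- if (sum(cnt) > 0) {
      tibble::tibble(
        msg_idx = unlist(lapply(which(cnt > 0), function(i) {
          good[sample.int(length(good), cnt[i])]
        })),
        hospital_id = rep(pq$hospital_id[cnt > 0], cnt[cnt > 0])
      )
    } else {
      tibble::tibble(msg_idx = integer(), hospital_id = character())
    }
    n_neg_target <- if (p_neg < 1) round(sum(cnt) * p_neg / (1 - p_neg)) else 0L
    neg_rows <- if (n_neg_target > 0 && length(neg) > 0) {
      z <- pq$perceived_quality / config$softmax_temperature
      w <- exp(z - max(z))
      cells_msg <- rep(neg, each = nrow(pq))
      cells_hosp <- rep(pq$hospital_id, times = length(neg))
      cells_w <- rep(w, times = length(neg))
      take <- sample(length(cells_msg), min(n_neg_target, length(cells_msg)),
                     prob = cells_w)
      tibble::tibble(msg_idx = cells_msg[take], hospital_id = cells_hosp[take])
    } else {
      tibble::tibble(msg_idx = integer(), hospital_id = character())
    }
    bind_rows(good_rows, neg_rows) |> mutate(district_id = d)
  })
  bind_rows(per_district) |>
    mutate(sentiment = messages$sentiment[.data$msg_idx])
}

# Render each planted mention through a sampled dictionary surface form,
# corrupting a fraction beyond every fuzzy-match threshold.
render_mentions <- function(mention_rows, registry, aliases, config) {
  if (nrow(mention_rows) == 0) {
    return(mention_rows |> mutate(surface_form = character(),
                                  corrupted = logical()))
  }
  canon_of <- setNames(registry$canonical_name, registry$hospital_id)
  mention_rows <- mention_rows |>
    group_by(.data$hospital_id) |>
    mutate(surface_form = {
      forms <- aliases$entries[[canon_of[[.data$hospital_id[1]]]]]
      forms[sample.int(length(forms), dplyr::n(), replace = TRUE)]
    }) |>
    ungroup()
  corrupted <- runif(nrow(mention_rows)) < config$corruption_rate
  if (any(corrupted)) {
    idx <- which(corrupted)
    extra <- alias_distance_threshold(mention_rows$surface_form[idx]) + 2L
    mention_rows$surface_form[idx] <- vapply(seq_along(idx), function(k) {
      corrupt_form(mention_rows$surface_form[idx[k]], extra[k])
    }, character(1))
  }
  mention_rows$corrupted <- corrupted
  mention_rows
}

# Assemble message texts: chatter fillers, planted mention forms, and the
# domain/request keywords on qualifying roots, in shuffled token order.
compose_texts <- function(messages, mention_rows) {
  n_msg <- nrow(messages)
  kf <- sample(3:8, n_msg, replace = TRUE)
  fillers <- sample(FILLER_WORDS, sum(kf), replace = TRUE)
  fill_list <- split(fillers, factor(rep(seq_len(n_msg), kf),
                                     levels = seq_len(n_msg)))
  extra <- vector("list", n_msg)
  if (nrow(mention_rows) > 0) {
    by_msg <- split(mention_rows$surface_form, mention_rows$msg_idx)
    extra[as.integer(names(by_msg))] <- by_msg
  }
  root_kw <- which(!messages$is_reply & messages$qualifying)
  for (i in root_kw) {
    extra[[i]] <- c(extra[[i]], DOMAIN_KEYWORD_DEFAULT, REQUEST_KEYWORD_DEFAULT)
  }
  vapply(seq_len(n_msg), function(i) {
    toks <- c(fill_list[[i]], extra[[i]])
    paste(sample(toks), collapse = " ")
  }, character(1))
}

#' Simulate a complete study with one call
#'
#' Convenience wrapper chaining [sim_demographics()], [sim_registry()]
#' (clinic counts taken from the demographics so registry and covariates
#' agree), [sim_aliases()] and [sim_corpus()] under one seed.
#'
#' @param config A [sim_config()].
#' @param clinic_source `"demographics"` (default) sizes each district's
#'   registry from the simulated demographics' `n_clinics`, keeping the
#'   covariates and registry consistent; `"config"` uses
#'   `config$hospitals_per_district` directly (handy for small fixtures).
#' @return A list with `config`, `demographics`, `registry`, `aliases`, and
#'   the `sim_corpus` components (`threads`, `messages`, `gold`,
#'   `perceived`, `mention_counts`).
#' @export
#' @examples
#' study <- sim_study(sim_config(n_districts = 2, threads_per_district = 20,
#'                               seed = 42))
#' study$mention_counts
sim_study <- function(config, clinic_source = c("demographics", "config")) {
  clinic_source <- match.arg(clinic_source)
  demographics <- sim_demographics(config)
  registry <- if (clinic_source == "demographics") {
    sim_registry(config, demographics = demographics)
  } else {
    sim_registry(config)
  }
  aliases <- sim_aliases(registry, config)
  corpus <- sim_corpus(registry, aliases, demographics, config)
  c(list(config = config, demographics = demographics, registry = registry,
         aliases = aliases),
    corpus[c("threads", "messages", "gold", "perceived", "mention_counts")])
}

#' Simulate ranking-level congruence data without message text
#'
#' The count-level variant of the generator for Monte-Carlo studies of the
#' congruence regression: demographics, registry, perceived quality and
#' deterministic mention counts are produced exactly as in [sim_corpus()],
#' but the mention budget is set to its expected value and no message
#' stream is rendered. Orders of magnitude faster when only the per-district
#' rankings matter (e.g. sign-recovery replications).
#'
#' @param config A [sim_config()].
#' @return A list with `demographics`, `registry`, `perceived`, and
#'   `mention_counts` (tibble of `district_id`, `hospital_id`, `mentions`,
#'   zero-count clinics omitted).
#' @export
sim_congruence_data <- function(config) {
  validate_sim_config(config)
  demographics <- sim_demographics(config)
  registry <- sim_registry(config, demographics = demographics, name_sep = 1L)
  perceived <- sim_perceived_quality(registry, demographics, config)
  exp_replies <- config$threads_per_district *
    max(0, config$messages_per_thread_mean - 1) *
    config$qualifying_fraction * (1 - config$sentiment_mix[["negative"]])
  n_slots <- round(config$mentions_per_reply * exp_replies)
  counts <- perceived |>
    group_by(.data$district_id) |>
    mutate(mentions = allocate_mention_counts(
      .data$perceived_quality, n_slots, n_cap = ceiling(exp_replies),
      temperature = config$softmax_temperature)) |>
    ungroup() |>
    filter(.data$mentions > 0) |>
    select("district_id", "hospital_id", "mentions")
  list(demographics = demographics, registry = registry,
       perceived = perceived, mention_counts = counts)
}
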