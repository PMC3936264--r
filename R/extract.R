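#' Strip markup from raw community pages
#'
#' Removes HTML tags and non-textual content (script and style blocks,
#' attributes) from crawled pages, returning visible text only. Plain-text
#' input passes through unchanged; malformed markup is handled leniently.
#'
#' @param x Character vector of raw HTML or plain text.
#' @return Character vector of visible text.
#' @export
#' @examples
#' strip_markup("<p>recommend <b>hanbyeol</b> clinic</p>")
strip_markup <- function(x) {
  vapply(x, function(s) {
    if (is.na(s) || !grepl("<", s, fixed = TRUE)) return(s)
    out <- tryCatch({
      doc <- xml2::read_html(s)
      xml2::xml_remove(xml2::xml_find_all(doc, ".//script | .//style"))
      # join text nodes with spaces so adjacent block elements stay separated
      paste(xml2::xml_text(xml2::xml_find_all(doc, ".//text()")),
            collapse = " ")
    }, error = function(e) gsub("<[^>]*>", " ", s))
    stringr::str_squish(out)
  }, character(1), USE.NAMES = FALSE)
}

#' Select candidate recommendation replies
#'
#' Keeps the reply messages of threads whose root contains both a domain
#' keyword and a request keyword (case-insensitive substring match) --
#' users' responses to others' requests for hospital recommendations.
#'
#' @param messages Message tibble with `message_id`, `thread_id`,
#'   `is_reply`, `text`.
#' @param domain_keywords,request_keywords Keyword sets; a root qualifies if
#'   it contains at least one of each.
#' @param threads Optional thread tibble; when given, messages referencing
#'   unknown threads raise an error.
#' @return The qualifying reply messages (same columns as `messages`).
#' @export
filter_candidates <- function(messages,
                              domain_keywords = DOMAIN_KEYWORD_DEFAULT,
                              request_keywords = REQUEST_KEYWORD_DEFAULT,
                              threads = NULL) {
  if (!is.null(threads)) {
    unknown <- setdiff(messages$thread_id, threads$thread_id)
    if (length(unknown) > 0) {
      abort(paste0("Messages reference unknown threads: ",
                   paste(head(unknown, 5), collapse = ", ")))
    }
  }
  contains_any <- function(text, kws) {
    hit <- rep(FALSE, length(text))
    for (kw in kws) {
      hit <- hit | stringr::str_detect(text, stringr::fixed(tolower(kw)))
    }
    hit
  }
  roots <- messages |> filter(!.data$is_reply)
  root_lc <- tolower(roots$text)
  qualifying <- roots$thread_id[contains_any(root_lc, domain_keywords) &
                                  contains_any(root_lc, request_keywords)]
  messages |>
    filter(.data$is_reply, .data$thread_id %in% qualifying)
}

# Matching table shared by normalize_expression and extract_mentions.
# Tie-breaking among equal distances: longer alias first (more specific),
# then lexicographically smallest canonical name.
dict_match_table <- function(dictionary, threshold = NULL) {
  if (!inherits(dictionary, "alias_dictionary")) {
    abort("`dictionary` must be an `alias_dictionary`.")
  }
  tbl <- as_tibble(dictionary) |>
    mutate(form_lc = stringr::str_squish(tolower(.data$surface_form)))
  if (nrow(tbl) == 0) abort("`dictionary` is empty.")
  tbl$cutoff <- if (is.null(threshold)) {
    alias_distance_threshold(tbl$form_lc)
  } else {
    rep_len(as.integer(threshold), nrow(tbl))
  }
  tbl$priority <- order(order(-nchar(tbl$form_lc), tbl$canonical_name))
  tbl
}

#' Stepwise expression normalization
#'
#' Resolves raw hospital expressions to canonical names through the
#' stepwise procedure: (1) exact canonical-name match, (2) exact
#' surface-form match, (3) minimum edit-distance surface-form match subject
#' to the per-alias threshold. Matching is case-insensitive after
#' whitespace normalization. Ties at the minimal distance prefer the longer
#' (more specific) alias, then the lexicographically smallest canonical
#' name. Expressions whose minimum distance exceeds the threshold -- and
#' empty expressions -- resolve to `NA`.
#'
#' @param surface Character vector of raw expressions.
#' @param dictionary An [alias_dictionary()].
#' @param threshold `NULL` for the default per-alias rule
#'   ([alias_distance_threshold()]) or a single integer used for every
#'   alias (0 forces exact-only matching).
#' @return A tibble with one row per input: `surface_form`,
#'   `canonical_name` (`NA` when unresolved), `hospital_id` (when the
#'   dictionary carries ids), `distance`.
#' @export
#' @examples
#' dict <- alias_dictionary(list("hanbyeol pediatric clinic" = "hanbyeol"))
#' normalize_expression(c("hanbyeol", "hanbyeol pediatric clinics"), dict)
normalize_expression <- function(surface, dictionary, threshold = NULL) {
  mt <- dict_match_table(dictionary, threshold)
  span_lc <- stringr::str_squish(tolower(surface))
  res <- resolve_spans(unique(span_lc), mt)
  out <- res[match(span_lc, res$span), ]
  tibble::tibble(surface_form = surface,
                 canonical_name = out$canonical_name,
                 hospital_id = out$hospital_id,
                 distance = out$distance)
}

# Resolve unique lowercased spans against a dict_match_table.
resolve_spans <- function(spans, mt) {
  canonical_name <- rep(NA_character_, length(spans))
  distance <- rep(NA_integer_, length(spans))

  nonempty <- nzchar(spans)
  # step 1: exact canonical
  canon_tbl <- mt |> filter(.data$is_canonical)
  i1 <- match(spans, canon_tbl$form_lc)
  hit1 <- nonempty & !is.na(i1)
  canonical_name[hit1] <- canon_tbl$canonical_name[i1[hit1]]
  distance[hit1] <- 0L

  # step 2: exact alias (deterministic winner among duplicated forms)
  ex_tbl <- mt |>
    arrange(.data$form_lc, dplyr::desc(.data$is_canonical),
            .data$priority) |>
    distinct(.data$form_lc, .keep_all = TRUE)
  todo <- nonempty & is.na(canonical_name)
  i2 <- match(spans[todo], ex_tbl$form_lc)
  hit2 <- !is.na(i2)
  canonical_name[todo][hit2] <- ex_tbl$canonical_name[i2[hit2]]
  distance[todo][hit2] <- 0L

  # step 3: minimum edit distance within threshold
  todo <- nonempty & is.na(canonical_name)
  if (any(todo) && any(mt$cutoff > 0)) {
    fz <- best_fuzzy_match(spans[todo], mt$form_lc,
                           as.integer(mt$cutoff), as.integer(mt$priority))
    hit3 <- !is.na(fz$index)
    canonical_name[todo][hit3] <- mt$canonical_name[fz$index[hit3]]
    distance[todo][hit3] <- fz$distance[hit3]
  }

  hospital_id <- rep(NA_character_, length(spans))
  if ("hospital_id" %in% names(mt)) {
    id_of <- mt |> distinct(.data$canonical_name, .data$hospital_id)
    hospital_id <- id_of$hospital_id[match(canonical_name, id_of$canonical_name)]
  }
  tibble::tibble(span = spans, canonical_name = canonical_name,
                 hospital_id = hospital_id, distance = distance)
}

# Whitespace tokens (lowercased, edge punctuation stripped) and their
# n-gram spans up to `max_ngram` tokens.
message_spans <- function(texts, max_ngram = 5L) {
  toks <- strsplit(stringr::str_squish(tolower(texts)), " ", fixed = TRUE)
  toks <- lapply(toks, function(tk) {
    tk <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", tk)
    tk[nzchar(tk)]
  })
  tok <- unlist(toks, use.names = FALSE)
  msg <- rep(seq_along(toks), lengths(toks))
  out_msg <- list()
  out_span <- list()
  for (n in seq_len(max_ngram)) {
    if (length(tok) < n) break
    start <- seq_len(length(tok) - n + 1L)
    start <- start[msg[start] == msg[start + n - 1L]]
    if (length(start) == 0) next
    span <- tok[start]
    for (j in seq_len(n - 1L)) span <- paste(span, tok[start + j])
    out_msg[[n]] <- msg[start]
    out_span[[n]] <- span
  }
  tibble::tibble(msg_row = unlist(out_msg),
                 span = unlist(out_span))
}

#' Extract hospital mentions from candidate messages
#'
#' Tokenizes each message on whitespace, forms n-gram spans up to
#' `max_ngram` tokens, resolves every span through
#' [normalize_expression()]'s stepwise procedure, and emits mention
#' records. By default identical (message, hospital) pairs are collapsed to
#' one record keeping the smallest distance (message-level counting, which
#' damps single-user repetition); set `dedupe = FALSE` for
#' occurrence-level records retaining every matched span.
#'
#' @param messages Candidate message tibble (`message_id`, `text`, and
#'   optionally `district_id`, `sentiment`, carried through).
#' @param dictionary An [alias_dictionary()].
#' @param threshold As in [normalize_expression()].
#' @param max_ngram Longest span, in tokens.
#' @param dedupe Collapse to one record per (message, hospital)?
#' @return A tibble of mention records: `message_id`, `hospital_id`,
#'   `canonical_name`, `surface_form` (the span as matched), `distance`,
#'   plus `district_id`/`sentiment` when present in `messages`.
#' @export
extract_mentions <- function(messages, dictionary, threshold = NULL,
                             max_ngram = 5L, dedupe = TRUE) {
  mt <- dict_match_table(dictionary, threshold)
  empty <- tibble::tibble(message_id = character(),
                          hospital_id = character(),
                          canonical_name = character(),
                          surface_form = character(),
                          distance = integer())
  if (nrow(messages) == 0) return(empty)
  spans <- message_spans(messages$text, max_ngram)
  if (nrow(spans) == 0) return(empty)
  res <- resolve_spans(unique(spans$span), mt)
  res <- res |> filter(!is.na(.data$canonical_name))
  hits <- spans |>
    inner_join(res, by = "span") |>
    transmute(msg_row = .data$msg_row,
              hospital_id = .data$hospital_id,
              canonical_name = .data$canonical_name,
              surface_form = .data$span,
              distance = .data$distance)
  if (dedupe && nrow(hits) > 0) {
    hits <- hits |>
      arrange(.data$msg_row, .data$canonical_name, .data$distance,
              dplyr::desc(nchar(.data$surface_form))) |>
      distinct(.data$msg_row, .data$canonical_name, .keep_all = TRUE)
  }
  carry <- intersect(c("district_id", "sentiment"), names(messages))
  out <- hits |>
    mutate(message_id = messages$message_id[.data$msg_row])
  for (col in carry) out[[col]] <- messages[[col]][hits$msg_row]
  out |>
    select("message_id", "hospital_id", "canonical_name", "surface_form",
           "distance", dplyr::all_of(carry))
}

#' Filter mentions by sentiment
#'
#' Retains positive, neutral and ambiguous mentions (ambiguous -- positive
#' and negative coexisting -- is treated as neutral) and drops negative
#' mentions, which are excluded from the crowdsourced quality measure.
#'
#' @param mentions Mention tibble with a `sentiment` column.
#' @param unlabeled `"keep"` (default) retains mentions with missing or
#'   `"unlabeled"` sentiment; `"error"` fails on them.
#' @return The retained mentions.
#' @export
filter_sentiment <- function(mentions, unlabeled = c("keep", "error")) {
  unlabeled <- match.arg(unlabeled)
  if (!"sentiment" %in% names(mentions)) {
    abort("`mentions` must have a `sentiment` column.")
  }
  is_unlabeled <- is.na(mentions$sentiment) | mentions$sentiment == "unlabeled"
  if (unlabeled == "error" && any(is_unlabeled)) {
    abort(paste0(sum(is_unlabeled), " mention(s) have unlabeled sentiment."))
  }
  mentions |>
    filter(is_unlabeled | .data$sentiment %in% c("positive", "neutral",
                                                 "ambiguous"))
}

#' Evaluate extraction against a gold standard
#'
#' Samples a fraction of messages (mirroring a human-tagging protocol) and
#' scores predicted mentions against gold mention sets at the (message,
#' hospital) level: precision = correct predicted / all predicted, recall =
#' correct predicted / all gold, F1 = 2PR/(P+R) (0 when P+R = 0; a metric
#' with an empty denominator is 0 unless its reference set is also empty,
#' in which case it is vacuously 1).
#'
#' @param predicted Mention tibble (`message_id`, `hospital_id`).
#' @param gold Gold tibble (`message_id`, `hospital_id`).
#' @param sample_fraction Fraction of messages to score, in (0, 1].
#' @param seed Integer seed for the message sample (required when
#'   `sample_fraction < 1`).
#' @return A one-row tibble: `precision`, `recall`, `f1`, `n_messages`,
#'   `n_predicted`, `n_gold`.
#' @export
evaluate_extraction <- function(predicted, gold, sample_fraction = 1,
                                seed = NULL) {
  if (sample_fraction <= 0 || sample_fraction > 1) {
    abort("`sample_fraction` must lie in (0, 1].")
  }
  ids <- union(unique(predicted$message_id), unique(gold$message_id))
  if (length(ids) == 0) abort("Empty evaluation sample: no messages to score.")
  ids <- sort(ids)
  if (sample_fraction < 1) {
    if (is.null(seed)) abort("`seed` is required when subsampling messages.")
    withr::local_seed(stream_seed(seed, SIM_STREAMS[["evaluation"]]))
    ids <- sample(ids, max(1L, ceiling(sample_fraction * length(ids))))
  }
  pred <- predicted |>
    filter(.data$message_id %in% ids) |>
    distinct(.data$message_id, .data$hospital_id)
  gld <- gold |>
    filter(.data$message_id %in% ids) |>
    distinct(.data$message_id, .data$hospital_id)
  tp <- nrow(inner_join(pred, gld, by = c("message_id", "hospital_id")))
  precision <- if (nrow(pred) > 0) tp / nrow(pred) else as.numeric(nrow(gld) == 0)
  recall <- if (nrow(gld) > 0) tp / nrow(gld) else as.numeric(nrow(pred) == 0)
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  tibble::tibble(precision = precision, recall = recall, f1 = f1,
                 n_messages = length(ids), n_predicted = nrow(pred),
                 n_gold = nrow(gld))
}
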