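#' Simulate a hospital registry
#'
#' Draws `hospitals_per_district` pediatric clinics per district with unique
#' canonical names, an antibiotic prescription rate per clinic (the inverse
#' quality index: lower rate = better care) from the configured Beta
#' distribution, and a doctor head count. Canonical names are built from
#' well-separated romanized base words plus the suffix "pediatric clinic",
#' so distinct clinics are never confusable within the fuzzy-match
#' thresholds used downstream.
#'
#' @param config A [sim_config()].
#' @param demographics Optional output of [sim_demographics()]; when given,
#'   each district's clinic count is taken from its `n_clinics` and doctor
#'   counts are drawn around its `doctors_per_clinic` target, keeping the
#'   registry and the covariates mutually consistent.
#' @param name_sep Minimum pairwise Levenshtein separation of clinic base
#'   names (default 4, which keeps distinct clinics outside each other's
#'   fuzzy-match reach when the registry feeds a text corpus; 1 means
#'   uniqueness only, sufficient -- and much faster -- when no message text
#'   will be rendered).
#' @return A tibble with one row per clinic: `hospital_id`, `canonical_name`,
#'   `district_id`, `antibiotic_rate`, `n_doctors`.
#' @export
#' @examples
#' sim_registry(sim_config(n_districts = 2, hospitals_per_district = 3, seed = 1))
sim_registry <- function(config, demographics = NULL, name_sep = 4L) {
  validate_sim_config(config)
  withr::local_seed(stream_seed(config$seed, SIM_STREAMS[["registry"]]))

  n_d <- config$n_districts
  counts <- rep_len(config$hospitals_per_district, n_d)
  doctor_target <- rep_len(config$covariate_means[["doctors_per_clinic"]], n_d)
  if (!is.null(demographics)) {
    stopifnot(nrow(demographics) == n_d)
    counts <- demographics$n_clinics
    doctor_target <- demographics$doctors_per_clinic
  }
  total <- sum(counts)
  bases <- random_base_names(total, min_sep = name_sep)
  district_ids <- sprintf("D%02d", seq_len(n_d))

  tibble::tibble(
    hospital_id = sprintf("H%04d", seq_len(total)),
    base_name = bases,
    canonical_name = paste(bases, "pediatric clinic"),
    district_id = rep(district_ids, counts),
    antibiotic_rate = rbeta(total, config$rate_shape1, config$rate_shape2),
    n_doctors = 1L + rpois(total, pmax(0, rep(doctor_target, counts) - 1))
  )
}

#' Simulate an alias dictionary for a registry
#'
#' Each canonical name always maps to itself; with probabilities tuned so the
#' mean set size equals `alias_mean`, it additionally receives an
#' abbreviation (base prefix + "pc"), a truncation (the bare base word), and
#' a misspelling at Levenshtein distance at most `typo_max_distance` from the
#' base. The dictionary is then pruned for unambiguity: any surface form
#' claimed by two clinics, any form within the fuzzy-match threshold of
#' another clinic's form, and any form within distance 2 of the chatter or
#' keyword lexicon is dropped (canonical names are never dropped). With
#' `alias_mean = 1` every set is just the canonical name.
#'
#' @param registry Output of [sim_registry()].
#' @param config A [sim_config()].
#' @return An [alias_dictionary()].
#' @export
sim_aliases <- function(registry, config) {
  validate_sim_config(config)
  if (nrow(registry) == 0) abort("`registry` must be nonempty.")
  withr::local_seed(stream_seed(config$seed, SIM_STREAMS[["aliases"]]))

  extras_mean <- config$alias_mean - 1
  p_abbrev <- min(1, extras_mean * 0.4)
  p_trunc <- min(1, extras_mean * 0.4)
  p_typo <- min(1, extras_mean * 0.2)

  bases <- if ("base_name" %in% names(registry)) {
    registry$base_name
  } else {
    stringr::str_remove(registry$canonical_name, " pediatric clinic$")
  }

  entries <- vector("list", nrow(registry))
  for (i in seq_len(nrow(registry))) {
    forms <- registry$canonical_name[i]
    base <- bases[i]
    if (runif(1) < p_abbrev) {
      forms <- c(forms, paste0(substr(base, 1L, 4L), "pc"))
    }
    if (runif(1) < p_trunc) forms <- c(forms, base)
    if (runif(1) < p_typo) {
      forms <- c(forms, corrupt_form(base, max(1L, config$typo_max_distance)))
    }
    entries[[i]] <- unique(forms)
  }
  names(entries) <- registry$canonical_name

  entries <- prune_alias_entries(entries)
  alias_dictionary(entries,
                   canonical_ids = setNames(registry$hospital_id,
                                            registry$canonical_name))
}

# Drop non-canonical surface forms that would make exact matching
# ambiguous (duplicates across clinics) or collide with the chatter /
# keyword lexicon (within distance 2, inside any fuzzy threshold). Fuzzy
# near-misses between distinct clinics' forms are left in -- exact matches
# always take precedence and fuzzy ties break deterministically.
prune_alias_entries <- function(entries) {
  canon <- names(entries)
  flat <- tibble::tibble(
    canonical = rep(canon, lengths(entries)),
    form = unlist(entries, use.names = FALSE)
  ) |>
    mutate(is_canonical = .data$form == .data$canonical)

  dup <- flat |>
    count(.data$form) |>
    filter(.data$n > 1L) |>
    pull(.data$form)
  flat <- flat |> filter(.data$is_canonical | !(.data$form %in% dup))

  lex <- alias_safety_lexicon()
  near_lex <- apply(adist(flat$form, lex), 1L, min) <= 2L
  flat <- flat |> filter(.data$is_canonical | !near_lex)

  split(flat$form, factor(flat$canonical, levels = canon))
}
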