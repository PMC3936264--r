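#' Pipeline configuration
#'
#' Collects the file paths and analysis options of a full run. The object
#' round-trips through JSON ([write_pipeline_config()] /
#' [read_pipeline_config()]) unchanged.
#'
#' @param registry,aliases,corpus,demographics Paths to the input registry
#'   CSV, alias JSON, corpus JSONL and demographics CSV.
#' @param gold Optional path to a gold JSONL for extraction evaluation.
#' @param out_dir Output directory (created if absent).
#' @param threshold Extraction distance threshold (`NULL` = per-alias rule).
#' @param tau_variant `"b"` or `"a"`.
#' @param min_district_n Minimum rankable clinics per district.
#' @param sentiment_unlabeled `"keep"` or `"error"`.
#' @param eval_sample_fraction Message fraction scored when a gold file is
#'   given; the default mirrors a 5.44% human-tagging protocol.
#' @param domain_keywords,request_keywords Candidate-filter keyword sets.
#' @param seed Integer seed (evaluation subsampling; recorded in provenance).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(registry, aliases, corpus, demographics,
                            gold = NULL, out_dir = ".",
                            threshold = NULL,
                            tau_variant = c("b", "a"),
                            min_district_n = 2L,
                            sentiment_unlabeled = c("keep", "error"),
                            eval_sample_fraction = 0.0544,
                            domain_keywords = DOMAIN_KEYWORD_DEFAULT,
                            request_keywords = REQUEST_KEYWORD_DEFAULT,
                            seed = 1L) {
  structure(list(registry = registry, aliases = aliases, corpus = corpus,
                 demographics = demographics, gold = gold, out_dir = out_dir,
                 threshold = threshold,
                 tau_variant = match.arg(tau_variant),
                 min_district_n = as.integer(min_district_n),
                 sentiment_unlabeled = match.arg(sentiment_unlabeled),
                 eval_sample_fraction = eval_sample_fraction,
                 domain_keywords = domain_keywords,
                 request_keywords = request_keywords,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$tau_variant <- raw$tau_variant %||% "b"
  raw$sentiment_unlabeled <- raw$sentiment_unlabeled %||% "keep"
  do.call(pipeline_config, raw[!vapply(raw, is.null, logical(1))])
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("Pipeline stage `", stage, "` failed: ",
                 conditionMessage(e)))
  })
}

#' Run the congruence analysis on in-memory data
#'
#' Chains candidate filtering, mention extraction, sentiment filtering,
#' per-district rank alignment, congruence statistics, and the
#' sociodemographic regression, and (when a gold standard is supplied)
#' extraction evaluation. Each stage's record count is logged in the run
#' report; any stage failure aborts naming the stage.
#'
#' @param registry,aliases,messages,demographics In-memory inputs
#'   (tibbles / an [alias_dictionary()]).
#' @param gold Optional gold mention tibble.
#' @param threshold,tau_variant,min_district_n,sentiment_unlabeled As in
#'   [pipeline_config()].
#' @param eval_sample_fraction,domain_keywords,request_keywords,seed As in
#'   [pipeline_config()].
#' @return A list of class `congruence_study`: `mentions`, `retained`,
#'   `ranking`, `congruence`, `features`, `fit_tau`, `fit_rho`,
#'   `correlations`, `evaluation` (or `NULL`), `report`.
#' @export
run_congruence_study <- function(registry, aliases, messages, demographics,
                                 gold = NULL,
                                 threshold = NULL,
                                 tau_variant = c("b", "a"),
                                 min_district_n = 2L,
                                 sentiment_unlabeled = c("keep", "error"),
                                 eval_sample_fraction = 0.0544,
                                 domain_keywords = DOMAIN_KEYWORD_DEFAULT,
                                 request_keywords = REQUEST_KEYWORD_DEFAULT,
                                 seed = 1L) {
  tau_variant <- match.arg(tau_variant)
  sentiment_unlabeled <- match.arg(sentiment_unlabeled)

  candidates <- run_stage("filter_candidates",
                          filter_candidates(messages, domain_keywords,
                                            request_keywords))
  mentions <- run_stage("extract_mentions",
                        extract_mentions(candidates, aliases, threshold))
  retained <- run_stage("filter_sentiment",
                        filter_sentiment(mentions, sentiment_unlabeled))
  counts <- run_stage("count_mentions", count_mentions(retained, registry))
  ranking <- run_stage("align_rankings",
                       align_rankings(counts, registry, min_district_n))
  congruence <- run_stage("congruence_table",
                          congruence_table(ranking, tau_variant))

  features <- run_stage("features", {
    covars <- c("birthrate", "education_mean", "education_sd",
                "population_density", "doctors_per_clinic", "availability")
    if (all(covars %in% names(demographics))) {
      demographics |> select("district_id", dplyr::all_of(covars))
    } else {
      build_features(demographics)
    }
  })

  model_data <- congruence |> inner_join(features, by = "district_id")
  fit_one <- function(dep) {
    if (sum(!is.na(model_data[[dep]])) > 7) {
      fit_congruence_ols(model_data, dependent = dep)
    } else {
      NULL
    }
  }
  fit_tau <- run_stage("regression_tau", fit_one("kendall_tau"))
  fit_rho <- run_stage("regression_rho", fit_one("spearman_rho"))
  correlations <- run_stage("correlation_matrix", {
    feats <- features |> filter(.data$district_id %in% congruence$district_id)
    if (nrow(feats) >= 3) correlation_matrix(feats) else NULL
  })

  evaluation <- if (!is.null(gold)) {
    run_stage("evaluate_extraction",
              evaluate_extraction(mentions, gold,
                                  sample_fraction = eval_sample_fraction,
                                  seed = seed))
  } else {
    NULL
  }

  excluded <- if ("excluded" %in% names(ranking)) {
    ranking |> filter(.data$excluded) |> distinct(.data$district_id) |> nrow()
  } else {
    0L
  }
  report <- list(
    threads = dplyr::n_distinct(messages$thread_id),
    messages_read = nrow(messages),
    candidates = nrow(candidates),
    mentions_extracted = nrow(mentions),
    mentions_retained = nrow(retained),
    clinics_ranked = nrow(ranking),
    districts_analyzed = nrow(congruence),
    districts_excluded = excluded,
    tau_variant = tau_variant,
    min_district_n = min_district_n,
    seed = seed
  )

  structure(list(mentions = mentions, retained = retained, ranking = ranking,
                 congruence = congruence, features = features,
                 fit_tau = fit_tau, fit_rho = fit_rho,
                 correlations = correlations, evaluation = evaluation,
                 report = report),
            class = "congruence_study")
}

#' @export
print.congruence_study <- function(x, ...) {
  r <- x$report
  cat("<congruence_study>\n")
  cat(sprintf("  %d messages -> %d candidates -> %d mentions (%d retained)\n",
              r$messages_read, r$candidates, r$mentions_extracted,
              r$mentions_retained))
  cat(sprintf("  %d districts analyzed (%d excluded)\n",
              r$districts_analyzed, r$districts_excluded))
  invisible(x)
}

#' Run the full file-based pipeline
#'
#' Reads every input named in the configuration, runs
#' [run_congruence_study()], and writes the output tables (mentions JSONL;
#' ranking, congruence, regression and correlation CSVs; evaluation and run
#' report JSON) into `out_dir`. Every output carries a provenance sidecar
#' with the seed and the configuration hash. Reruns with an identical
#' configuration produce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return The `congruence_study` object, invisibly, with the report
#'   (including output paths) attached.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  registry <- run_stage("read_registry", read_registry(config$registry))
  aliases <- run_stage("read_aliases", read_alias_dictionary(config$aliases))
  messages <- run_stage("read_corpus", read_corpus(config$corpus))
  demographics <- run_stage("read_demographics",
                            read_demographics(config$demographics))
  gold <- if (!is.null(config$gold)) {
    run_stage("read_gold", read_gold(config$gold))
  } else {
    NULL
  }

  study <- run_congruence_study(
    registry, aliases, messages, demographics, gold = gold,
    threshold = config$threshold, tau_variant = config$tau_variant,
    min_district_n = config$min_district_n,
    sentiment_unlabeled = config$sentiment_unlabeled,
    eval_sample_fraction = config$eval_sample_fraction,
    domain_keywords = config$domain_keywords,
    request_keywords = config$request_keywords,
    seed = config$seed
  )

  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  meta <- list(seed = config$seed, config_hash = rlang::hash(unclass(config)))
  out <- function(name) file.path(config$out_dir, name)

  write_mentions(study$retained, out("mentions.jsonl"), meta)
  readr::write_csv(study$ranking, out("ranking.csv"))
  write_provenance(out("ranking.csv"), meta)
  readr::write_csv(study$congruence, out("congruence.csv"))
  write_provenance(out("congruence.csv"), meta)
  for (dep in c("tau", "rho")) {
    fit <- study[[paste0("fit_", dep)]]
    if (!is.null(fit)) {
      readr::write_csv(tidy(fit), out(paste0("regression_", dep, ".csv")))
      write_provenance(out(paste0("regression_", dep, ".csv")), meta)
    }
  }
  if (!is.null(study$correlations)) {
    readr::write_csv(study$correlations, out("correlations.csv"))
    write_provenance(out("correlations.csv"), meta)
  }
  if (!is.null(study$evaluation)) {
    jsonlite::write_json(as.list(study$evaluation), out("evaluation.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report <- c(study$report, list(config_hash = meta$config_hash,
                                 out_dir = config$out_dir))
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  study$report <- report
  invisible(study)
}
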