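#' Read and write pipeline artifacts
#'
#' Tabular artifacts (registry, demographics, rankings, congruence,
#' regression tables) are CSV; corpora, gold standards and mentions are
#' JSONL (UTF-8, one object per line, streamable). Readers validate the
#' documented schema and report the offending field and line. Writers
#' optionally record provenance (seed and configuration hash) in a
#' `<path>.meta.json` sidecar.
#'
#' @param x The object to write.
#' @param path File path.
#' @param meta Optional named list (e.g. `list(seed = 1, config_hash = h)`)
#'   written to `<path>.meta.json`.
#' @return Readers return tibbles (or an [alias_dictionary()]); writers
#'   return `path` invisibly.
#' @name pipeline_io
NULL

write_provenance <- function(path, meta) {
  if (!is.null(meta)) {
    jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  }
  invisible(path)
}

check_columns <- function(df, required, path) {
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0(path, ": missing field(s) ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (col in required) {
    bad <- which(is.na(df[[col]]))
    if (length(bad) > 0) {
      abort(paste0(path, ": field `", col, "` missing or NA at line ",
                   bad[1] + 1L, " (of the data records)"))
    }
  }
  invisible(df)
}

write_jsonl <- function(df, path, meta = NULL) {
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  jsonlite::stream_out(as.data.frame(df), con, verbose = FALSE)
  write_provenance(path, meta)
}

read_jsonl <- function(path, required) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  df <- tryCatch(jsonlite::stream_in(con, verbose = FALSE),
                 error = function(e) {
                   abort(paste0(path, ": malformed JSONL (",
                                conditionMessage(e), ")"))
                 })
  if (nrow(df) == 0 && length(df) == 0) {
    df <- as.data.frame(setNames(rep(list(character()), length(required)),
                                 required))
  }
  # a required key absent on some lines surfaces as NA in that column
  check_columns(df, required, path)
  tibble::as_tibble(df)
}

#' @rdname pipeline_io
#' @export
write_registry <- function(x, path, meta = NULL) {
  readr::write_csv(x, path)
  write_provenance(path, meta)
}

#' @rdname pipeline_io
#' @export
read_registry <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("hospital_id", "canonical_name", "district_id",
                      "antibiotic_rate", "n_doctors"), path)
  bad <- which(df$antibiotic_rate < 0 | df$antibiotic_rate > 1)
  if (length(bad) > 0) {
    abort(paste0(path, ": `antibiotic_rate` outside [0, 1] at line ",
                 bad[1] + 1L))
  }
  bad <- which(df$n_doctors < 1)
  if (length(bad) > 0) {
    abort(paste0(path, ": `n_doctors` below 1 at line ", bad[1] + 1L))
  }
  df
}

#' @rdname pipeline_io
#' @export
write_demographics <- function(x, path, meta = NULL) {
  readr::write_csv(x, path)
  write_provenance(path, meta)
}

#' @rdname pipeline_io
#' @export
read_demographics <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, "district_id", path)
  df
}

#' @rdname pipeline_io
#' @export
write_alias_dictionary <- function(x, path, meta = NULL) {
  stopifnot(inherits(x, "alias_dictionary"))
  payload <- list(entries = x$entries)
  if (!is.null(x$canonical_ids)) payload$canonical_ids <- as.list(x$canonical_ids)
  jsonlite::write_json(payload, path, auto_unbox = FALSE, pretty = TRUE)
  write_provenance(path, meta)
}

#' @rdname pipeline_io
#' @export
read_alias_dictionary <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(payload$entries)) abort(paste0(path, ": missing `entries`."))
  ids <- if (!is.null(payload$canonical_ids)) {
    unlist(payload$canonical_ids)
  } else {
    NULL
  }
  alias_dictionary(as.list(payload$entries), canonical_ids = ids)
}

#' @rdname pipeline_io
#' @export
write_corpus <- function(x, path, meta = NULL) {
  write_jsonl(x[, c("message_id", "thread_id", "district_id", "is_reply",
                    "text", "sentiment")], path, meta)
}

#' @rdname pipeline_io
#' @export
read_corpus <- function(path) {
  read_jsonl(path, c("message_id", "thread_id", "district_id", "is_reply",
                     "text", "sentiment"))
}

#' @rdname pipeline_io
#' @export
write_gold <- function(x, path, meta = NULL) {
  write_jsonl(x, path, meta)
}

#' @rdname pipeline_io
#' @export
read_gold <- function(path) {
  read_jsonl(path, c("message_id", "hospital_id"))
}

#' @rdname pipeline_io
#' @export
write_mentions <- function(x, path, meta = NULL) {
  write_jsonl(x, path, meta)
}

#' @rdname pipeline_io
#' @export
read_mentions <- function(path) {
  read_jsonl(path, c("message_id", "hospital_id", "surface_form", "distance"))
}
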