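#' Alias dictionary
#'
#' Maps each canonical hospital name to the set of surface forms (acronyms,
#' abbreviations, misspellings) under which it appears in community messages.
#' Every canonical name is always a member of its own set.
#'
#' @param entries Named list: canonical name -> character vector of surface
#'   forms. The canonical name is added to its own set if missing.
#' @param canonical_ids Optional named character vector mapping canonical
#'   names to hospital ids (carried through extraction output when present).
#' @return An object of class `alias_dictionary`.
#' @export
#' @examples
#' dict <- alias_dictionary(list("hanbyeol pediatric clinic" = c("hanbyeol", "hpc")))
#' as_tibble(dict)
alias_dictionary <- function(entries, canonical_ids = NULL) {
  if (!is.list(entries) || is.null(names(entries)) || any(names(entries) == "")) {
    abort("`entries` must be a fully named list of character vectors.")
  }
  if (anyDuplicated(names(entries))) {
    abort("Canonical names must be unique.")
  }
  entries <- lapply(seq_along(entries), function(i) {
    forms <- unique(c(names(entries)[i], as.character(entries[[i]])))
    forms[nzchar(forms)]
  }) |> setNames(names(entries))
  structure(list(entries = entries, canonical_ids = canonical_ids),
            class = "alias_dictionary")
}

#' @export
print.alias_dictionary <- function(x, ...) {
  sizes <- lengths(x$entries)
  cat(sprintf("<alias_dictionary> %d hospitals, %d surface forms (mean %.2f per hospital)\n",
              length(x$entries), sum(sizes), mean(sizes)))
  invisible(x)
}

#' Flatten an alias dictionary to a tibble
#'
#' @param x An `alias_dictionary`.
#' @param ... Unused.
#' @return A tibble with columns `canonical_name`, `surface_form`,
#'   `is_canonical`, and `hospital_id` when ids are attached.
#' @export
as_tibble.alias_dictionary <- function(x, ...) {
  out <- tibble::tibble(
    canonical_name = rep(names(x$entries), lengths(x$entries)),
    surface_form = unlist(x$entries, use.names = FALSE)
  ) |>
    mutate(is_canonical = .data$surface_form == .data$canonical_name)
  if (!is.null(x$canonical_ids)) {
    out$hospital_id <- unname(x$canonical_ids[out$canonical_name])
  }
  out
}

#' Default per-alias distance threshold
#'
#' The stepwise normalizer accepts a fuzzy match when the edit distance does
#' not exceed `max(1, floor(0.25 * nchar(alias)))`, so longer surface forms
#' tolerate proportionally more corruption while short forms allow at most a
#' single edit. Pass a fixed numeric threshold to the extraction functions to
#' override (0 forces exact-only matching).
#'
#' @param alias Character vector of surface forms.
#' @return Integer vector of maximum accepted distances.
#' @export
#' @examples
#' alias_distance_threshold(c("hpc", "hanbyeol pediatric clinic"))
alias_distance_threshold <- function(alias) {
  pmax(1L, as.integer(floor(0.25 * nchar(alias))))
}

#' Levenshtein edit distance
#'
#' Unit-cost insertions, deletions and substitutions, computed case
#' sensitively on the inputs as given (extraction lowercases beforehand).
#'
#' @param a,b Character vectors; distances are computed elementwise after
#'   recycling, or as a full matrix when `pairwise = FALSE`.
#' @param pairwise If `FALSE`, return the `length(a)` by `length(b)` matrix.
#' @return Integer distances.
#' @export
#' @examples
#' edit_distance("kitten", "sitting")
edit_distance <- function(a, b, pairwise = TRUE) {
  if (pairwise) {
    n <- max(length(a), length(b))
    a <- rep_len(a, n)
    b <- rep_len(b, n)
    out <- integer(n)
    for (i in seq_len(n)) out[i] <- adist(a[i], b[i])
    out
  } else {
    m <- adist(a, b)
    dimnames(m) <- list(a, b)
    storage.mode(m) <- "integer"
    m
  }
}
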