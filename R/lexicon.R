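# Token inventory for synthetic message text. Hospital-name realism is
# token-level only: names are romanized-Korean-like syllable compounds and
# filler words are a fixed chatter vocabulary. Fillers are at least 6
# characters and kept well away (edit distance >= 5) from the name-structure
# words "pediatric"/"clinic", so that no n-gram of pure chatter can fall
# inside the fuzzy-match threshold of a dictionary entry.

FILLER_WORDS <- c(
  "jinjja", "daebak", "juseyo", "gamsahae", "eonjena", "geunyang",
  "jeongmal", "yeogiseo", "saenggak", "hangsang", "wanjeon", "jigeumeun",
  "areumdawo", "gwaenchana", "moreugesseo", "saranghae", "yaksokhae",
  "baeganpa", "dangyeonhaji", "mariya", "eomeona", "halmoni",
  "dongsaeng", "yeodongsaeng", "maeildallae", "gajokdeul", "bangapseumnida",
  "oneureun", "naeireun", "eojeneun", "kamsahamnida", "sillyehamnida"
)

NAME_SUFFIX_WORDS <- c("pediatric", "clinic")

DOMAIN_KEYWORD_DEFAULT <- "pediatric"
REQUEST_KEYWORD_DEFAULT <- "recommendation"

NAME_CONSONANTS <- c("b", "ch", "d", "g", "h", "j", "k", "m", "n", "r", "s",
                     "t", "w", "y")
NAME_VOWELS <- c("a", "e", "i", "o", "u", "ae", "eo")
NAME_CODAS <- c("", "", "n", "m", "ng")

# Words no generated alias may sit within distance 2 of (fillers, the two
# name-structure words, and the thread keywords).
alias_safety_lexicon <- function(domain_keywords = DOMAIN_KEYWORD_DEFAULT,
                                 request_keywords = REQUEST_KEYWORD_DEFAULT) {
  unique(c(FILLER_WORDS, NAME_SUFFIX_WORDS, domain_keywords, request_keywords))
}

random_base_syllable <- function(n) {
  paste0(sample(NAME_CONSONANTS, n, replace = TRUE),
         sample(NAME_VOWELS, n, replace = TRUE),
         sample(NAME_CODAS, n, replace = TRUE))
}

# Draw `n` distinct base words, pairwise Levenshtein distance >= min_sep,
# by rejection sampling. Lengths are bounded to 6-10 characters: with the
# 17-character " pediatric clinic" suffix this caps every canonical name's
# fuzzy threshold at 6 edits, one less than the smallest edit cost (7) of
# adding or dropping a whole token, so token-misaligned spans can never
# fuzzy-match a canonical name.
random_base_names <- function(n, min_sep = 3L, max_rounds = 40L) {
  accepted <- character(0)
  for (round in seq_len(max_rounds)) {
    pool_n <- max(1000L, 4L * (n - length(accepted)))
    cand <- paste0(random_base_syllable(pool_n),
                   random_base_syllable(pool_n),
                   random_base_syllable(pool_n))
    cand <- unique(cand[nchar(cand) >= 6L & nchar(cand) <= 10L])
    cand <- c(accepted, cand)
    accepted <- if (min_sep <= 1L) {
      unique(cand)
    } else {
      cand[select_separated(cand, n, as.integer(min_sep))]
    }
    if (length(accepted) >= n) return(accepted[seq_len(n)])
  }
  abort("Could not draw enough well-separated hospital base names.")
}

# Apply `k` random character edits (substitution / insertion / deletion).
corrupt_form <- function(form, k) {
  letters_pool <- letters
  chars <- strsplit(form, "", fixed = TRUE)[[1]]
  for (i in seq_len(k)) {
    op <- sample(c("sub", "ins", "del"), 1L,
                 prob = if (length(chars) > 2L) c(0.5, 0.25, 0.25) else c(0.6, 0.4, 0))
    pos <- sample(length(chars), 1L)
    if (op == "sub") {
      repl <- sample(setdiff(letters_pool, chars[pos]), 1L)
      chars[pos] <- repl
    } else if (op == "ins") {
      chars <- append(chars, sample(letters_pool, 1L), after = pos)
    } else {
      chars <- chars[-pos]
    }
  }
  paste(chars, collapse = "")
}
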