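# Independent oracles used to cross-check the implementation. These are
# deliberately naive (quadratic DP, exhaustive double loops, sort-based
# ranking) and share no code with the package internals they verify.

# Full-matrix Levenshtein DP, unit costs.
lev_dp <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  m <- length(av)
  n <- length(bv)
  d <- matrix(0L, m + 1, n + 1)
  d[, 1] <- 0:m
  d[1, ] <- 0:n
  if (m > 0 && n > 0) {
    for (i in seq_len(m)) {
      for (j in seq_len(n)) {
        d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                               d[i, j] + (av[i] != bv[j]))
      }
    }
  }
  d[m + 1, n + 1]
}

# Exhaustive pair classification by double loop.
brute_pair_counts <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- tb <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[i] - x[j]
      dy <- y[i] - y[j]
      if (dx == 0 && dy == 0) tb <- tb + 1L
      else if (dx == 0) tx <- tx + 1L
      else if (dy == 0) ty <- ty + 1L
      else if (sign(dx) == sign(dy)) conc <- conc + 1L
      else disc <- disc + 1L
    }
  }
  list(concordant = conc, discordant = disc, tied_x = tx, tied_y = ty,
       tied_both = tb)
}

# Sort-based average-rank oracle (descending: largest value gets rank 1).
rank_desc_oracle <- function(v) {
  out <- numeric(length(v))
  for (i in seq_along(v)) {
    larger <- sum(v > v[i])
    equal <- sum(v == v[i])
    out[i] <- larger + (equal + 1) / 2
  }
  out
}

# A small handmade dictionary with ids, used across extraction tests.
toy_dictionary <- function() {
  alias_dictionary(
    list(
      "hanbyeol pediatric clinic" = c("hanbyeol", "hbpc"),
      "songrim pediatric clinic" = c("songrim", "srpc"),
      "dallae pediatric clinic" = c("dallae")
    ),
    canonical_ids = c("hanbyeol pediatric clinic" = "H01",
                      "songrim pediatric clinic" = "H02",
                      "dallae pediatric clinic" = "H03")
  )
}

toy_messages <- function() {
  tibble::tibble(
    message_id = sprintf("M%02d", 1:6),
    thread_id = c("T1", "T1", "T1", "T2", "T2", "T3"),
    district_id = "D01",
    is_reply = c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE),
    text = c("pediatric recommendation please",
             "we love hanbyeol pediatric clinic",
             "srpc was fine and hanbyeol too",
             "chatting about weather",
             "songrim is great",
             "pediatric recommendation again"),
    sentiment = c("neutral", "positive", "neutral", "neutral", "positive",
                  "neutral")
  )
}
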