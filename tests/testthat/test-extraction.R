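test_that("strip_markup removes tags, scripts and attributes but keeps plain text", {
  expect_equal(strip_markup("<p>recommend A clinic</p>"), "recommend A clinic")
  expect_equal(strip_markup("just plain text"), "just plain text")
  fixture <- paste0(
    "<html><head><script>var x = 1;</script>",
    "<style>.a { color: red }</style></head>",
    "<body><h1>Thread</h1><p>go to <b>hanbyeol</b> clinic",
    "<img src='pic.png' alt='photo'/> it helped</p></body></html>"
  )
  # hand-stripped reference for the fixture above
  expect_equal(strip_markup(fixture), "Thread go to hanbyeol clinic it helped")
  expect_false(grepl("var x|color|pic.png", strip_markup(fixture)))
})

test_that("candidate filter keeps replies of keyword-matching threads only", {
  msgs <- toy_messages()
  cand <- filter_candidates(msgs)
  expect_equal(cand$message_id, c("M02", "M03"))

  # thread without keywords contributes nothing; root-only threads neither
  expect_false(any(cand$thread_id %in% c("T2", "T3")))

  # brute-force count over a mixed corpus: qualifying replies enumerated
  withr::with_seed(1, {
    roots <- tibble::tibble(
      message_id = sprintf("R%02d", 1:10),
      thread_id = sprintf("T%02d", 1:10),
      is_reply = FALSE,
      text = ifelse(1:10 <= 4, "pediatric recommendation wanted", "hello there")
    )
    n_rep <- sample(0:4, 10, replace = TRUE)
    replies <- tibble::tibble(
      message_id = sprintf("P%02d", seq_len(sum(n_rep))),
      thread_id = rep(roots$thread_id, n_rep),
      is_reply = TRUE,
      text = "some reply"
    )
    all_msgs <- dplyr::bind_rows(roots, replies)
    expect_equal(nrow(filter_candidates(all_msgs)), sum(n_rep[1:4]))
  })
})

test_that("stepwise normalization resolves exact, alias and fuzzy expressions", {
  dict <- toy_dictionary()
  res <- normalize_expression(
    c("hanbyeol pediatric clinic", "srpc", "hanbyeol", "dalae",
      "completely unrelated", ""),
    dict
  )
  expect_equal(res$canonical_name[1], "hanbyeol pediatric clinic")
  expect_equal(res$distance[1], 0L)
  expect_equal(res$canonical_name[2], "songrim pediatric clinic")
  expect_equal(res$distance[2], 0L)
  expect_equal(res$hospital_id[3], "H01")
  # "dalae" is distance 1 from alias "dallae" only
  expect_equal(res$canonical_name[4], "dallae pediatric clinic")
  expect_equal(res$distance[4], 1L)
  expect_true(is.na(res$canonical_name[5]))
  expect_true(is.na(res$canonical_name[6]))

  # brute-force nearest-alias verification of the fuzzy match
  forms <- as_tibble(dict)$surface_form
  dists <- vapply(forms, function(f) lev_dp("dalae", f), numeric(1))
  expect_equal(min(dists), 1)
  expect_equal(unname(forms[which.min(dists)]), "dallae")

  # matching is case-insensitive after whitespace normalization
  res2 <- normalize_expression("  HanByeol   Pediatric  Clinic ", dict)
  expect_equal(res2$canonical_name, "hanbyeol pediatric clinic")
  expect_equal(res2$distance, 0L)
})

test_that("normalization ties break deterministically and distances are exact minima", {
  # two aliases at equal distance: prefer the longer alias, then the
  # lexicographically smallest canonical name
  dict <- alias_dictionary(list(
    "aaa clinic" = c("abcd"),
    "bbb clinic" = c("abcde")
  ))
  res <- normalize_expression("abcdx", dict, threshold = 2)
  d_short <- lev_dp("abcdx", "abcd")
  d_long <- lev_dp("abcdx", "abcde")
  expect_equal(d_short, d_long)  # genuine tie
  expect_equal(res$canonical_name, "bbb clinic")  # longer alias wins

  dict2 <- alias_dictionary(list(
    "aaa clinic" = c("abcde"),
    "bbb clinic" = c("abcdf")
  ))
  res2 <- normalize_expression("abcdx", dict2, threshold = 2)
  expect_equal(res2$canonical_name, "aaa clinic")  # canonical tie-break

  # returned distance equals the DP-oracle minimum over all aliases
  cfg <- sim_config(n_districts = 2, hospitals_per_district = 4,
                    threads_per_district = 5, seed = 21)
  reg <- sim_registry(cfg)
  dict3 <- sim_aliases(reg, cfg)
  forms <- as_tibble(dict3)$surface_form
  withr::with_seed(3, {
    probes <- c(vapply(sample(forms, 12, replace = TRUE), function(f) {
      crowdcongruence:::corrupt_form(f, sample(0:2, 1))
    }, character(1)), "jinjja", "gwaenchana daebak")
  })
  res3 <- normalize_expression(probes, dict3, threshold = 3)
  for (i in seq_along(probes)) {
    d_all <- vapply(forms, function(f) lev_dp(tolower(probes[i]), f),
                    numeric(1))
    if (is.na(res3$distance[i])) {
      expect_gt(min(d_all), 3)
    } else {
      expect_equal(res3$distance[i], min(d_all))
    }
  }
})

test_that("raising the distance threshold never loses resolved mentions", {
  cfg <- sim_config(n_districts = 2, hospitals_per_district = 5,
                    threads_per_district = 30, corruption_rate = 0.5,
                    seed = 8)
  st <- sim_study(cfg, clinic_source = "config")
  cand <- filter_candidates(st$messages)
  n_resolved <- vapply(0:4, function(thr) {
    nrow(extract_mentions(cand, st$aliases, threshold = thr))
  }, numeric(1))
  expect_true(all(diff(n_resolved) >= 0))
})

test_that("mention extraction finds multiple hospitals and deduplicates per message", {
  dict <- toy_dictionary()
  msgs <- tibble::tibble(
    message_id = c("A", "B"),
    district_id = "D01",
    sentiment = "positive",
    text = c("go hanbyeol pediatric clinic or srpc maybe",
             "hanbyeol hanbyeol hanbyeol")
  )
  m <- extract_mentions(msgs, dict)
  expect_equal(sort(m$hospital_id[m$message_id == "A"]), c("H01", "H02"))
  # same hospital mentioned thrice -> one deduplicated record
  expect_equal(sum(m$message_id == "B"), 1L)
  expect_equal(m$hospital_id[m$message_id == "B"], "H01")
  # occurrence-level counting available by flag
  m2 <- extract_mentions(msgs, dict, dedupe = FALSE)
  expect_gt(sum(m2$message_id == "B"), 1L)
})

test_that("sentiment filter retains positive/neutral/ambiguous and drops negative", {
  mentions <- tibble::tibble(
    message_id = sprintf("M%03d", 1:100),
    hospital_id = "H01",
    sentiment = rep(c("positive", "neutral", "negative", "ambiguous"),
                    c(60, 28, 8, 4))
  )
  kept <- filter_sentiment(mentions)
  expect_equal(nrow(kept), 92)
  expect_false(any(kept$sentiment == "negative"))

  all_pos <- mentions |> dplyr::filter(sentiment == "positive")
  expect_identical(filter_sentiment(all_pos), all_pos)

  unl <- tibble::tibble(message_id = "M1", hospital_id = "H01",
                        sentiment = "unlabeled")
  expect_equal(nrow(filter_sentiment(unl)), 1)
  expect_error(filter_sentiment(unl, unlabeled = "error"), "unlabeled")
})

test_that("extraction evaluation computes precision, recall and F1 as defined", {
  gold <- tibble::tibble(message_id = "M1", hospital_id = c("H01", "H02"))
  pred <- gold
  perfect <- evaluate_extraction(pred, gold)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)

  # a fixture engineered to hit precision 0.84 and recall 0.73 exactly
  ng <- 2100
  np <- 1825
  tp <- 1533
  gold2 <- tibble::tibble(message_id = sprintf("M%04d", seq_len(ng)),
                          hospital_id = "H01")
  pred2 <- dplyr::bind_rows(
    gold2[seq_len(tp), ],
    tibble::tibble(message_id = sprintf("X%04d", seq_len(np - tp)),
                   hospital_id = "H01")
  )
  ev <- evaluate_extraction(pred2, gold2)
  expect_equal(ev$precision, 0.84)
  expect_equal(ev$recall, 0.73)
  expect_equal(ev$f1, 2 * 0.84 * 0.73 / (0.84 + 0.73), tolerance = 1e-12)

  # no predictions against nonempty gold: all-zero metrics by convention
  none <- evaluate_extraction(gold2[0, ], gold2)
  expect_equal(c(none$precision, none$recall, none$f1), c(0, 0, 0))
  expect_error(evaluate_extraction(gold2[0, ], gold2[0, ]), "Empty")
})

test_that("normalization is idempotent on canonical names", {
  cfg <- sim_config(n_districts = 2, hospitals_per_district = 6,
                    threads_per_district = 5, seed = 13)
  reg <- sim_registry(cfg)
  dict <- sim_aliases(reg, cfg)
  res <- normalize_expression(reg$canonical_name, dict)
  expect_equal(res$canonical_name, reg$canonical_name)
  expect_true(all(res$distance == 0L))
})
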