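test_that("configuration validation rejects inconsistent settings", {
  expect_error(sim_config(n_districts = 0), "n_districts")
  expect_error(sim_config(hospitals_per_district = c(2, 3)),
               "hospitals_per_district")
  expect_error(sim_config(sentiment_mix = c(positive = 0.6, neutral = 0.6,
                                            negative = -0.2, ambiguous = 0)),
               "sentiment_mix")
  expect_error(sim_config(corruption_rate = 1.5), "corruption_rate")
  expect_error(sim_config(messages_per_thread_mean = 0.5), "request root")
  expect_s3_class(sim_config(seed = 7), "sim_config")
})

test_that("registry generation respects counts, rates and determinism", {
  cfg <- sim_config(n_districts = 4, hospitals_per_district = c(3, 5, 2, 7),
                    threads_per_district = 5, seed = 6)
  reg <- sim_registry(cfg)
  expect_equal(nrow(reg), 17)
  expect_equal(as.integer(table(reg$district_id)), c(3L, 5L, 2L, 7L))
  expect_true(all(reg$antibiotic_rate >= 0 & reg$antibiotic_rate <= 1))
  expect_true(all(reg$n_doctors >= 1))
  expect_false(anyDuplicated(reg$canonical_name) > 0)
  expect_identical(reg, sim_registry(cfg))

  one <- sim_config(n_districts = 3, hospitals_per_district = 1,
                    threads_per_district = 5, seed = 2)
  expect_equal(nrow(sim_registry(one)), 3)

  # sized from the reference setting's per-district clinic counts
  ref <- reference_district_clinics()
  big <- sim_config(n_districts = nrow(ref),
                    hospitals_per_district = ref$n_mentioned,
                    threads_per_district = 5, seed = 1)
  expect_equal(nrow(sim_registry(big)), 779)
})

test_that("alias dictionaries contain identities, hit the target mean size, and honor d_max", {
  cfg <- sim_config(n_districts = 4, hospitals_per_district = 25,
                    threads_per_district = 5, seed = 10)
  reg <- sim_registry(cfg)
  dict <- sim_aliases(reg, cfg)
  expect_true(all(vapply(seq_along(dict$entries), function(i) {
    names(dict$entries)[i] %in% dict$entries[[i]]
  }, logical(1))))
  expect_lt(abs(mean(lengths(dict$entries)) - cfg$alias_mean), 0.45)

  # variant generation disabled -> identity sets only
  cfg1 <- sim_config(n_districts = 2, hospitals_per_district = 4,
                     threads_per_district = 5, alias_mean = 1, seed = 10)
  reg1 <- sim_registry(cfg1)
  dict1 <- sim_aliases(reg1, cfg1)
  expect_true(all(lengths(dict1$entries) == 1L))

  # every generated variant lies within d_max = 1 of its source form,
  # verified with the independent DP oracle
  flat <- as_tibble(dict)
  for (i in which(!flat$is_canonical)) {
    base <- sub(" pediatric clinic$", "", flat$canonical_name[i])
    d_best <- min(lev_dp(flat$surface_form[i], base),
                  lev_dp(flat$surface_form[i], flat$canonical_name[i]),
                  lev_dp(flat$surface_form[i],
                         paste0(substr(base, 1, 4), "pc")))
    expect_lte(d_best, cfg$typo_max_distance)
  }
})

test_that("demographic draws center on the configured summary statistics", {
  cfg <- sim_config(n_districts = 1000, threads_per_district = 5, seed = 3)
  demo <- sim_demographics(cfg)
  se <- cfg$covariate_sds[["birthrate"]] / sqrt(1000)
  expect_lt(abs(mean(demo$birthrate) - 1.048), 3 * se)
  expect_equal(demo$population_density,
               demo$population / (demo$area_km2 * 1e6))
  expect_equal(demo$doctors_per_clinic, demo$n_doctors / demo$n_clinics)
  expect_equal(demo$availability, 1000 * demo$n_clinics / demo$population)

  zero <- sim_config(n_districts = 5, threads_per_district = 5,
                     covariate_sds = setNames(rep(0, 6),
                                              names(cfg$covariate_sds)),
                     population_sd = 0, seed = 3)
  dz <- sim_demographics(zero)
  expect_equal(nrow(dplyr::distinct(dz |> dplyr::select(-district_id))), 1)

  expect_identical(demo, sim_demographics(cfg))
})

test_that("noise SD is the configured linear function of z-scored covariates", {
  cfg <- sim_config(n_districts = 50, threads_per_district = 5, seed = 4)
  demo <- sim_demographics(cfg)
  sds <- district_noise_sd(demo, cfg)
  co <- cfg$noise_coefficients
  manual <- co[["intercept"]] +
    co[["birthrate"]] * (demo$birthrate - 1.048) / 0.100 +
    co[["education_sd"]] * (demo$education_sd - 3.496) / 0.183 +
    co[["population_density"]] * (demo$population_density - 0.016) / 0.007 +
    co[["doctors_per_clinic"]] * (demo$doctors_per_clinic - 1.641) / 0.396
  expect_equal(sds, pmax(0, manual))
})

test_that("corpora reproduce the configured thread and sentiment structure", {
  cfg <- sim_config(n_districts = 6, threads_per_district = 400,
                    hospitals_per_district = 8, seed = 14)
  st <- sim_study(cfg, clinic_source = "config")
  n_threads <- nrow(st$threads)
  expect_equal(n_threads, 2400)

  mpt <- nrow(st$messages) / n_threads
  # Poisson(4.36) replies + root: SE of the mean over 2400 threads
  se <- sqrt(4.36 / n_threads)
  expect_lt(abs(mpt - 5.36), 4 * se)

  # sentiment mix convergence at n >= 10,000 messages, 3 SE tolerance
  expect_gt(nrow(st$messages), 10000)
  emp <- prop.table(table(factor(st$messages$sentiment,
                                 levels = names(cfg$sentiment_mix))))
  for (lab in names(cfg$sentiment_mix)) {
    p <- cfg$sentiment_mix[[lab]]
    se_p <- sqrt(p * (1 - p) / nrow(st$messages))
    expect_lt(abs(emp[[lab]] - p), 3 * se_p + 1e-9)
  }

  # gold consistency: every gold mention resolves to a registry clinic in
  # the message's district
  expect_true(all(st$gold$hospital_id %in% st$registry$hospital_id))
  joined <- st$gold |>
    dplyr::left_join(st$registry, by = "hospital_id",
                     suffix = c("", ".reg"))
  expect_true(all(joined$district_id == joined$district_id.reg))
})

test_that("identical configurations give byte-identical corpus files", {
  cfg <- sim_config(n_districts = 3, threads_per_district = 40,
                    hospitals_per_district = 5, seed = 77)
  f1 <- withr::local_tempfile(fileext = ".jsonl")
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(sim_study(cfg, clinic_source = "config")$messages, f1)
  write_corpus(sim_study(cfg, clinic_source = "config")$messages, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("mention allocation is monotone, capped and exact in total", {
  q <- c(0.9, 0.5, 0.2, 0.1)
  cnt <- allocate_mention_counts(q, 20, n_cap = 10, temperature = 0.3)
  expect_equal(order(-cnt), order(-q))
  expect_true(all(diff(cnt[order(-q)]) < 0 | cnt[order(-q)][-1] == 0))
  expect_true(all(cnt <= 10))
  expect_equal(allocate_mention_counts(q, 0), integer(4))
  # noiseless ordering: counts strictly decrease along perceived quality
  withr::with_seed(31, {
    for (rep in 1:20) {
      pq <- sort(runif(8), decreasing = TRUE)
      cnt <- allocate_mention_counts(pq, 60, n_cap = 40, temperature = 0.2)
      pos <- cnt[cnt > 0]
      expect_true(all(diff(pos) < 0) || length(pos) <= 1)
    }
  })
})

test_that("covariate-linked noise makes congruence fall with birthrate", {
  cfg <- sim_config(n_districts = 200, threads_per_district = 20, seed = 99)
  dat <- sim_congruence_data(cfg)
  ct <- congruence_table(align_rankings(dat$mention_counts, dat$registry))
  md <- dplyr::inner_join(ct, dat$demographics, by = "district_id")
  expect_lt(cor(md$birthrate, md$kendall_tau, use = "complete.obs"), 0)
})
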