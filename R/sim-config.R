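#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. The defaults
#' reproduce the statistical structure of the emulated setting: 29 analysis
#' districts whose 779 pediatric clinics are rank-ordered by antibiotic
#' prescription rate, community threads averaging 5.36 messages, a
#' 92.03% / 7.97% positive-or-neutral vs negative sentiment split, hospital
#' names carried by about 3 surface forms each, and a generative link in
#' which district covariates control the noise between perceived and true
#' clinic quality (so the downstream regression has known recoverable signs).
#'
#' @param n_districts Number of districts to simulate.
#' @param hospitals_per_district Clinics per district; a scalar or a vector of
#'   length `n_districts` (e.g. the mentioned-clinic counts of the reference
#'   setting, which sum to 779).
#' @param threads_per_district Community threads generated per district. The
#'   default matches the emulated setting's volume (32,422 threads over 29
#'   districts, about 1100 each); tests and examples pass smaller values.
#' @param messages_per_thread_mean Mean total messages per thread (request
#'   root plus replies); reply counts are `Poisson(mean - 1)` per thread.
#' @param sentiment_mix Named probabilities for `positive`, `neutral`,
#'   `negative`, `ambiguous` message sentiment; must sum to 1. The default
#'   splits the 92.03% non-negative mass evenly between positive and neutral
#'   (the split within that mass is not separately known) and assigns
#'   ambiguous probability 0.
#' @param corruption_rate Fraction of rendered mentions corrupted beyond the
#'   alias dictionary (out-of-dictionary misspellings). The default 0.25
#'   produces extraction recall on the scale observed for informal Korean
#'   text (roughly 0.75).
#' @param noise_coefficients Named vector (`intercept` plus covariate names)
#'   giving the per-district perceived-quality noise SD as a linear function
#'   of z-scored covariates, truncated at zero:
#'   `sd_d = max(0, intercept + sum_j coef_j * z_dj)`. Units are antibiotic
#'   prescription-rate points. Positive coefficients mean noisier (less
#'   congruent) crowd information in districts high on that covariate.
#' @param rate_shape1,rate_shape2 Beta shape parameters for clinic antibiotic
#'   prescription rates (default Beta(6, 4): mean 0.60, SD 0.15, the scale of
#'   pediatric outpatient antibiotic prescribing in the emulated period).
#' @param alias_mean Target mean alias-set size per hospital (including the
#'   canonical name itself); default 3.
#' @param typo_max_distance Maximum Levenshtein distance of generated
#'   misspelling aliases from their source form.
#' @param softmax_temperature Temperature of the softmax that converts
#'   perceived quality into mention shares (prescription-rate units).
#' @param mentions_per_reply Mean hospital-mention slots per candidate reply.
#' @param covariate_means,covariate_sds Named generative means and SDs of the
#'   six district covariates (defaults: the summary statistics of the
#'   emulated setting).
#' @param population_mean,population_sd District population draw parameters.
#' @param qualifying_fraction Fraction of threads whose root is a pediatric
#'   recommendation request (only these carry hospital mentions).
#' @param seed Integer master seed; all generator randomness derives from it
#'   through fixed sub-streams, so equal configs give byte-identical output.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_districts = 4, hospitals_per_district = 6, seed = 7)
#' cfg$sentiment_mix
sim_config <- function(n_districts = 29,
                       hospitals_per_district = 27,
                       threads_per_district = 1100,
                       messages_per_thread_mean = 5.36,
                       sentiment_mix = c(positive = 0.46015, neutral = 0.46015,
                                         negative = 0.0797, ambiguous = 0),
                       corruption_rate = 0.25,
                       noise_coefficients = c(intercept = 0.45,
                                              birthrate = 0.15,
                                              education_mean = 0,
                                              education_sd = 0.06,
                                              population_density = 0.09,
                                              doctors_per_clinic = 0.06,
                                              availability = 0),
                       rate_shape1 = 6,
                       rate_shape2 = 4,
                       alias_mean = 3,
                       typo_max_distance = 1,
                       softmax_temperature = 0.2,
                       mentions_per_reply = 1.2,
                       covariate_means = c(birthrate = 1.048,
                                           education_mean = 12.390,
                                           education_sd = 3.496,
                                           population_density = 0.016,
                                           doctors_per_clinic = 1.641,
                                           availability = 0.060),
                       covariate_sds = c(birthrate = 0.100,
                                         education_mean = 0.833,
                                         education_sd = 0.183,
                                         population_density = 0.007,
                                         doctors_per_clinic = 0.396,
                                         availability = 0.010),
                       population_mean = 450000,
                       population_sd = 90000,
                       qualifying_fraction = 0.9,
                       seed = 1L) {
  cfg <- list(
    n_districts = as.integer(n_districts),
    hospitals_per_district = as.integer(hospitals_per_district),
    threads_per_district = as.integer(threads_per_district),
    messages_per_thread_mean = messages_per_thread_mean,
    sentiment_mix = sentiment_mix,
    corruption_rate = corruption_rate,
    noise_coefficients = noise_coefficients,
    rate_shape1 = rate_shape1,
    rate_shape2 = rate_shape2,
    alias_mean = alias_mean,
    typo_max_distance = as.integer(typo_max_distance),
    softmax_temperature = softmax_temperature,
    mentions_per_reply = mentions_per_reply,
    covariate_means = covariate_means,
    covariate_sds = covariate_sds,
    population_mean = population_mean,
    population_sd = population_sd,
    qualifying_fraction = qualifying_fraction,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' @param cfg A `sim_config` object.
#' @return `cfg`, invisibly unchanged, or an error describing the violation.
#' @export
validate_sim_config <- function(cfg) {
  if (!inherits(cfg, "sim_config")) {
    abort("`cfg` must be a `sim_config` object.")
  }
  if (cfg$n_districts < 1L) {
    abort("`n_districts` must be a positive integer.")
  }
  hpd <- cfg$hospitals_per_district
  if (any(hpd < 1L) || !(length(hpd) %in% c(1L, cfg$n_districts))) {
    abort("`hospitals_per_district` must be positive, of length 1 or `n_districts`.")
  }
  if (cfg$threads_per_district < 1L) {
    abort("`threads_per_district` must be a positive integer.")
  }
  if (cfg$messages_per_thread_mean < 1) {
    abort("`messages_per_thread_mean` must be at least 1 (the request root).")
  }
  mix <- cfg$sentiment_mix
  needed <- c("positive", "neutral", "negative", "ambiguous")
  if (!all(needed %in% names(mix))) {
    abort("`sentiment_mix` must name positive, neutral, negative, ambiguous.")
  }
  if (any(mix < 0) || any(mix > 1) || abs(sum(mix) - 1) > 1e-8) {
    abort("`sentiment_mix` probabilities must lie in [0, 1] and sum to 1.")
  }
  if (cfg$corruption_rate < 0 || cfg$corruption_rate > 1) {
    abort("`corruption_rate` must lie in [0, 1].")
  }
  if (!("intercept" %in% names(cfg$noise_coefficients))) {
    abort("`noise_coefficients` must include an `intercept` term.")
  }
  if (cfg$rate_shape1 <= 0 || cfg$rate_shape2 <= 0) {
    abort("Beta shape parameters must be positive.")
  }
  if (cfg$alias_mean < 1) {
    abort("`alias_mean` must be at least 1 (the canonical name itself).")
  }
  if (cfg$softmax_temperature <= 0) {
    abort("`softmax_temperature` must be positive.")
  }
  if (cfg$qualifying_fraction < 0 || cfg$qualifying_fraction > 1) {
    abort("`qualifying_fraction` must lie in [0, 1].")
  }
  if (any(cfg$covariate_sds < 0)) {
    abort("`covariate_sds` must be non-negative.")
  }
  invisible(cfg)
}

# Fixed sub-stream scheme: every generator stage seeds its own RNG stream
# derived from the master seed, so stages are individually reproducible and
# adding messages to one district never perturbs another stage's draws.
stream_seed <- function(seed, stream) {
  (abs(as.integer(seed)) %% 1000000L) * 1000L + as.integer(stream)
}

SIM_STREAMS <- c(registry = 1L, aliases = 2L, demographics = 3L,
                 corpus = 4L, census = 5L, evaluation = 6L, messages = 7L)
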