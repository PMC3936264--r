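# crowdcongruence

Measure how well hospital-quality beliefs crowdsourced from geospecific
online health communities agree with official government quality data, and
explain where — and why — that agreement breaks down.

The package is written for health-informatics and infodemiology
researchers studying user-generated health content. It models the South
Korean pediatric setting: parents' community forums segmented by
metropolitan district, an official registry in which every pediatric
clinic carries an antibiotic prescription rate r (prescriptions / visits —
an inverse quality index, since pediatric antibiotic overuse is harmful),
and district-level census covariates.

## What it computes

For each district *d*, two rankings over the clinics mentioned online:

* the **crowd ranking** — clinics ordered by descending frequency of
  positive/neutral mentions in replies to recommendation-request threads,
  extracted by dictionary lookup with stepwise edit-distance normalization
  (exact canonical match → exact alias match → minimum-Levenshtein match
  within a per-alias threshold);
* the **government ranking** — the same clinics ordered by ascending
  antibiotic prescription rate.

Congruence is their rank correlation, computed from first principles:

* Kendall tau-b: `τ = (C − D) / √((n₀ − n₁)(n₀ − n₂))`, with C/D the
  concordant/discordant pair counts, `n₀ = n(n−1)/2`, and n₁, n₂ the pair
  counts tied in each ranking (tau-a selectable);
* Spearman rho: Pearson correlation of the average-tie rank vectors
  (equals `1 − 6Σdᵢ²/(n(n²−1))` when tie-free).

Variation in congruence across districts is then modelled by OLS on six
sociodemographic covariates (birthrate; mean and SD of married women's
education in years; population density; doctors per clinic; clinics per
1000 residents), reported with raw and standardized coefficients
(`β_std = β·SD(x)/SD(y)`), classical SEs, p-values and adjusted R².

Because the original crawled corpora are not redistributable, a synthetic
generator produces registries, alias dictionaries (acronyms, truncations,
misspellings), district demographics and message corpora with known ground
truth, including a generative link in which district covariates control
the noise between perceived and true clinic quality — so extraction
accuracy and regression signs are verifiable against construction. See the
methods vignette (`vignettes/crowdcongruence-methods.Rmd`) for the model
and every default.

## Worked example

```r
library(crowdcongruence)

cfg <- sim_config(n_districts = 10, threads_per_district = 80, seed = 42)
st  <- sim_study(cfg)
study <- run_congruence_study(st$registry, st$aliases, st$messages,
                              st$demographics, gold = st$gold,
                              eval_sample_fraction = 1)
study
#> <congruence_study>
#>   4237 messages -> 3094 candidates -> 2742 mentions (2524 retained)
#>   10 districts analyzed (0 excluded)

study$evaluation
#> # A tibble: 1 × 6
#>   precision recall    f1 n_messages n_predicted n_gold
#>       <dbl>  <dbl> <dbl>      <int>       <int>  <int>
#> 1     0.997  0.801 0.888       2633        2742   3414

head(study$congruence, 3)
#> # A tibble: 3 × 6
#>   district_id     n kendall_tau tau_rank spearman_rho rho_rank
#>   <chr>       <int>       <dbl>    <int>        <dbl>    <int>
#> 1 D01            10     -0.0667        7       -0.176        7
#> 2 D02            16      0.707         1        0.830        1
#> 3 D03             4      0.667         2        0.8          2
```

Reading the output: extraction recovers about 81% of planted mentions
(25% are deliberately corrupted beyond the dictionary, emulating
out-of-dictionary misspellings in informal text) with near-perfect
precision; each analyzed district then gets its mentioned-clinic count
`n`, both congruence indexes, and their across-district ranks. `tidy()`
and `glance()` on `study$fit_tau` give the regression table and model
summary; `plot_congruence()`, `plot_rank_agreement()` and `autoplot()`
draw the standard figures.

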