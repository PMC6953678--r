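# seastrat

Design-based abundance estimation for stratified random towed-video surveys
of benthic epifauna, built around the assessment of the European flat oyster
(*Ostrea edulis*) in the Swedish Skagerrak. The package takes tabular survey
data — one row per filmed site with its living and dead counts over a known
filmed area — and a stratified sampling frame (area × depth-band cells with
areal extents), and produces population totals with standard errors plus the
stock metrics a manager asks for next: occurrence frequencies, the share of
the population in oyster-bed densities, detection-corrected totals, biomass
and exploitation rates. A synthetic-survey generator with known ground truth
makes the whole pipeline statistically testable.

## The estimator

For stratum *st* with areal weight `W_st = A_st / Σ A_st`, site-density mean
`ȳ_st` and unbiased sample variance `s²_st` over `n_st` sites:

```
ȳ      = Σ_st W_st · ȳ_st                 (stratified mean density, /m²)
V(ȳ)   = Σ_st W_st² · s²_st / n_st        (variance of that mean)
T̂      = ȳ · N  ±  sqrt(V(ȳ)) · N        (total ± SE over extent N, m²)
```

Independently planned surveys are estimated separately and combined by
summing totals, with the combined SE the root sum of squares of the survey
SEs. Sites — not transects — are the sampling units; rocky sites recorded
absent by visual inspection enter as exact zeros; a frame cell with no sites
is an error unless explicitly excluded. See the methods vignette
(`vignettes/stratified-survey-estimation.Rmd`) for the design decisions and
their rationale.

## Worked example

Simulate a survey over the packaged Skagerrak frame (five areas × three
depth bands, extents in km²) at the original inventory's sampling
intensities, then estimate:

```r
library(seastrat)

sim <- simulate_survey(seed = 42)          # population truth + one survey
est <- estimate_population(sim$sites, skagerrak_frame())
est
#> <population_estimate: combined (living)>
#>   total   37.59 million individuals (SE 14.50 million)
#>   mean    0.2474 per m2 over 151.96 km2
#>   surveys: coastal, koster
```

The generated truth for this seed is 39.22 million individuals, well inside
one SE. The domain-by-depth reporting grid (millions):

```r
estimate_grid(est)
#> # A tibble: 3 × 6
#>   survey_id `0.5-3` `3-6` `6-10` total se_total
#> 1 coastal     23.7  11.2    0.48 35.3     14.4
#> 2 koster       1.78  0.43   0.06  2.27     1.16
#> 3 combined    25.4  11.6    0.54 37.6     14.5
```

Concentration of the stock in bed densities (≥ 5 /m², the OSPAR oyster-bed
threshold), from transect-level densities:

```r
bed_share(cumulative_density_curve(sim$transects), 5)
#> # A tibble: 1 × 6
#>   threshold population_share n_units_at_or_above n_units unit_share denominator
#> 1         5            0.623                   8     139     0.0576 nonzero
```

62% of all counted individuals sit on 8 of the 139 transects that held any
living oyster — the patchiness that makes the SE large. Downstream stock
arithmetic:

```r
detection_correction(est, 1.25)$total / 1e6   # 20% video miss rate corrected
#> [1] 46.99
biomass(est, 63)                              # 63 g mean individual weight
#> # A tibble: 1 × 3
#>   mean_weight_g total_tonnes se_tonnes
#> 1            63        2368.      913.
exploitation_rate(est, landings = 88000)      # % of the stock removed per year
#> # A tibble: 1 × 4
#>   landings multiplier     stock rate_percent
#> 1    88000          1 37592470.        0.234
```

Real data enter through `read_sites()` / `read_transects()` /
`load_strata()` (CSV + YAML; schemas in `?validate_sites` and
`?load_strata`), and everything above applies unchanged. File-writing
entry points (`run_simulate()`, `run_estimate()`, `run_metrics()`,
`run_report()`) and a thin CLI wrapper (`inst/cli/survey-report.R`) cover
scripted use.

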