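# mfbc — otolith back-calculation of fish length-at-age

`mfbc` reconstructs the growth history of reef fishes from their otoliths and
uses it to compare protected and exploited populations. Marine reserves are
"no take" areas, so repeated sampling inside them is rarely possible; a single
collection of otoliths, however, carries a longitudinal record, because an
otolith accretes one annulus (ring) per year. Back-calculation converts the
radius of each annulus into the body length the fish had when that ring
formed, turning one capture into a length-at-age series per fish.

The package is aimed at fisheries and marine-conservation scientists who have
per-fish records of capture length, otolith radius at capture, and the radii
of annuli 1..A, and who want to ask: do fish inside reserves reach larger
sizes at age than fish on fished reefs, and are younger year classes larger
than older ones?

## The model

The core is the modified Fry back-calculation (MFBC). Body length is assumed
to follow an allometric relation in otolith radius, L = a + b·R^c, whose
intercept *a* is the "biological intercept". The back-calculated length at
annulus *i* interpolates log size linearly in log radius between a formation
anchor (R₀ₚ, L₀ₚ) and the capture anchor (R_cpt, L_cpt):

    Li = a + exp( ln(L0p − a)
                  + [ln(Lcpt − a) − ln(L0p − a)] · [ln(Ri) − ln(R0p)]
                    / [ln(Rcpt) − ln(R0p)] )

where R₀ₚ is the mean radius of the first annulus across the sample and
L₀ₚ = a + b·R₀ₚ^c. `mfbc()` estimates (a, b, c) by pooled nonlinear least
squares of capture length on capture radius and returns a fitted model object
with the usual `print`, `summary`, `coef`, `predict`, `plot`, `residuals`
and `simulate` methods; `predict()`/`back_calculate()` yields one observation
per fish-annulus, labelled with the calendar year in which that annulus
formed (the last annulus is assigned the year before capture).

Downstream, `pool_by_age()` assembles per-age cohorts, `cohort_anova()` runs
an additive two-way ANOVA (`length ~ status + year`, Type II sums of squares
for the unbalanced designs) per age with an a posteriori power analysis based
on Cohen's f² and the noncentral F distribution, `cohort_summary_table()`
builds the descriptive per-age comparison (means, standard errors, absolute
and midpoint-percent differences), and `loess_trend()`/`plot_cohorts()` draw
LOESS (span 0.95) year-class trends with 95% confidence bands.
`simulate_population()` generates populations with known ground truth (von
Bertalanffy growth, individual variability, a year-class trend and a mid-life
protection effect) so every stage can be validated against truth.

## Worked example

```r
library(mfbc)

sim <- simulate_population(sim_config(rng_seed = 2015))  # 111 MR + 159 FR fish
fit <- mfbc(sim$fish)
fit
#> Modified Fry back-calculation model
#>   fish: 270  ( 1013 annulus readings )
#>   allometry  L = a + b * R^c   [ nls ]
#>       a       b       c
#>  6.6251 56.3894  0.8767
#>   anchors: R0p = 0.5449  L0p = 39.74

obs <- back_calculate(fit)
res <- cohort_anova(obs)
res[res$age %in% c(1, 4, 6, 12),
    c("age", "n", "gate", "status_F", "status_p", "year_F", "year_p", "power")]
#>  age   n                gate status_F status_p year_F   year_p power
#>    1 263            analyzed    0.448   0.5040   3.51 0.000135 0.103
#>    4 121            analyzed   10.700   0.0014   1.65 0.118000 0.906
#>    6  61            analyzed    5.730   0.0202   1.51 0.193000 0.668
#>   12   3 skipped_single_year       NA       NA     NA       NA    NA
```

The fitted allometry recovers the simulator's generating constants (a = 8,
b = 55, c = 0.9) up to sampling noise. At age 1 the reserve and fished
populations are statistically indistinguishable (status F = 0.45, p = 0.50)
while the year effect is already strong (p < 0.001, younger year classes
larger); by ages 4–6 the injected mid-life protection effect produces clear
status effects (e.g. F = 10.7, p = 0.001 at age 4, with a posteriori power
0.91). Age 12 is gated (`skipped_single_year`): all of its observations
belong to a single year class, so no two-way model can be fitted.

```r
tab <- cohort_summary_table(obs)
tab[tab$age %in% c(1, 4, 8), ]
#>  age mr_n mr_mean mr_se fr_n fr_mean fr_se absolute_diff percent_diff
#>    1  108   40.10  0.45  155   39.47  0.36          0.63         1.60
#>    4   46   75.62  1.27   75   70.92  0.88          4.70         6.42
#>    8   13   93.59  2.38   11   86.62  3.25          6.97         7.74

plot_cohorts(obs, res, file = "cohorts.pdf")   # LOESS panels per age
```

A complete seeded run — simulate (or read a CSV), fit, back-calculate, pool,
analyze, plot, with every artefact written to a directory — is one call:

```r
run <- run_pipeline(list(), out_dir = "run1", seed = 7)
```

Field data are read with `read_fish_table()` (long format, one row per
fish-annulus, or wide format with `r1..rN` columns).

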