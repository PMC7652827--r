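# canopyhazard

Tools for asking **how and why trees die** from long-term forest-census
data: networks of permanent plots in which every stem ≥ 10 cm diameter is
tagged, measured at irregular intervals, and — when found dead — diagnosed
as having died *standing* (physiological failure) or *broken/uprooted*
(structural failure). The package is aimed at forest ecologists and
demographers working with such inventories (e.g. Amazonian plot networks),
and at modellers who need empirically grounded mortality risk functions.

It implements, as tested and reusable components:

* **Demographic rates.** Annualised mortality per census interval,
  `m = (1 − (N_t1/N_t0)^(1/T)) × 100` (% yr⁻¹), aggregated to plots by
  census-interval-weighted means, and to regions/basin by area-weighted
  bootstrap means with percentile 95% CIs; Tukey HSD comparisons with
  compact letter displays; mode-specific rates (survivors of a mode include
  trees dying by the other mode).
* **Mode-of-death bias correction.** Standing deaths break while they wait
  to be found, so the broken/uprooted proportion inflates with the census
  interval. The correction fits `Pmod = β0 + β1·CIL̄ + ε` with the mean
  census-interval length centred to zero and reports the intercept as the
  corrected proportion; a region term gives interval-adjusted regional
  proportions with Tukey-adjusted pairwise contrasts.
* **Survival records.** Tree-level covariates (diameter `D` in metres, with
  optional `D²`; relative growth `100·((D_t1−D_t0)/T)/D_t0` in % yr⁻¹ from
  the antepenultimate→penultimate censuses) plus species traits (max
  diameter, mean growth, wood density, water-deficit affiliation) attached
  through a species → genus → family → plot imputation cascade; palm and
  impossible-shrinkage exclusions; single-record or counting-process
  (left-truncated, time-varying) representations.
* **A proportional-hazards engine, written from scratch** (Rcpp):
  `h(t) = h0(t)·exp(X′β + zb)` with a log-normal per-plot frailty `b`
  estimated by penalized partial likelihood (variance profiled on a Laplace
  marginal likelihood), Efron/Breslow ties, per-term Wald χ², AIC model
  ladders, bidirectional stepwise selection and VIF screening, plus
  mode-specific (cause-specific) refits.
* **A synthetic forest generator** with known ground truth — hazard
  coefficients, plot frailties, true modes of death, post-mortem breakage
  and trait missingness — so every stage above is validated by simulation
  without access-controlled field data.

## Worked example

```r
library(canopyhazard)

sim <- simulate_forest(sim_config(n_plots_per_region = 12, n_species = 400,
                                  stem_density_ha = 400), seed = 2024)
ds  <- filter_plots(sim$data)                 # gap/area/elevation filters
pr  <- plot_mortality_rate(ds)                # one rate per plot
regional_rate_summary(pr, B = 10000, seed = 2024)
#>   scope        mean ci_lo ci_hi n_plots     B
#> 1 EastCentral  3.10  2.24  3.91      12 10000
#> 2 Northern     1.73  1.30  2.32      12 10000
#> 3 Southern     2.28  1.74  2.83      12 10000
#> 4 Western      1.87  1.56  2.18      12 10000
#> 5 Basin        2.26  1.91  2.64      48 10000
```

Plot-level mortality sits around 2% yr⁻¹ with bootstrap CIs per region —
the scale observed in real lowland tropical networks (regional differences
here reflect sampling noise plus plot frailty, not built-in regional
effects).

```r
mp <- plot_mode_proportions(ds)
fit_cil_correction(mp)
#> CIL-corrected broken_uprooted proportion: 0.568 (SE 0.009)
#> slope 0.0372 yr^-1 (p = 0.178), R^2 = 0.039, n = 48 plots
```

The corrected broken/uprooted share (56.8%) is the proportion a plot
censused at the network's mean interval would record; the positive slope is
the census-interval bias created by the generator's 0.04 yr⁻¹ post-mortem
breakage rate.

```r
rec <- assemble_survival_records(filter_plots(ds, min_censuses = 3))
fit_cox(rec, frailty = TRUE)
#> Cox proportional-hazards fit (efron ties), plot frailty theta = 0.367
#> n = 24167, events = 4607, loglik = -43502.550, AIC = 87021.10
#>                  coef      se  chisq        p
#> rel_growth    9.0e-03 0.02200   0.16  6.9e-01
#> D            -1.4e+01 0.64000 450.00 4.0e-100
#> D2            1.7e+01 1.20000 220.00  1.0e-48
#> max_d        -2.1e-03 0.00014 220.00  4.4e-49
#> mean_growth   1.5e-01 0.02200  47.00  8.9e-12
#> wood_density -6.5e-01 0.09900  43.00  5.2e-11
#> wda           1.5e-04 0.00014   1.20  2.7e-01
```

Coefficients are log hazard ratios on natural scales: smaller trees,
smaller-statured and faster-growing species, and lighter-wooded species die
faster, and the recovered frailty variance (0.37) reflects the plot
heterogeneity the generator injected (0.25, estimated here from 48 plots).
`model_ladder()`, `stepwise_aic()`, `fit_by_mode()` and
`run_full_analysis()` continue from these records; `tidy()`, `glance()` and
`autoplot()` work on the fitted objects. A command-line wrapper for the
pipeline lives at `inst/cli/canopyhazard.R`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the package's full pipeline from scratch — simulating a 48-plot
forest network at the given seed, then validating, filtering, estimating
rates with the 10,000-replicate bootstrap, correcting mode-of-death
proportions, assembling survival records and fitting the hazard-model
ladder — failing (non-zero exit) if any stage fails, and writes the JSON
results object to `--out`.

## Vignette

`vignettes/canopyhazard-methods.Rmd` documents the models and their
assumptions, every tunable threshold with units and defaults, what the
synthetic forest does and does not emulate, and the numerical choices in
the frailty engine.
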