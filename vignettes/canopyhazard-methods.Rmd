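---
title: "Models and methods behind canopyhazard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind canopyhazard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

canopyhazard analyses tree mortality in networks of permanent forest
inventory plots: repeated censuses of every stem at least 10 cm in diameter,
with dead trees diagnosed as having died *standing* (suggesting
physiological failure) or *broken/uprooted* (structural failure). This
vignette describes the statistical models, the choices we made where the
methodology was genuinely open, and what the synthetic-data tests do and do
not establish.

## Demographic rates

The annualised mortality rate over one census interval of length $T$ years
is

$$m = \left(1 - \left(\tfrac{N_{t1}}{N_{t0}}\right)^{1/T}\right)\times 100,$$

where $N_{t0}$ trees were alive at the first census and $N_{t1}$ of them
survived to the second. `interval_mortality_rate()` implements this; the
quantity is exactly invariant to splitting an interval in two (survival
fractions compound), which the tests verify on random instances. Plot-level
rates are the mean of per-interval rates weighted by interval length
(`plot_mortality_rate()`). Trees recruited mid-record enter the counts at
their first alive census; stems that disappear without a death record are
censored out of both $N_{t0}$ and $N_{t1}$ for subsequent intervals — the
source protocol does not say how such "lost" stems were handled, so we chose
the convention that never fabricates a death.

Mode-specific rates apply the same formula with $N_{t1}$ equal to
$N_{t0}$ minus the deaths of the target mode only: trees dying by the other
mode (or with an unassessed mode) count as survivors of that cause. A plot
enters mode-of-death analyses only when at least half of its dead trees and
at least five trees have an assessed mode.

Regional and basin summaries are area-weighted bootstrap means
(`bootstrap_weighted_mean()`): plots are resampled uniformly with
replacement, each replicate is the area-weighted mean of the resampled
plots, and the 95% interval is the percentile interval over (by default)
10,000 replicates. Weights enter the replicate mean, not the sampling
probabilities — the most literal reading of "weighted means of randomly
resampled values" — and we use plain percentile intervals rather than BCa.
Regions are compared with Tukey's HSD on plot-level rates (homoscedastic
one-way ANOVA, as is conventional), with a compact letter display computed
exactly by enumerating maximal cliques of the non-significance graph (the
number of regions is small).

Because the regional aggregation could weight by area within regions or
basin-wide only, `regional_rate_summary()` weights within each region by
plot area (and the basin row across all plots); this is the default and the
only variant we report.

## Census-interval bias in the mode of death

A tree that dies standing may break before the next visit, so the recorded
proportion of broken/uprooted deaths grows with the census interval. The
correction regresses the plot-level proportion of one mode on the plot's
mean census-interval length (CIL), centred to mean zero,

$$P_{\mathrm{mod}} = \beta_0 + \beta_1\,\overline{\mathrm{CIL}} + \varepsilon,$$

and reports the intercept $\beta_0$ — the proportion at the across-plot
mean interval — as the corrected value (`fit_cil_correction()`). Proportions
are modelled on the identity scale with unweighted ordinary least squares;
out-of-$[0,1]$ corrected values are reported with a warning and never
silently clipped. Adding a region factor to the same model
(`fit_regional_mode_model()`) yields regional proportions adjusted to the
common mean interval, with t-based intervals on the adjusted means and
all pairwise regional contrasts given studentized-range (Tukey) adjusted
p-values. Centring always uses the mean over the plots entering the
specific fit. We emit confidence intervals on the adjusted means (not the
region coefficients) as the headline quantity, since those are what the
regional tables compare.

Under the generator's breakage model (below) the expected standing
proportion at interval length $c$ is $p_s\,(1-e^{-rc})/(rc)$, nearly linear
over realistic intervals, so the OLS slope estimates the linearised flip
rate; the acceptance tests verify that $\beta_1$ and $\beta_0$ cover their
population values computed by numerical integration.

## Survival records and covariates

The hazard model uses two tree-level covariates — diameter $D$ (entered in
metres, with an optional quadratic term for the U-shaped size-mortality
relationship) and relative growth

$$\mathrm{rel.growth} = 100 \times \frac{(D_{t1}-D_{t0})/T}{D_{t0}}
\quad [\%\,\mathrm{yr}^{-1}],$$

measured between the antepenultimate and penultimate censuses at which the
tree was observed — and four species-level traits: maximum diameter (mm,
95th quantile of the species size distribution), mean diameter growth
(mm yr$^{-1}$), wood density (g cm$^{-3}$) and water-deficit affiliation
(mm; more negative = more drought-affiliated). Units are fixed and asserted
at I/O: diameters are mm in files and metres in model matrices, which puts
the size coefficients on the order of 10.

Missing species traits cascade: species value, then the genus mean (over
species), then the family mean, then the individual-weighted mean over the
tree's plot; the level used is recorded per trait so masking experiments
can audit the cascade. Palms are excluded (no secondary growth), as are
records with relative growth below $-5\%$ yr$^{-1}$ (biologically
impossible shrinkage, i.e. measurement error).

Two representations of time-at-risk are provided:

* **single** (default, matching the headline convention of the source
  analysis): one record per tree, entry at its first alive census, exit at
  the death census (or, optionally, the interval midpoint) or last alive
  census, covariates frozen at the final two pre-exit observations.
* **counting**: one row per tree per census interval, $(t_k, t_{k+1}]$ in
  calendar years with left truncation, diameter from the interval-start
  census and relative growth from the interval before it.

The single-record convention measures covariates at systematically
different times for dead versus surviving trees (just before death versus
mid-record), which is fine for descriptive risk ranking but biased by
construction against a known generating model — our simulations show it can
even flip the sign of a weak growth effect. All parameter-recovery
experiments therefore use the counting representation with midpoint death
times, which removes both the differential timing and most of the
"zombie exposure" of trees that died early in a long interval. Users can
switch via `assemble_survival_records(representation=, death_time=,
risk_from=)`.

## The proportional-hazards engine

Mortality risk is modelled as

$$h(t) = h_0(t)\,\exp(X'\beta + z b),$$

with $X$ the covariates above and $b$ a per-plot random intercept
capturing shared plot conditions. The partial likelihood, score and
observed information are computed in compiled code with incremental
risk-set accumulation, supporting Efron (default — census data are heavily
tied) and Breslow tie handling and left-truncated (start–stop) rows.
Newton–Raphson with step-halving iterates to a relative log-likelihood
change below $10^{-9}$ (at most 50 iterations).

The frailty is log-normal with mean 1 on the hazard scale, estimated by
penalized partial likelihood: for fixed variance $\theta$ the penalty is
$-\sum_j b_j^2/(2\theta)$, and $\theta$ is chosen by maximising the
Laplace-approximate marginal likelihood

$$\ell_m(\theta) = \ell_p(\hat\beta,\hat b) - \frac{\hat b'\hat b}{2\theta}
 - \frac{q}{2}\log\theta - \frac12\log\det\!\big(H_{bb} + I/\theta\big),$$

profiled on a coarse grid refined by golden-section search; the profile is
continuous down to $\theta \to 0$ (no heterogeneity), so the boundary needs
no special casing. Standard errors come from the penalized observed
information. A gamma-frailty EM backend was considered and not built: the
log-normal penalized formulation is a single coherent likelihood, it is the
default of the reference implementations practitioners use for "plot as a
random effect", and the simulations recover $\theta \in \{0, 0.25, 1\}$
accurately with it, so a second backend would only duplicate the oracle
cross-checks.

Per-term $\chi^2$ is the Wald statistic $(\beta/\mathrm{SE})^2$ (the
conventional display); a likelihood-ratio counterpart via drop-one refits
is available (`term_lr_chisq()`) and agrees within 15% on well-behaved
fits. AIC is $-2\ell + 2k$ with $k$ the number of fixed-effect terms plus
one when $\theta$ is estimated, using the marginal likelihood for frailty
fits; model ranking (`model_ladder()`) treats differences above 2 as
meaningful. Stepwise selection (`stepwise_aic()`) is bidirectional from the
full model, respects the $D/D^2$ hierarchy, re-estimates the frailty at
every candidate, and — because a greedy path can stall above the null
model — falls back to a forward pass from the null if that has lower AIC,
guaranteeing the selected AIC is at most the minimum of the full and null
models. Collinearity is screened with variance-inflation factors
($1/(1-R^2_j)$, flagging $>10$). Mode-specific fits (`fit_by_mode()`)
treat deaths of the other (or unknown) mode as censored at the death time,
i.e. cause-specific hazards.

Covariates enter unstandardised so coefficients are on natural scales.

## The synthetic forest

`sim_config()`/`simulate_forest()` generate a monitoring network with known
truth: four regions, 0.5–2 ha plots, irregular census schedules averaging
2.8 years (Gaussian jitter, truncated at 1 year), a species pool with
log-normal abundances and realistic trait distributions, initial stem
diameters roughly exponential above the 100 mm threshold, and per-tree
growth equal to the species mean times a log-normal individual multiplier.
Death times are drawn *exactly* by inversion from the piecewise-constant
hazard defined by the census segments — no continuous-time approximation —
with covariates updated at each census; the growth covariate in the hazard
is the tree's relative growth over the previous interval, which is what
the measurable quantity estimates. Recruits cross the threshold at a
quasi-equilibrium flux and enter observation at their first census after
crossing (this closed-form draw replaces an explicit burn-in; the knob
`recruit_turnover` sets the flux). Measured diameters add Gaussian noise
(default 1 mm, clamped at the 100 mm floor).

The baseline `h0` is the annual hazard of a tree with reference covariates
(a typical stem), which keeps it interpretable as a rate; the default
0.016 yr$^{-1}$ together with the default coefficients yields a realized
basin-wide rate of about 1.9% yr$^{-1}$, inside the 1.3–2.8% yr$^{-1}$
range reported for Amazon regions. Default coefficient magnitudes follow
the published basin-wide fit for growth, size-trait, wood-density and
drought-affiliation terms; the two size terms default to a mild U-shape
($-8, +8$ per m and m$^2$) because the published pair, used *generatively*
with a realistic size distribution, implies an implausibly large hazard
amplitude across the 10–50 cm range and makes a ~2% yr$^{-1}$ mean rate
unreachable. The frailty variance defaults to 0.25 (moderate plot
heterogeneity; nothing is published to pin it).

Mode of death is drawn at death: standing with probability
$\mathrm{logit}^{-1}(a_0 + a_1\,\mathrm{rel.growth})$, $a_1 < 0$ by default
so slow growers tend to die standing. A standing death found $\tau$ years
later is recorded broken/uprooted with probability $1-e^{-r\tau}$
(`degrade_mode_of_death()`, default $r = 0.04$ yr$^{-1}$, the regime the
bias correction targets), and a configurable fraction of deaths
(default 30%) is left unassessed. `mask_traits()` removes trait values at
species, genus and family level (defaults 14%, 6%, 3%) so the imputation
cascade is exercised end to end.

What the generator does **not** emulate: spatially explicit treefall gaps
or any spatial autocorrelation beyond the plot frailty, climate time
series and temporal trends in rates, species interactions,
point-of-measurement changes, and taxonomic noise. A green simulation test
therefore establishes that the estimators recover the stated generative
world — not that any of these field complications are handled.

## Numerical and degenerate-input choices

* Validation rejects non-monotone census dates, duplicate
  (plot, tree, census) keys, alive diameters under 100 mm, repeated or
  posthumous life status, and modes of death on living trees — each with
  the offending identifier in the message.
* Plots closer than 1 km merge only when their census schedules align
  index-by-index within 0.5 years (and have equal length); incompatible
  candidates are reported, not silently merged. Merged plots must share a
  region label; a conflict aborts.
* Empty filter results warn rather than error; an all-censored likelihood
  is 0 with a warning; exact collinearity reports an infinite VIF; a
  singular information matrix aborts with a perfect-separation hint.
* Bootstrap, simulation and masking are deterministic given their seed
  (isolated RNG scopes), and the pipeline manifest records every seed and
  threshold, so a run is reproducible from the manifest alone.

## Scaling of the validation suite

The replicated acceptance experiments (coefficient recovery, frailty
recovery, interval-bias correction, bootstrap coverage, stepwise pruning,
mode-specific contrasts) are sized to finish in roughly ten minutes on one
CPU: 200 replicates of ~5,000-tree worlds for coefficient recovery and the
bias correction, 10 replicates per frailty variance, 500 bootstrap
landscapes, 100 stepwise and 60 mode-contrast replicates, and a single
~23,000-tree world for the model ladder. Thresholds are the criteria
themselves (bias under 10%, coverage within stated bands, orderings in at
least the stated fraction of replicates); only replicate counts were
scaled.
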