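#' Configuration for the synthetic forest-census generator
#'
#' The defaults describe a realistic pan-Amazonian monitoring network: four
#' geological regions, 0.5–2 ha plots, irregular census intervals averaging
#' 2.8 years, trees entering at the 10 cm diameter threshold, and a
#' proportional-hazards mortality process
#' `h(t) = h0 * exp((X - X_ref)' beta + b_plot)` whose covariates (tree
#' diameter and relative growth, species maximum size, mean growth, wood
#' density and water-deficit affiliation) are updated piecewise-constant at
#' each census. `h0` is the annual hazard of a tree with reference covariates
#' `X_ref`, which makes it directly interpretable as a baseline mortality
#' rate. Dead trees die standing with a probability that decreases
#' logistically with relative growth (slow growers tend to die standing);
#' standing deaths found `tau` years later are mis-recorded as
#' broken/uprooted with probability `1 - exp(-breakage_rate * tau)`.
#'
#' @param n_plots_per_region Plots simulated in each of the four regions.
#' @param plot_area_range Plot area range, hectares.
#' @param stem_density_ha Expected live stems (>= 10 cm) per hectare.
#' @param n_species Number of species in the regional pool.
#' @param beta Named true log-hazard coefficients for the terms
#'   `D` (m), `D2` (m^2), `rel_growth` (% yr^-1), `max_d` (mm),
#'   `mean_growth` (mm yr^-1), `wood_density` (g cm^-3), `wda` (mm). Terms
#'   omitted from the vector get coefficient 0.
#' @param h0 Annual hazard of the reference tree (events yr^-1).
#' @param frailty_var Variance of the log-normal plot frailty on the log
#'   hazard scale (mean 1 on the hazard scale).
#' @param census_interval_mean,census_interval_sd,census_interval_min Census
#'   schedule: intervals are Gaussian with this mean/sd, truncated below.
#' @param horizon_yr Monitoring horizon per plot, years (must exceed twice
#'   the mean interval so at least three censuses exist).
#' @param standing_intercept,standing_slope Logistic model (on the logit
#'   scale) for the probability that a death is a standing death as a
#'   function of the tree's relative growth (% yr^-1).
#' @param breakage_rate Post-mortem breakage rate, yr^-1: a tree that died
#'   standing and is found `tau` years later is recorded broken/uprooted
#'   with probability `1 - exp(-breakage_rate * tau)`.
#' @param assess_prob Probability that a death has its mode assessed.
#' @param measure_sd_mm Diameter measurement noise sd, mm.
#' @param growth_sdlog sdlog of the individual log-normal growth multiplier
#'   (mean 1) applied to the species mean growth rate.
#' @param missing_rates Named rates (`species`, `genus`, `family`) used by
#'   [mask_traits()].
#' @param palm_frac Fraction of species that are palms (family Arecaceae).
#' @param recruit_turnover Annual recruitment flux as a fraction of the
#'   initial stand (balances mortality at quasi-equilibrium).
#' @param wd_mean,wd_sd,max_d_meanlog,max_d_sdlog,mean_growth_meanlog,
#'   mean_growth_sdlog,wda_mean,wda_sd Species-trait distributions.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_plots_per_region = 47,
                       plot_area_range = c(0.5, 2),
                       stem_density_ha = 520,
                       n_species = 3800,
                       beta = c(D = -8, D2 = 8, rel_growth = -0.08,
                                max_d = -0.002, mean_growth = 0.2,
                                wood_density = -0.7, wda = -1e-4),
                       h0 = 0.016,
                       frailty_var = 0.25,
                       census_interval_mean = 2.8,
                       census_interval_sd = 0.8,
                       census_interval_min = 1,
                       horizon_yr = 12,
                       standing_intercept = 0.3,
                       standing_slope = -0.5,
                       breakage_rate = 0.04,
                       assess_prob = 0.7,
                       measure_sd_mm = 1,
                       growth_sdlog = 0.5,
                       missing_rates = c(species = 0.14, genus = 0.06,
                                         family = 0.03),
                       palm_frac = 0.05,
                       recruit_turnover = 0.018,
                       wd_mean = 0.65, wd_sd = 0.15,
                       max_d_meanlog = log(350), max_d_sdlog = 0.35,
                       mean_growth_meanlog = log(1.3),
                       mean_growth_sdlog = 0.6,
                       wda_mean = -200, wda_sd = 120) {
  cfg <- as.list(environment())
  if (cfg$n_plots_per_region < 1 || cfg$n_species < 1)
    abort("need at least one plot per region and one species",
          class = "canopyhazard_config_error")
  if (cfg$h0 < 0 || cfg$breakage_rate < 0 || cfg$frailty_var < 0 ||
      cfg$measure_sd_mm < 0 || cfg$recruit_turnover < 0)
    abort("rates and variances must be non-negative",
          class = "canopyhazard_config_error")
  if (cfg$assess_prob < 0 || cfg$assess_prob > 1 ||
      any(cfg$missing_rates < 0) || any(cfg$missing_rates > 1))
    abort("probabilities must lie in [0, 1]",
          class = "canopyhazard_config_error")
  if (cfg$horizon_yr <= 2 * cfg$census_interval_mean)
    abort("horizon must exceed twice the mean census interval",
          class = "canopyhazard_config_error")
  full_beta <- setNames(numeric(length(.term_names)), .term_names)
  full_beta[names(cfg$beta)] <- cfg$beta
  cfg$beta <- full_beta
  structure(cfg, class = "sim_config")
}

# reference covariates at which the hazard equals h0 (near the means of the
# default stand and trait distributions, so h0 reads as a typical-tree rate)
.sim_ref <- c(D = 0.21, D2 = 0.0441, rel_growth = 0.9, max_d = 370,
              mean_growth = 1.55, wood_density = 0.65, wda = -195)

sim_species_pool <- function(cfg) {
  n <- cfg$n_species
  n_gen <- max(1L, ceiling(n / 3))
  n_fam <- max(1L, ceiling(n_gen / 4))
  genus_of <- sample.int(n_gen, n, replace = TRUE)
  fam_of_gen <- sample.int(n_fam, n_gen, replace = TRUE)
  n_palm <- round(cfg$palm_frac * n)
  is_palm_sp <- seq_len(n) <= n_palm
  fam <- ifelse(is_palm_sp, "Arecaceae", paste0("Fam", fam_of_gen[genus_of]))
  genus <- ifelse(is_palm_sp, paste0("Palmus", genus_of),
                  paste0("Genus", genus_of))
  tibble(
    species = paste0(genus, " sp", seq_len(n)),
    genus = genus, family = fam, is_palm = is_palm_sp,
    wood_density = pmin(1.1, pmax(0.2, rnorm(n, cfg$wd_mean, cfg$wd_sd))),
    max_d = pmax(150, rlnorm(n, cfg$max_d_meanlog, cfg$max_d_sdlog)),
    mean_growth = rlnorm(n, cfg$mean_growth_meanlog, cfg$mean_growth_sdlog),
    wda = pmin(0, rnorm(n, cfg$wda_mean, cfg$wda_sd)),
    abundance = rlnorm(n, 0, 1.5))
}

.region_boxes <- list(
  Northern = list(lat = c(0, 4), lon = c(-63, -57)),
  EastCentral = list(lat = c(-5, -1), lon = c(-55, -49)),
  Western = list(lat = c(-8, -2), lon = c(-75, -69)),
  Southern = list(lat = c(-14, -10), lon = c(-64, -56)))

sim_plot_table <- function(cfg) {
  purrr::map_dfr(.regions, function(rg) {
    n <- cfg$n_plots_per_region
    box <- .region_boxes[[rg]]
    tibble(
      plot_id = sprintf("%s-%02d", substr(rg, 1, 3), seq_len(n)),
      region = rg,
      area_ha = runif(n, cfg$plot_area_range[1], cfg$plot_area_range[2]),
      lat = runif(n, box$lat[1], box$lat[2]),
      lon = runif(n, box$lon[1], box$lon[2]),
      elev_m = runif(n, 50, 400))
  })
}

sim_census_dates <- function(cfg) {
  start <- 1990 + runif(1, 0, 5)
  dates <- start
  while (tail(dates, 1) - start < cfg$horizon_yr) {
    gap <- max(cfg$census_interval_min,
               rnorm(1, cfg$census_interval_mean, cfg$census_interval_sd))
    dates <- c(dates, tail(dates, 1) + gap)
  }
  dates
}

#' Simulate a forest-census dataset with known ground truth
#'
#' Generates plots, a species pool with traits, and tree histories whose
#' death times are drawn exactly (by inversion, segment by segment) from the
#' piecewise-constant proportional hazard defined in [sim_config()]. Trees
#' are observed only at their plot's censuses: diameters carry measurement
#' noise, deaths are discovered at the first census after they occur, the
#' recorded mode of death is degraded by post-mortem breakage, and a fraction
#' of deaths is left unassessed.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; the simulation is deterministic given the seed.
#' @return A list with `data` (a [census_dataset()]) and `truth` (a list of
#'   tibbles: `trees` with true death time, true mode and entry time;
#'   `plots` with the per-plot frailty on the log-hazard scale).
#' @export
simulate_forest <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(as.integer(seed), simulate_forest_impl(cfg))
}

simulate_forest_impl <- function(cfg) {
  species <- sim_species_pool(cfg)
  plots <- sim_plot_table(cfg)
  nplot <- nrow(plots)
  b_plot <- if (cfg$frailty_var > 0)
    rnorm(nplot, -cfg$frailty_var / 2, sqrt(cfg$frailty_var)) else rep(0, nplot)

  all_obs <- vector("list", nplot)
  all_truth <- vector("list", nplot)
  sched_list <- vector("list", nplot)
  bnames <- .term_names
  beta <- cfg$beta[bnames]

  for (ip in seq_len(nplot)) {
    dates <- sim_census_dates(cfg)
    sched_list[[ip]] <- dates
    K <- length(dates)
    n_init <- rpois(1, plots$area_ha[ip] * cfg$stem_density_ha)
    span <- dates[K] - dates[1]
    n_rec <- rpois(1, n_init * cfg$recruit_turnover * span)
    n <- n_init + n_rec
    if (n == 0) next
    sp_idx <- sample.int(nrow(species), n, replace = TRUE,
                         prob = species$abundance)
    g <- species$mean_growth[sp_idx] *
      rlnorm(n, -cfg$growth_sdlog^2 / 2, cfg$growth_sdlog)
    # recruits cross the 100 mm threshold at a uniform time in the record
    cross <- c(rep(dates[1], n_init), runif(n_rec, dates[1], dates[K]))
    d_at_cross <- c(pmin(100 + rexp(n_init, 1 / 110),
                         1.1 * species$max_d[sp_idx[seq_len(n_init)]]),
                    rep(100, n_rec))
    # entry = first census at or after crossing
    entry_k <- findInterval(cross, dates, left.open = TRUE) + 1L
    entry_k <- pmin(entry_k, K)
    entry_t <- dates[entry_k]
    d_entry <- d_at_cross + g * (entry_t - cross)

    # true diameter at each census (NA before entry)
    Dmat <- outer(rep(1, n), dates)
    Dmat <- d_entry + g * (Dmat - entry_t)
    Dmat[Dmat < 0] <- 0

    # piecewise-constant hazard per census segment
    E <- rexp(n)
    death_t <- rep(NA_real_, n)
    rg_at_death <- rep(NA_real_, n)
    cum <- numeric(n)
    alive <- rep(TRUE, n)
    for (k in seq_len(K - 1)) {
      at_risk <- alive & entry_k <= k
      if (!any(at_risk)) next
      Dk <- Dmat[at_risk, k] / 1000
      # growth covariate is the tree's relative growth over the PREVIOUS
      # census interval (growth prior to the segment), matching how it can
      # be measured; in the entry segment the current-census value stands in
      kprev <- ifelse(entry_k[at_risk] >= k, k, k - 1L)
      Dprev <- Dmat[cbind(which(at_risk), kprev)]
      rg <- 100 * g[at_risk] / pmax(Dprev, 100)
      X <- cbind(rel_growth = rg, D = Dk, D2 = Dk^2,
                 max_d = species$max_d[sp_idx[at_risk]],
                 mean_growth = species$mean_growth[sp_idx[at_risk]],
                 wood_density = species$wood_density[sp_idx[at_risk]],
                 wda = species$wda[sp_idx[at_risk]])[, bnames, drop = FALSE]
      eta <- drop((X - matrix(.sim_ref[bnames], nrow(X), length(bnames),
                              byrow = TRUE)) %*% beta)
      h <- cfg$h0 * exp(eta + b_plot[ip])
      len <- dates[k + 1] - dates[k]
      add <- h * len
      idx <- which(at_risk)
      dies <- cum[idx] + add >= E[idx] & h > 0
      if (any(dies)) {
        di <- idx[dies]
        death_t[di] <- dates[k] + (E[di] - cum[di]) / h[dies]
        rg_at_death[di] <- rg[dies]
        alive[di] <- FALSE
      }
      cum[idx] <- cum[idx] + add
    }

    p_standing <- plogis(cfg$standing_intercept +
                           cfg$standing_slope * rg_at_death)
    true_mode <- ifelse(is.na(death_t), NA_character_,
                        ifelse(runif(n) < p_standing, "standing",
                               "broken_uprooted"))
    found_k <- ifelse(is.na(death_t), NA_integer_,
                      findInterval(death_t, dates, left.open = TRUE) + 1L)

    tree_id <- sprintf("%s-t%05d", plots$plot_id[ip], seq_len(n))
    # build observation rows census by census
    obs <- purrr::map_dfr(seq_len(K), function(k) {
      live <- which(entry_k <= k & (is.na(death_t) | death_t > dates[k]))
      dead_now <- which(!is.na(found_k) & found_k == k & entry_k <= k)
      rows <- list()
      if (length(live)) {
        d_meas <- pmax(100, Dmat[live, k] +
                         rnorm(length(live), 0, cfg$measure_sd_mm))
        rows$alive <- tibble(
          tree = live, census_date = dates[k], d_mm = d_meas,
          status = "alive", mode_of_death = "not_applicable")
      }
      if (length(dead_now)) {
        rows$dead <- tibble(
          tree = dead_now, census_date = dates[k], d_mm = NA_real_,
          status = "dead", mode_of_death = "unassessed")
      }
      bind_rows(rows)
    })
    obs$plot_id <- plots$plot_id[ip]
    obs$tree_id <- tree_id[obs$tree]
    obs$species <- species$species[sp_idx[obs$tree]]
    obs$genus <- species$genus[sp_idx[obs$tree]]
    obs$family <- species$family[sp_idx[obs$tree]]
    obs$is_palm <- species$is_palm[sp_idx[obs$tree]]
    all_obs[[ip]] <- obs |> select(-"tree")

    all_truth[[ip]] <- tibble(
      tree_id = tree_id, plot_id = plots$plot_id[ip],
      species = species$species[sp_idx],
      entry_time = entry_t,
      death_time = death_t,
      found_time = ifelse(is.na(found_k), NA_real_, dates[pmax(found_k, 1)]),
      true_mode = true_mode,
      growth_mm_yr = g) |>
      filter(!is.na(.data$death_time) | .data$entry_time <= dates[K])
  }

  trees <- bind_rows(all_obs)
  truth_trees <- bind_rows(all_truth)
  traits <- species |> select(-"abundance", -"is_palm")
  ds <- census_dataset(plots, trees, traits, validate = FALSE)
  truth <- list(trees = truth_trees,
                plots = tibble(plot_id = plots$plot_id, frailty = b_plot))

  # record assessed modes, then post-mortem breakage degradation
  ds <- apply_mode_recording(ds, truth, cfg$assess_prob)
  ds <- degrade_mode_of_death_impl(ds, truth, cfg$breakage_rate)
  list(data = ds, truth = truth)
}

apply_mode_recording <- function(ds, truth, assess_prob) {
  dead <- which(ds$trees$status == "dead")
  if (!length(dead)) return(ds)
  key <- paste(ds$trees$plot_id[dead], ds$trees$tree_id[dead])
  tkey <- paste(truth$trees$plot_id, truth$trees$tree_id)
  mode <- truth$trees$true_mode[match(key, tkey)]
  assessed <- runif(length(dead)) < assess_prob
  ds$trees$mode_of_death[dead] <- ifelse(assessed, mode, "unassessed")
  ds
}

#' Degrade recorded modes of death by post-mortem breakage
#'
#' Trees that truly died standing but are only found `tau` years later may
#' have broken in the meantime and are then recorded as broken/uprooted, with
#' probability `1 - exp(-r * tau)`. Truly broken/uprooted trees are never
#' recorded standing.
#'
#' @param ds A [census_dataset()] whose dead records carry assessed modes.
#' @param truth The truth list from [simulate_forest()] (used for the true
#'   death times and true modes).
#' @param r Breakage rate, yr^-1 (must be >= 0).
#' @param seed Integer seed.
#' @return The dataset with degraded `mode_of_death` entries.
#' @export
degrade_mode_of_death <- function(ds, truth, r, seed = 1) {
  if (r < 0) abort("breakage rate must be non-negative",
                   class = "canopyhazard_config_error")
  withr::with_seed(as.integer(seed),
                   degrade_mode_of_death_impl(ds, truth, r))
}

degrade_mode_of_death_impl <- function(ds, truth, r) {
  if (r == 0) return(ds)
  dead <- which(ds$trees$status == "dead" &
                  ds$trees$mode_of_death == "standing")
  if (!length(dead)) return(ds)
  key <- paste(ds$trees$plot_id[dead], ds$trees$tree_id[dead])
  tkey <- paste(truth$trees$plot_id, truth$trees$tree_id)
  m <- match(key, tkey)
  truly_standing <- truth$trees$true_mode[m] == "standing"
  tau <- pmax(0, ds$trees$census_date[dead] - truth$trees$death_time[m])
  flip <- truly_standing & runif(length(dead)) < 1 - exp(-r * tau)
  ds$trees$mode_of_death[dead][flip] <- "broken_uprooted"
  ds
}

#' Mask species-trait values hierarchically
#'
#' Introduces missingness the way real trait compilations are incomplete:
#' individual species lose a trait value at rate `rates["species"]`, whole
#' genera at rate `rates["genus"]` (all member species lose the value, so the
#' family branch of the imputation cascade is exercised) and whole families
#' at rate `rates["family"]` (forcing the plot-level fallback).
#'
#' @param traits A species-trait tibble (see [read_trait_table()]).
#' @param rates Named rates for `species`, `genus` and `family`.
#' @param seed Integer seed.
#' @param which_traits Trait columns to mask (default all four).
#' @return The trait table with `NA`s introduced; the per-level masking draws
#'   are attached as attribute `"mask"`.
#' @export
mask_traits <- function(traits, rates = c(species = 0.14, genus = 0.06,
                                          family = 0.03),
                        seed = 1, which_traits = .trait_names) {
  if (any(rates < 0) || any(rates > 1))
    abort("masking rates must lie in [0, 1]",
          class = "canopyhazard_config_error")
  withr::with_seed(as.integer(seed), {
    genera <- unique(traits$genus)
    fams <- unique(traits$family)
    mask_log <- list()
    for (tr in which_traits) {
      sp_hit <- runif(nrow(traits)) < rates[["species"]]
      gen_hit <- genera[runif(length(genera)) < rates[["genus"]]]
      fam_hit <- fams[runif(length(fams)) < rates[["family"]]]
      hit <- sp_hit | traits$genus %in% gen_hit | traits$family %in% fam_hit
      traits[[tr]][hit] <- NA_real_
      mask_log[[tr]] <- list(species = sp_hit, genus = gen_hit,
                             family = fam_hit)
    }
    attr(traits, "mask") <- mask_log
    traits
  })
}
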