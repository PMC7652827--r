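# shared simulation experiments used by the acceptance suite

# clean parameter-recovery world: known hazard coefficients, no measurement
# noise, no frailty unless requested
recovery_sim <- function(seed, beta, theta = 0, n_plots_per_region = 4,
                         density = 320, area = c(0.9, 1.1), h0 = 0.02, ...) {
  args <- list(n_plots_per_region = n_plots_per_region, n_species = 150,
               stem_density_ha = density, plot_area_range = area,
               beta = beta, h0 = h0, frailty_var = theta, measure_sd_mm = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  cfg <- do.call(canopyhazard::sim_config, args)
  sim <- canopyhazard::simulate_forest(cfg, seed = seed)
  canopyhazard::assemble_survival_records(
    canopyhazard::filter_plots(sim$data, min_censuses = 3),
    representation = "counting", death_time = "midpoint")
}

# mode-of-death world for the census-interval-length bias correction:
# plots with one interval of length CIL ~ U(1, 6), deaths uniform within it,
# true standing probability 1/2, breakage applied by the package degrader
cil_world <- function(seed, r = 0.04, n_plots = 120, n_dead = 40) {
  withr::with_seed(seed, {
    cil <- runif(n_plots, 1, 6)
    plots <- tibble::tibble(
      plot_id = sprintf("P%03d", seq_len(n_plots)), region = "Western",
      area_ha = 1, lat = seq(-8, -2, length.out = n_plots), lon = -72,
      elev_m = 100)
    trees <- purrr::map_dfr(seq_len(n_plots), function(j) {
      td <- runif(n_dead, 0, cil[j])
      mode <- ifelse(runif(n_dead) < 0.5, "standing", "broken_uprooted")
      tibble::tibble(
        plot_id = plots$plot_id[j],
        tree_id = rep(sprintf("t%03d", seq_len(n_dead)), 2),
        species = "Genus1 sp1", family = "Fam1", is_palm = FALSE,
        census_date = rep(c(2000, 2000 + cil[j]), each = n_dead),
        d_mm = rep(c(150, NA), each = n_dead),
        status = rep(c("alive", "dead"), each = n_dead),
        mode_of_death = c(rep("not_applicable", n_dead), mode),
        death_time = rep(2000 + td, 2), true_mode = rep(mode, 2))
    })
    truth <- list(trees = trees[trees$status == "dead",
                                c("plot_id", "tree_id", "death_time",
                                  "true_mode")])
    ds <- canopyhazard::census_dataset(
      plots, dplyr::select(trees, -"death_time", -"true_mode"))
    canopyhazard::degrade_mode_of_death(ds, truth, r, seed = seed + 1)
  })
}

# expected fraction of standing deaths still recorded standing when found at
# the end of an interval of length c (deaths uniform in the interval)
standing_retention <- function(c, r) (1 - exp(-r * c)) / (r * c)
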