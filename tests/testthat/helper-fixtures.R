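# hand-built census fixture: 1 plot, 2 trees, 3 censuses
tiny_dataset <- function() {
  plots <- tibble::tibble(
    plot_id = "P1", region = "Western", area_ha = 1,
    lat = -4.5, lon = -72.1, elev_m = 120)
  trees <- tibble::tibble(
    plot_id = "P1",
    tree_id = rep(c("t1", "t2"), each = 3),
    species = rep(c("Genus1 sp1", "Genus2 sp2"), each = 3),
    family = rep(c("Fam1", "Fam2"), each = 3),
    is_palm = FALSE,
    census_date = rep(c(2000, 2002.5, 2005), 2),
    d_mm = c(150, 155, 160, 200, 204, NA),
    status = c("alive", "alive", "alive", "alive", "alive", "dead"),
    mode_of_death = c(rep("not_applicable", 5), "standing"))
  canopyhazard::census_dataset(plots, trees)
}

# multi-plot fixture exercising the plot filters
filter_fixture <- function() {
  plots <- tibble::tibble(
    plot_id = c("OK", "GAP", "SMALL", "HIGH", "ONE"),
    region = "Northern", area_ha = c(1, 1, 0.4, 1, 1),
    lat = c(1, 1.5, 2, 2.5, 3), lon = -60 + 0:4, elev_m = c(100, 100, 100, 1200, 100))
  mk <- function(pid, dates) tibble::tibble(
    plot_id = pid, tree_id = paste0(pid, "-t1"), species = "Genus1 sp1",
    family = "Fam1", is_palm = FALSE, census_date = dates,
    d_mm = 150 + seq_along(dates), status = "alive",
    mode_of_death = "not_applicable")
  trees <- dplyr::bind_rows(
    mk("OK", c(2000, 2004, 2008)), mk("GAP", c(2000, 2012)),
    mk("SMALL", c(2000, 2004)), mk("HIGH", c(2000, 2004)),
    mk("ONE", 2000))
  canopyhazard::census_dataset(plots, trees)
}

# direct, exhaustively expanded Cox partial log-likelihood (independent of
# the package's incremental engine)
oracle_partial_loglik <- function(time, status, X, beta, ties = "efron",
                                  offset = 0) {
  eta <- drop(as.matrix(X) %*% beta) + offset
  ll <- 0
  for (t in sort(unique(time[status == 1]))) {
    D <- which(time == t & status == 1)
    R <- which(time >= t)
    d <- length(D)
    ll <- ll + sum(eta[D])
    for (k in seq_len(d) - 1) {
      f <- if (ties == "efron") k / d else 0
      ll <- ll - log(sum(exp(eta[R])) - f * sum(exp(eta[D])))
    }
  }
  ll
}

# random micro survival data with controllable tying
random_micro_records <- function(n, tie_prob = 0.5, p = 2) {
  time <- sample(1:4, n, replace = TRUE) +
    ifelse(runif(n) < tie_prob, 0, runif(n))
  tibble::tibble(
    tree_id = paste0("t", seq_len(n)), plot_id = "P1",
    time_at_risk = time,
    event = rbinom(n, 1, 0.6),
    x1 = rnorm(n), x2 = rnorm(n))[seq_len(n), ]
}

# small fast simulation configuration for tests (overridable defaults)
test_sim_config <- function(...) {
  args <- list(n_plots_per_region = 3, n_species = 80, stem_density_ha = 150,
               plot_area_range = c(0.6, 1))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(canopyhazard::sim_config, args)
}

# records drawn directly from an exponential proportional-hazards model
# (no census structure), for focused engine tests
direct_cox_records <- function(n, beta, h0 = 0.1, cens_time = 8) {
  p <- length(beta)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- names(beta)
  t_death <- rexp(n, h0 * exp(drop(X %*% beta)))
  dplyr::bind_cols(
    tibble::tibble(tree_id = paste0("t", seq_len(n)), plot_id = "P1",
                   time_at_risk = pmin(t_death, cens_time),
                   event = as.integer(t_death <= cens_time)),
    tibble::as_tibble(X))
}
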