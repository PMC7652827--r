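#' Annualised mortality rate from one census interval
#'
#' Computes `m = (1 - (N_t1 / N_t0)^(1/T)) * 100`, the per-capita annual
#' mortality rate in % yr^-1 implied by `N_t0` individuals alive at the
#' start of an interval of length `T` years of which `N_t1` survive.
#'
#' @param n_t0 Individuals alive at the start of the interval (>= 1).
#' @param n_t1 Individuals surviving to the end (0 <= n_t1 <= n_t0).
#' @param t_yr Interval length in years (> 0). All arguments vectorised.
#' @return Mortality rate(s) in % yr^-1.
#' @export
interval_mortality_rate <- function(n_t0, n_t1, t_yr) {
  if (any(n_t0 < 1)) abort("mortality rate undefined for N_t0 = 0",
                           class = "canopyhazard_validation_error")
  if (any(n_t1 < 0) || any(n_t1 > n_t0))
    abort("need 0 <= N_t1 <= N_t0", class = "canopyhazard_validation_error")
  if (any(t_yr <= 0)) abort("interval length must be positive",
                            class = "canopyhazard_validation_error")
  (1 - (n_t1 / n_t0)^(1 / t_yr)) * 100
}

# cohort survival counts for each consecutive census pair of each plot.
# Trees enter N_t0 from their first alive census; trees that vanish or are
# flagged lost without a death record are censored out of both counts.
interval_counts <- function(ds, mode = NULL) {
  obs <- ds$trees |> select("plot_id", "tree_id", "census_index", "status",
                            "mode_of_death")
  pairs <- ds$censuses |>
    group_by(.data$plot_id) |>
    mutate(t1 = lead(.data$date), k1 = lead(.data$census_index)) |>
    ungroup() |>
    filter(!is.na(.data$t1)) |>
    transmute(.data$plot_id, k0 = .data$census_index, .data$k1,
              t0 = .data$date, .data$t1, t_yr = .data$t1 - .data$date)
  start <- obs |> filter(.data$status == "alive") |>
    select("plot_id", "tree_id", k0 = "census_index")
  end <- obs |> select("plot_id", "tree_id", k1 = "census_index",
                       end_status = "status", "mode_of_death")
  joined <- start |>
    inner_join(pairs, by = c("plot_id", "k0")) |>
    left_join(end, by = c("plot_id", "tree_id", "k1")) |>
    filter(!is.na(.data$end_status), .data$end_status %in% c("alive", "dead"))
  joined |>
    group_by(.data$plot_id, .data$k0, .data$k1, .data$t0, .data$t1,
             .data$t_yr) |>
    summarise(
      n_t0 = n(),
      n_dead = sum(.data$end_status == "dead"),
      n_dead_standing = sum(.data$end_status == "dead" &
                              .data$mode_of_death == "standing"),
      n_dead_broken = sum(.data$end_status == "dead" &
                            .data$mode_of_death == "broken_uprooted"),
      .groups = "drop")
}

#' Per-interval mortality rates for every plot
#'
#' @param ds A [census_dataset()].
#' @return A tibble with one row per plot per census interval: counts
#'   (`n_t0`, `n_dead`), interval length `t_yr` and the annualised rate `m`
#'   (% yr^-1).
#' @export
interval_rates <- function(ds) {
  interval_counts(ds) |>
    mutate(n_t1 = .data$n_t0 - .data$n_dead,
           m = interval_mortality_rate(.data$n_t0, .data$n_t1, .data$t_yr)) |>
    select("plot_id", "k0", "k1", "t0", "t1", "t_yr", "n_t0", "n_t1",
           "n_dead", "m")
}

#' Plot-level mortality rates
#'
#' Aggregates per-interval rates to one rate per plot as the mean across
#' intervals weighted by the census-interval length.
#'
#' @param intervals Output of [interval_rates()] (or any tibble with
#'   `plot_id`, `m` and `t_yr`), or a [census_dataset()].
#' @param plots Optional plot table used to attach `region` and `area_ha`;
#'   filled automatically when `intervals` is a `census_dataset`.
#' @return A tibble with one row per plot: `m_plot` (% yr^-1), total
#'   monitoring `span_yr`, `n_intervals`, plus `region`/`area_ha` if
#'   available.
#' @export
plot_mortality_rate <- function(intervals, plots = NULL) {
  if (inherits(intervals, "census_dataset")) {
    plots <- intervals$plots
    intervals <- interval_rates(intervals)
  }
  if (!nrow(intervals)) abort("no census intervals to aggregate",
                              class = "canopyhazard_validation_error")
  out <- intervals |>
    group_by(.data$plot_id) |>
    summarise(m_plot = sum(.data$m * .data$t_yr) / sum(.data$t_yr),
              span_yr = sum(.data$t_yr), n_intervals = n(),
              .groups = "drop")
  if (!is.null(plots))
    out <- out |> left_join(plots |> select("plot_id", "region", "area_ha"),
                            by = "plot_id")
  out
}

#' Mode-specific mortality rates
#'
#' Applies the interval mortality-rate formula per mode of death: for, say,
#' standing death, the survivors `N_t1` are all trees that did not die
#' standing (trees dying broken/uprooted count as survivors of standing
#' death). Only plots passing [mode_assessment_eligibility()] are used;
#' ineligible plots are reported in the `"exclusions"` attribute.
#'
#' @param ds A [census_dataset()].
#' @return A tibble with one row per eligible plot per mode (`standing`,
#'   `broken_uprooted`): the interval-length-weighted plot rate `m_plot`
#'   (% yr^-1) plus `region`/`area_ha`.
#' @export
mode_specific_rates <- function(ds) {
  elig <- mode_assessment_eligibility(ds)
  keep <- elig$plot_id[elig$eligible]
  counts <- interval_counts(ds) |> filter(.data$plot_id %in% keep)
  long <- bind_rows(
    counts |> mutate(mode = "standing", n_mode = .data$n_dead_standing),
    counts |> mutate(mode = "broken_uprooted", n_mode = .data$n_dead_broken)) |>
    mutate(m = interval_mortality_rate(.data$n_t0, .data$n_t0 - .data$n_mode,
                                       .data$t_yr))
  out <- long |>
    group_by(.data$plot_id, .data$mode) |>
    summarise(m_plot = sum(.data$m * .data$t_yr) / sum(.data$t_yr),
              span_yr = sum(.data$t_yr), .groups = "drop") |>
    left_join(ds$plots |> select("plot_id", "region", "area_ha"),
              by = "plot_id")
  attr(out, "exclusions") <- elig |> filter(!.data$eligible) |>
    transmute(.data$plot_id, rule = .data$reason)
  out
}

#' Area-weighted bootstrap mean and percentile confidence interval
#'
#' Resamples plots with replacement `B` times; each replicate is the
#' area-weighted mean of the resampled plot values, and the summary is the
#' mean of the replicates with the 2.5th/97.5th percentile interval.
#'
#' @param values Plot-level values (e.g. mortality rates, % yr^-1).
#' @param weights Plot weights (areas, ha); all positive.
#' @param B Number of bootstrap replicates (default 10000).
#' @param seed Integer seed; the summary is deterministic given the seed.
#' @param conf Confidence level (default 0.95).
#' @return A one-row tibble: `mean`, `ci_lo`, `ci_hi`, `n_plots`, `B`,
#'   `seed`.
#' @export
bootstrap_weighted_mean <- function(values, weights = rep(1, length(values)),
                                    B = 10000, seed = 1, conf = 0.95) {
  n <- length(values)
  if (n < 1 || length(weights) != n)
    abort("values and weights must have equal positive length",
          class = "canopyhazard_validation_error")
  if (any(weights <= 0)) abort("weights must be positive",
                               class = "canopyhazard_validation_error")
  if (B < 1) abort("B must be at least 1",
                   class = "canopyhazard_validation_error")
  reps <- withr::with_seed(as.integer(seed), {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
    vw <- matrix(values[idx] * weights[idx], nrow = B)
    wm <- matrix(weights[idx], nrow = B)
    rowSums(vw) / rowSums(wm)
  })
  a <- (1 - conf) / 2
  ci <- unname(quantile(reps, c(a, 1 - a), type = 7))
  tibble(mean = mean(reps), ci_lo = ci[1], ci_hi = ci[2],
         n_plots = n, B = as.integer(B), seed = as.integer(seed))
}

#' Basin- and region-level bootstrapped rate summaries
#'
#' @param plot_rates Output of [plot_mortality_rate()] (needs `m_plot`,
#'   `region`, `area_ha`).
#' @param B,seed,conf Passed to [bootstrap_weighted_mean()].
#' @return A tibble with one row per region plus a `"Basin"` row: `scope`,
#'   `mean`, `ci_lo`, `ci_hi`, `n_plots`.
#' @export
regional_rate_summary <- function(plot_rates, B = 10000, seed = 1,
                                  conf = 0.95) {
  basin <- bootstrap_weighted_mean(plot_rates$m_plot, plot_rates$area_ha,
                                   B = B, seed = seed, conf = conf) |>
    mutate(scope = "Basin")
  by_region <- plot_rates |>
    group_by(scope = .data$region) |>
    group_modify(~ bootstrap_weighted_mean(
      .x$m_plot, .x$area_ha, B = B,
      seed = derive_seed(seed, match(.y$scope, .regions)), conf = conf)) |>
    ungroup()
  bind_rows(by_region, basin) |>
    select("scope", "mean", "ci_lo", "ci_hi", "n_plots", "B")
}

#' Compare regional means with Tukey's honest significant differences
#'
#' Runs a one-way analysis of variance of the plot-level values on region and
#' reports every pairwise mean difference with a family-wise adjusted p-value
#' from the studentized-range distribution, plus a compact letter display
#' (regions sharing a letter are not significantly different).
#'
#' @param plot_rates A tibble with `region` and a value column.
#' @param value Name of the value column (default `"m_plot"`).
#' @param alpha Significance level for the letter display (default 0.05).
#' @return An object of class `region_comparison` with elements `pairs`
#'   (tibble: `region_a`, `region_b`, `diff`, `ci_lo`, `ci_hi`, `p_adj`) and
#'   `letters` (tibble: `region`, `mean`, `letters`).
#' @export
compare_regions <- function(plot_rates, value = "m_plot", alpha = 0.05) {
  df <- tibble(region = plot_rates$region, y = plot_rates[[value]]) |>
    filter(!is.na(.data$y))
  sizes <- df |> count(.data$region)
  small <- sizes$region[sizes$n < 2]
  if (length(small)) {
    warn(paste0("region(s) with fewer than 2 plots excluded: ",
                paste(small, collapse = ", ")))
    df <- df |> filter(!.data$region %in% small)
  }
  if (n_distinct(df$region) < 2)
    abort("need at least two regions with two or more plots",
          class = "canopyhazard_validation_error")
  df$region <- factor(df$region)
  fit <- aov(y ~ region, data = df)
  tk <- TukeyHSD(fit)$region
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  pairs <- tibble(
    region_a = vapply(nm, `[[`, "", 1L),
    region_b = vapply(nm, `[[`, "", 2L),
    diff = tk[, "diff"], ci_lo = tk[, "lwr"], ci_hi = tk[, "upr"],
    p_adj = tk[, "p adj"])
  letters_tbl <- compact_letters(pairs, df, alpha)
  structure(list(pairs = pairs, letters = letters_tbl, fit = fit),
            class = "region_comparison")
}

# compact letter display via maximal cliques of the "not significantly
# different" graph (group counts are small, so enumeration is exact)
compact_letters <- function(pairs, df, alpha) {
  groups <- levels(df$region)
  k <- length(groups)
  ns_mat <- matrix(TRUE, k, k, dimnames = list(groups, groups))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$region_a[i]; b <- pairs$region_b[i]
    ns <- pairs$p_adj[i] >= alpha
    ns_mat[a, b] <- ns_mat[b, a] <- ns
  }
  subsets <- purrr::map(seq_len(2^k - 1), function(m) {
    groups[bitwAnd(m, 2^(seq_len(k) - 1)) > 0]
  })
  is_clique <- vapply(subsets, function(s) {
    all(ns_mat[s, s, drop = FALSE]) }, TRUE)
  cliques <- subsets[is_clique]
  maximal <- cliques[!vapply(cliques, function(s) {
    any(vapply(cliques, function(t) length(t) > length(s) && all(s %in% t),
               TRUE)) }, TRUE)]
  maximal <- maximal[order(-vapply(maximal, length, 1L),
                           vapply(maximal, `[[`, "", 1L))]
  lab <- letters[seq_along(maximal)]
  means <- df |> group_by(region = as.character(.data$region)) |>
    summarise(mean = mean(.data$y), .groups = "drop")
  means$letters <- unname(vapply(means$region, function(g) {
    paste0(lab[vapply(maximal, function(s) g %in% s, TRUE)], collapse = "")
  }, ""))
  means
}

#' @export
print.region_comparison <- function(x, ...) {
  cat("Tukey HSD regional comparison\n")
  print(x$letters)
  print(x$pairs, n = Inf)
  invisible(x)
}
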