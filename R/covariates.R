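#' Relative diameter growth rate
#'
#' `100 * ((D_t1 - D_t0) / T) / D_t0`, in % yr^-1: the annual diameter
#' increment between the antepenultimate and penultimate censuses relative to
#' the starting diameter.
#'
#' @param d_t0,d_t1 Diameters at the two censuses, millimetres (`d_t0 > 0`).
#' @param t_yr Time between the censuses, years (> 0). Vectorised.
#' @return Relative growth in % yr^-1.
#' @export
relative_growth <- function(d_t0, d_t1, t_yr) {
  if (any(d_t0 <= 0, na.rm = TRUE))
    abort("starting diameter must be positive",
          class = "canopyhazard_validation_error")
  if (any(t_yr <= 0, na.rm = TRUE))
    abort("time span must be positive",
          class = "canopyhazard_validation_error")
  100 * ((d_t1 - d_t0) / t_yr) / d_t0
}

#' Linear and quadratic size terms
#'
#' Tree size enters the hazard model as a polynomial `b1*D + b2*D^2` to allow
#' the U-shaped size-mortality relationship; the quadratic term can be
#' dropped for the linear-size model variants.
#'
#' @param d_m Diameter in metres.
#' @param quadratic Include the squared term (default `TRUE`).
#' @return A tibble with column `D` and, when requested, `D2`.
#' @export
size_terms <- function(d_m, quadratic = TRUE) {
  if (any(d_m <= 0, na.rm = TRUE))
    abort("diameter must be positive", class = "canopyhazard_validation_error")
  if (quadratic) tibble(D = d_m, D2 = d_m^2) else tibble(D = d_m)
}

#' Attach species traits to trees with hierarchical imputation
#'
#' Resolves each trait for each tree through the cascade: the species' own
#' value; failing that the mean over species of the same genus; failing that
#' the mean over species of the same family; failing that the
#' individual-weighted mean over all trees of the same plot whose trait could
#' be resolved at species, genus or family level. The level used is recorded
#' per trait.
#'
#' @param trees A tibble of distinct trees with `plot_id`, `species`,
#'   `genus`, `family`.
#' @param traits A species-trait table (see [read_trait_table()]).
#' @param trait_names Traits to resolve (default all four).
#' @return `trees` with one value column per trait and matching
#'   `<trait>_level` columns (`"species"`, `"genus"`, `"family"` or
#'   `"plot"`).
#' @export
impute_traits <- function(trees, traits, trait_names = .trait_names) {
  if (is.null(traits) || !nrow(traits))
    abort("no trait table available", class = "canopyhazard_validation_error")
  out <- trees
  for (tr in trait_names) {
    sp_val <- traits[[tr]][match(out$species, traits$species)]
    gen_tbl <- traits |> group_by(.data$genus) |>
      summarise(v = mean(.data[[tr]], na.rm = TRUE), .groups = "drop")
    gen_val <- gen_tbl$v[match(out$genus, gen_tbl$genus)]
    gen_val[is.nan(gen_val)] <- NA_real_
    fam_tbl <- traits |> group_by(.data$family) |>
      summarise(v = mean(.data[[tr]], na.rm = TRUE), .groups = "drop")
    fam_val <- fam_tbl$v[match(out$family, fam_tbl$family)]
    fam_val[is.nan(fam_val)] <- NA_real_
    val <- sp_val
    level <- ifelse(!is.na(sp_val), "species", NA_character_)
    use_gen <- is.na(val) & !is.na(gen_val)
    val[use_gen] <- gen_val[use_gen]; level[use_gen] <- "genus"
    use_fam <- is.na(val) & !is.na(fam_val)
    val[use_fam] <- fam_val[use_fam]; level[use_fam] <- "family"
    # plot fallback: individual-weighted mean of resolved co-occurring trees
    if (any(is.na(val))) {
      plot_tbl <- tibble(plot_id = out$plot_id, v = val) |>
        group_by(.data$plot_id) |>
        summarise(v = mean(.data$v, na.rm = TRUE), .groups = "drop")
      plot_val <- plot_tbl$v[match(out$plot_id, plot_tbl$plot_id)]
      plot_val[is.nan(plot_val)] <- NA_real_
      use_plot <- is.na(val) & !is.na(plot_val)
      val[use_plot] <- plot_val[use_plot]; level[use_plot] <- "plot"
      if (any(is.na(val)))
        abort(sprintf("trait '%s' unresolvable for some trees (empty trait table and plot)",
                      tr),
              class = "canopyhazard_validation_error")
    }
    out[[tr]] <- val
    out[[paste0(tr, "_level")]] <- level
  }
  out
}

#' Build analysis-ready survival records
#'
#' Turns tree observation histories into one survival record per tree for
#' the proportional-hazards analysis. A tree contributes a record when its
#' plot has at least `min_censuses` censuses and the tree has at least two
#' alive observations before its exit (death record, or final census when
#' censored): the diameter `D` is taken from the penultimate alive
#' observation (converted to metres), relative growth from the
#' antepenultimate-to-penultimate interval, species traits are attached via
#' [impute_traits()], palms and trees with relative growth below
#' `growth_floor` (physiologically impossible shrinkage, i.e. measurement
#' error) are excluded. Time at risk runs from the tree's first alive census
#' to the death census (event) or last alive census (censored); with
#' `risk_from = "growth_interval"` it runs from the penultimate alive census
#' instead, and with `death_time = "midpoint"` deaths are placed at the
#' middle of the last-alive-to-found-dead interval.
#'
#' @param ds A [census_dataset()] carrying a trait table.
#' @param growth_floor Exclusion threshold for relative growth (% yr^-1,
#'   default -5).
#' @param exclude_palms Drop palms (family Arecaceae), default `TRUE`.
#' @param min_censuses Minimum plot censuses (default 3).
#' @param death_time `"census"` (default) or `"midpoint"`.
#' @param risk_from `"first_census"` (default) or `"growth_interval"`.
#' @param representation `"single"` (default; one record per tree with fixed
#'   covariates, the convention of the headline analysis) or `"counting"`
#'   (one row per tree per census interval with time-varying covariates:
#'   each row spans `(start_time, stop_time]` in calendar years, the
#'   diameter comes from the interval-start census and relative growth from
#'   the census interval before it, so trees enter risk at their second
#'   alive census). The counting form avoids the differential covariate
#'   timing of the single-record form and is used for sensitivity checks
#'   and parameter-recovery experiments.
#' @return A tibble of survival records: `tree_id`, `plot_id`, `region`,
#'   `time_at_risk` (yr), `event` (0/1), `mode` (recorded mode for deaths),
#'   `D` (m), `D2`, `rel_growth` (% yr^-1), the four species traits and
#'   their imputation levels. The exclusion tally is attached as attribute
#'   `"exclusions"`.
#' @export
assemble_survival_records <- function(ds, growth_floor = -5,
                                      exclude_palms = TRUE,
                                      min_censuses = 3,
                                      death_time = c("census", "midpoint"),
                                      risk_from = c("first_census",
                                                    "growth_interval"),
                                      representation = c("single",
                                                         "counting")) {
  death_time <- match.arg(death_time)
  risk_from <- match.arg(risk_from)
  representation <- match.arg(representation)
  excl <- list()
  n_census <- ds$censuses |> count(.data$plot_id, name = "n_census")
  bad_plots <- n_census$plot_id[n_census$n_census < min_censuses]
  excl$few_censuses <- tibble(
    plot_id = bad_plots, rule = sprintf("fewer than %d censuses", min_censuses))
  obs <- ds$trees |> filter(!.data$plot_id %in% bad_plots)

  if (exclude_palms) {
    palms <- obs |> filter(.data$is_palm) |>
      distinct(.data$plot_id, .data$tree_id)
    excl$palms <- palms |> mutate(rule = "palm")
    obs <- obs |> filter(!.data$is_palm)
  }

  if (representation == "counting") {
    out <- build_counting_records(obs, ds, growth_floor, death_time)
    attr(out, "exclusions") <- bind_rows(bind_rows(excl),
                                         attr(out, "exclusions"))
    return(out)
  }

  # per-tree extraction, vectorised over the sorted alive observations:
  # for each tree we need its first alive date and the last / second-last /
  # third-last alive observations
  obs2 <- obs |> filter(.data$status %in% c("alive", "dead"))
  alive <- obs2 |> filter(.data$status == "alive") |>
    arrange(.data$plot_id, .data$tree_id, .data$census_date)
  akey <- paste(alive$plot_id, alive$tree_id, sep = "\r")
  runs <- rle(akey)$lengths
  last_i <- cumsum(runs)
  first_i <- last_i - runs + 1L
  prev_i <- ifelse(runs >= 2, last_i - 1L, NA_integer_)
  prev2_i <- ifelse(runs >= 3, last_i - 2L, NA_integer_)
  at <- function(i, col) ifelse(is.na(i), NA_real_, col[ifelse(is.na(i), 1L, i)])
  per_alive <- tibble(
    plot_id = alive$plot_id[last_i], tree_id = alive$tree_id[last_i],
    species = alive$species[last_i], genus = alive$genus[last_i],
    family = alive$family[last_i],
    n_alive = runs,
    first_date = alive$census_date[first_i],
    last_alive = alive$census_date[last_i],
    d_last = alive$d_mm[last_i], t_last = alive$census_date[last_i],
    d_prev = at(prev_i, alive$d_mm), t_prev = at(prev_i, alive$census_date),
    d_prev2 = at(prev2_i, alive$d_mm),
    t_prev2 = at(prev2_i, alive$census_date))
  deaths <- obs2 |> filter(.data$status == "dead") |>
    select("plot_id", "tree_id", dspecies = "species", dgenus = "genus",
           dfamily = "family", death_date = "census_date",
           mode = "mode_of_death")
  per_tree <- per_alive |>
    full_join(deaths, by = c("plot_id", "tree_id")) |>
    mutate(dead = !is.na(.data$death_date),
           n_alive = coalesce(.data$n_alive, 0L),
           species = coalesce(.data$species, .data$dspecies),
           genus = coalesce(.data$genus, .data$dgenus),
           family = coalesce(.data$family, .data$dfamily)) |>
    select(-"dspecies", -"dgenus", -"dfamily")
  # dead trees: growth pair = (second-last, last) alive observations; exit at
  # the death census. Censored trees: the last alive census is the exit, so
  # the growth pair shifts back one observation.
  per_tree <- per_tree |>
    mutate(
      d_pen2 = if_else(.data$dead, .data$d_last, .data$d_prev),
      d_ante2 = if_else(.data$dead, .data$d_prev, .data$d_prev2),
      t_pen2 = if_else(.data$dead, .data$t_last, .data$t_prev),
      t_ante2 = if_else(.data$dead, .data$t_prev, .data$t_prev2))

  too_few <- is.na(per_tree$d_ante2) | is.na(per_tree$d_pen2) |
    is.na(per_tree$t_ante2)
  excl$too_few <- per_tree |> filter(too_few) |>
    transmute(.data$plot_id, .data$tree_id,
              rule = "fewer than 2 growth observations before exit")
  rec <- per_tree |> filter(!too_few)

  rec <- rec |>
    mutate(rel_growth = relative_growth(.data$d_ante2, .data$d_pen2,
                                        .data$t_pen2 - .data$t_ante2))
  shrunk <- rec$rel_growth < growth_floor
  excl$shrinkage <- rec |> filter(shrunk) |>
    transmute(.data$plot_id, .data$tree_id,
              rule = sprintf("relative growth below %g%% yr^-1", growth_floor))
  rec <- rec |> filter(!shrunk)

  exit <- ifelse(rec$dead,
                 if (death_time == "census") rec$death_date
                 else (rec$last_alive + rec$death_date) / 2,
                 rec$last_alive)
  entry <- if (risk_from == "first_census") rec$first_date else rec$t_pen2
  rec$time_at_risk <- exit - entry
  zero_time <- rec$time_at_risk <= 0
  excl$zero_time <- rec |> filter(zero_time) |>
    transmute(.data$plot_id, .data$tree_id, rule = "non-positive time at risk")
  rec <- rec |> filter(!zero_time)

  rec <- rec |>
    mutate(event = as.integer(.data$dead),
           mode = if_else(.data$dead, .data$mode, NA_character_),
           D = mm_to_m(.data$d_pen2), D2 = .data$D^2)
  rec <- impute_traits(rec, ds$traits)
  rec |>
    left_join(ds$plots |> select("plot_id", "region"), by = "plot_id") |>
    select("tree_id", "plot_id", "region", "species", "time_at_risk",
           "event", "mode", "D", "D2", "rel_growth",
           tidyr::all_of(.trait_names),
           tidyr::ends_with("_level")) -> out
  attr(out, "exclusions") <- bind_rows(excl)
  out
}

# one row per tree per census interval: (start, stop] in calendar years,
# diameter from the interval-start census, relative growth from the interval
# before it
build_counting_records <- function(obs, ds, growth_floor, death_time) {
  o <- obs |> filter(.data$status %in% c("alive", "dead")) |>
    arrange(.data$plot_id, .data$tree_id, .data$census_date)
  key <- paste(o$plot_id, o$tree_id, sep = "\r")
  n <- nrow(o)
  same_nxt <- c(key[-1] == key[-n], FALSE)
  same_prv <- c(FALSE, key[-1] == key[-n])
  i <- which(o$status == "alive" & same_nxt & same_prv)
  rows <- tibble(
    tree_id = o$tree_id[i], plot_id = o$plot_id[i],
    species = o$species[i], genus = o$genus[i], family = o$family[i],
    start_time = o$census_date[i],
    stop_time = if (death_time == "midpoint")
      ifelse(o$status[i + 1] == "dead",
             (o$census_date[i] + o$census_date[i + 1]) / 2,
             o$census_date[i + 1])
    else o$census_date[i + 1],
    event = as.integer(o$status[i + 1] == "dead"),
    mode = if_else(o$status[i + 1] == "dead", o$mode_of_death[i + 1],
                   NA_character_),
    D = mm_to_m(o$d_mm[i]),
    d_prev = o$d_mm[i - 1], t_prev = o$census_date[i - 1])
  excl <- list()
  miss <- is.na(rows$D) | is.na(rows$d_prev)
  excl$missing <- rows |> filter(miss) |>
    transmute(.data$plot_id, .data$tree_id, rule = "missing diameter")
  rows <- rows |> filter(!miss) |>
    mutate(rel_growth = relative_growth(.data$d_prev, m_to_mm(.data$D),
                                        .data$start_time - .data$t_prev),
           D2 = .data$D^2)
  shrunk <- rows$rel_growth < growth_floor
  excl$shrinkage <- rows |> filter(shrunk) |>
    transmute(.data$plot_id, .data$tree_id,
              rule = sprintf("relative growth below %g%% yr^-1", growth_floor))
  rows <- rows |> filter(!shrunk)
  rows <- impute_traits(rows, ds$traits)
  out <- rows |>
    left_join(ds$plots |> select("plot_id", "region"), by = "plot_id") |>
    select("tree_id", "plot_id", "region", "species", "start_time",
           "stop_time", "event", "mode", "D", "D2", "rel_growth",
           tidyr::all_of(.trait_names), tidyr::ends_with("_level"))
  attr(out, "exclusions") <- bind_rows(excl)
  out
}
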