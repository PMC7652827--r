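#' Apply plot-level eligibility filters
#'
#' Removes plots that do not meet the monitoring-quality rules used for the
#' demographic analyses: lowland elevation, no census gap longer than
#' `max_census_gap_yr`, area at least `min_area_ha`, and at least
#' `min_censuses` censuses (use 3 for the survival-analysis subset, 2 for
#' rate estimation). Trees of excluded plots are dropped with their plot.
#'
#' @param ds A [census_dataset()].
#' @param max_census_gap_yr Maximum allowed interval between consecutive
#'   censuses, years (default 10).
#' @param min_area_ha Minimum plot area, hectares (default 0.5). Run
#'   [merge_nearby_plots()] first to rescue clusters of small plots.
#' @param max_elevation_m Maximum elevation, metres a.s.l. (default 1000).
#' @param min_censuses Minimum number of censuses (default 2).
#' @return The filtered `census_dataset`. The exclusion report (a tibble with
#'   `plot_id` and `rule`) is attached as attribute `"exclusions"` and can be
#'   retrieved with [exclusion_report()].
#' @export
filter_plots <- function(ds, max_census_gap_yr = 10, min_area_ha = 0.5,
                         max_elevation_m = 1000, min_censuses = 2) {
  sched <- ds$censuses |>
    group_by(.data$plot_id) |>
    summarise(n_census = n(),
              max_gap = if (n() > 1) max(diff(.data$date)) else NA_real_,
              .groups = "drop")
  info <- ds$plots |> left_join(sched, by = "plot_id")
  info$n_census[is.na(info$n_census)] <- 0L
  rules <- list(
    `elevation > max` = info$elev_m > max_elevation_m,
    `census gap > max` = !is.na(info$max_gap) & info$max_gap > max_census_gap_yr,
    `area < min` = info$area_ha < min_area_ha,
    `too few censuses` = info$n_census < min_censuses)
  excl <- purrr::map2_dfr(rules, names(rules), function(hit, rule) {
    tibble(plot_id = info$plot_id[which(hit)], rule = rule)
  })
  keep <- setdiff(ds$plots$plot_id, excl$plot_id)
  if (!length(keep)) warn("all plots excluded by the filters")
  out <- census_dataset(
    ds$plots |> filter(.data$plot_id %in% keep),
    ds$trees |> filter(.data$plot_id %in% keep) |>
      select(-"census_index"),
    ds$traits, validate = FALSE)
  attr(out, "exclusions") <- excl |> arrange(.data$plot_id)
  out
}

#' Retrieve the exclusion report left by a filtering step
#'
#' @param x An object returned by [filter_plots()], [merge_nearby_plots()] or
#'   [assemble_survival_records()].
#' @return A tibble describing what was excluded and why (empty when nothing
#'   was).
#' @export
exclusion_report <- function(x) {
  attr(x, "exclusions") %||% tibble(plot_id = character(), rule = character())
}

haversine_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6371.0088 * asin(pmin(1, sqrt(a)))
}

#' Merge plots closer than a distance threshold
#'
#' Small plots laid out close together (often subplots of one transect) are
#' merged into a single analysis unit: plots whose great-circle (haversine)
#' distance is below `max_distance_km` form a connected component and are
#' merged when their census schedules align index-by-index within
#' `schedule_tol_yr` and have the same number of censuses. The merged plot
#' has the summed area, the union of trees, area-weighted mean coordinates
#' and elevation, and the index-wise mean census dates. Plots whose schedules
#' are incompatible are left unmerged and reported. Members of a component
#' must share a region label; differing regions abort.
#'
#' @param ds A [census_dataset()].
#' @param max_distance_km Distance threshold, kilometres (default 1).
#' @param schedule_tol_yr Maximum index-wise census-date difference for two
#'   plots to be considered on the same schedule (default 0.5 years).
#' @return A `census_dataset` with merged plots; unmergeable candidate pairs
#'   are reported in the `"exclusions"` attribute with rule
#'   `"incompatible census schedule"`.
#' @export
merge_nearby_plots <- function(ds, max_distance_km = 1.0,
                               schedule_tol_yr = 0.5) {
  p <- ds$plots
  n <- nrow(p)
  if (n < 2) return(ds)
  sched <- split(ds$censuses$date, ds$censuses$plot_id)
  compatible <- function(a, b) {
    da <- sched[[a]]; db <- sched[[b]]
    length(da) == length(db) && all(abs(da - db) <= schedule_tol_yr)
  }
  # adjacency among all plots below the distance threshold
  adj <- matrix(FALSE, n, n)
  unmerged <- tibble(plot_id = character(), rule = character())
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- haversine_km(p$lat[i], p$lon[i], p$lat[j], p$lon[j])
    if (d < max_distance_km) {
      if (compatible(p$plot_id[i], p$plot_id[j])) {
        adj[i, j] <- adj[j, i] <- TRUE
      } else {
        unmerged <- bind_rows(unmerged, tibble(
          plot_id = c(p$plot_id[i], p$plot_id[j]),
          rule = "incompatible census schedule"))
      }
    }
  }
  comp <- rep(0L, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      stack <- i
      while (length(stack)) {
        k <- stack[[1]]; stack <- stack[-1]
        if (comp[k] == 0L) {
          comp[k] <- cid
          stack <- c(stack, which(adj[k, ] & comp == 0L))
        }
      }
    }
  }
  new_plots <- list(); map <- character(0)
  new_sched <- list()
  for (g in unique(comp)) {
    idx <- which(comp == g)
    if (length(idx) == 1L) {
      new_plots[[length(new_plots) + 1]] <- p[idx, ]
      map[p$plot_id[idx]] <- p$plot_id[idx]
      next
    }
    if (n_distinct(p$region[idx]) > 1)
      abort(paste0("plots to merge have differing region labels: ",
                   paste(p$plot_id[idx], collapse = ", ")),
            class = "canopyhazard_validation_error")
    id <- paste(sort(p$plot_id[idx]), collapse = "+")
    w <- p$area_ha[idx] / sum(p$area_ha[idx])
    new_plots[[length(new_plots) + 1]] <- tibble(
      plot_id = id, region = p$region[idx[1]],
      area_ha = sum(p$area_ha[idx]),
      lat = sum(w * p$lat[idx]), lon = sum(w * p$lon[idx]),
      elev_m = sum(w * p$elev_m[idx]))
    map[p$plot_id[idx]] <- id
    dates <- do.call(rbind, sched[p$plot_id[idx]])
    new_sched[[id]] <- colMeans(dates)
  }
  trees <- ds$trees |> select(-"census_index")
  # snap member observation dates onto the merged schedule so the merged plot
  # has one census-date sequence
  for (id in names(new_sched)) {
    members <- names(map)[map == id]
    for (m in members) {
      rows <- trees$plot_id == m
      idx <- vapply(trees$census_date[rows],
                    function(d) which.min(abs(sched[[m]] - d)), 1L)
      trees$census_date[rows] <- new_sched[[id]][idx]
    }
  }
  trees$plot_id <- unname(map[trees$plot_id])
  out <- census_dataset(bind_rows(new_plots), trees, ds$traits,
                        validate = FALSE)
  attr(out, "exclusions") <- distinct(unmerged)
  out
}

#' Mode-of-death assessment eligibility per plot
#'
#' A plot enters mode-of-death analyses only when at least 50% of its dead
#' trees, and at least 5 trees, had their mode of death assessed.
#'
#' @param ds A [census_dataset()].
#' @param min_fraction Minimum assessed fraction of dead trees (default 0.5).
#' @param min_assessed Minimum number of assessed dead trees (default 5).
#' @return A tibble with one row per plot: `plot_id`, `n_dead`, `n_assessed`,
#'   `eligible`, `reason` (`NA` when eligible).
#' @export
mode_assessment_eligibility <- function(ds, min_fraction = 0.5,
                                        min_assessed = 5) {
  ds$trees |>
    group_by(.data$plot_id) |>
    summarise(
      n_dead = sum(.data$status == "dead"),
      n_assessed = sum(.data$status == "dead" &
                         .data$mode_of_death %in% c("standing", "broken_uprooted")),
      .groups = "drop") |>
    mutate(
      eligible = .data$n_dead > 0 &
        .data$n_assessed >= min_assessed &
        .data$n_assessed / pmax(.data$n_dead, 1) >= min_fraction,
      reason = case_when(
        .data$n_dead == 0 ~ "no deaths",
        .data$n_assessed < min_assessed ~ "fewer than 5 assessed",
        .data$n_assessed / .data$n_dead < min_fraction ~
          "less than 50% assessed",
        TRUE ~ NA_character_)) |>
    right_join(ds$plots["plot_id"], by = "plot_id") |>
    mutate(n_dead = coalesce(.data$n_dead, 0L),
           n_assessed = coalesce(.data$n_assessed, 0L),
           eligible = coalesce(.data$eligible, FALSE),
           reason = if_else(.data$n_dead == 0, "no deaths", .data$reason))
}
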