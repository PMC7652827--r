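#' Construct a census dataset
#'
#' Bundles the three tables that describe a set of monitored forest plots into
#' a single validated object: a plot table, a long observation table (one row
#' per tree per census) and an optional species-trait table.
#'
#' @param plots A data frame with columns `plot_id`, `region`, `area_ha`,
#'   `lat`, `lon`, `elev_m`. Regions must be one of `"Northern"`,
#'   `"EastCentral"`, `"Western"`, `"Southern"`.
#' @param trees A data frame with one row per tree per census and columns
#'   `plot_id`, `tree_id`, `species`, `family`, `is_palm`, `census_date`
#'   (decimal years), `d_mm` (stem diameter, millimetres, `NA` when not
#'   measured), `status` (`"alive"`, `"dead"`, `"not_yet_recruited"`,
#'   `"lost"`) and `mode_of_death` (`"standing"`, `"broken_uprooted"`,
#'   `"unassessed"`, `"not_applicable"`). A `genus` column is optional; when
#'   absent it is parsed as the first whitespace-separated token of `species`.
#' @param traits Optional species-trait table, see [read_trait_table()].
#' @param validate Run [validate_census_dataset()] on the result.
#'
#' @return An object of class `census_dataset`: a list with tibbles `plots`,
#'   `trees`, `traits` and a derived `censuses` table (`plot_id`,
#'   `census_index`, `date`) giving each plot's census schedule.
#' @export
census_dataset <- function(plots, trees, traits = NULL, validate = TRUE) {
  plots <- as_tibble(plots)
  trees <- as_tibble(trees)
  if (!"genus" %in% names(trees)) {
    trees$genus <- vapply(strsplit(as.character(trees$species), "\\s+"),
                          `[[`, "", 1L)
  }
  if (!"mode_of_death" %in% names(trees)) trees$mode_of_death <- "not_applicable"
  trees$mode_of_death[is.na(trees$mode_of_death)] <- "not_applicable"
  trees <- trees[, intersect(c("plot_id", "tree_id", "species", "genus",
                               "family", "is_palm", "census_date", "d_mm",
                               "status", "mode_of_death"), names(trees))]
  censuses <- trees |>
    distinct(.data$plot_id, date = .data$census_date) |>
    arrange(.data$plot_id, .data$date) |>
    group_by(.data$plot_id) |>
    mutate(census_index = seq_len(n()) - 1L) |>
    ungroup() |>
    select("plot_id", "census_index", "date")
  trees <- trees |>
    left_join(censuses, by = c(plot_id = "plot_id", census_date = "date")) |>
    arrange(.data$plot_id, .data$tree_id, .data$census_index)
  ds <- structure(
    list(plots = plots, trees = trees,
         traits = if (is.null(traits)) NULL else as_tibble(traits),
         censuses = censuses),
    class = "census_dataset")
  if (validate) validate_census_dataset(ds)
  ds
}

#' @export
print.census_dataset <- function(x, ...) {
  cat(sprintf(
    "<census_dataset> %d plots (%.2f ha), %d trees, %d observations\n",
    nrow(x$plots), sum(x$plots$area_ha),
    n_distinct(paste(x$trees$plot_id, x$trees$tree_id)), nrow(x$trees)))
  invisible(x)
}

#' Validate a census dataset
#'
#' Checks the structural invariants of the census tables: required columns,
#' positive plot areas, strictly increasing census dates within plots, no
#' duplicated (plot, tree, census) keys, minimum 100 mm diameter for alive
#' observations, at most one alive-to-dead transition per tree with no alive
#' record after death, and that a mode of death is only recorded for dead
#' observations.
#'
#' @param ds A [census_dataset()].
#' @return `ds`, invisibly; aborts with an informative message on violation.
#' @export
validate_census_dataset <- function(ds) {
  need_p <- c("plot_id", "region", "area_ha", "lat", "lon", "elev_m")
  miss <- setdiff(need_p, names(ds$plots))
  if (length(miss)) abort(paste0("plot table is missing column(s): ",
                                 paste(miss, collapse = ", ")),
                          class = "canopyhazard_format_error")
  need_t <- c("plot_id", "tree_id", "species", "family", "is_palm",
              "census_date", "d_mm", "status", "mode_of_death")
  miss <- setdiff(need_t, names(ds$trees))
  if (length(miss)) abort(paste0("census table is missing column(s): ",
                                 paste(miss, collapse = ", ")),
                          class = "canopyhazard_format_error")
  if (any(ds$plots$area_ha <= 0))
    abort("plot areas must be positive", class = "canopyhazard_validation_error")
  bad_region <- setdiff(unique(ds$plots$region), .regions)
  if (length(bad_region))
    abort(paste0("unknown region label(s): ", paste(bad_region, collapse = ", ")),
          class = "canopyhazard_validation_error")
  bad_status <- setdiff(unique(ds$trees$status), .statuses)
  if (length(bad_status))
    abort(paste0("unknown status value(s): ", paste(bad_status, collapse = ", ")),
          class = "canopyhazard_validation_error")
  orphan <- setdiff(unique(ds$trees$plot_id), ds$plots$plot_id)
  if (length(orphan))
    abort(paste0("trees reference unknown plot(s): ",
                 paste(orphan, collapse = ", ")),
          class = "canopyhazard_validation_error")
  dup <- ds$trees |>
    count(.data$plot_id, .data$tree_id, .data$census_date) |>
    filter(.data$n > 1)
  if (nrow(dup))
    abort(paste0("duplicated (plot, tree, census) rows, e.g. ",
                 dup$plot_id[1], "/", dup$tree_id[1], " at ",
                 format(dup$census_date[1])),
          class = "canopyhazard_validation_error")
  nm <- ds$censuses |>
    group_by(.data$plot_id) |>
    summarise(ok = all(diff(.data$date) > 0), .groups = "drop") |>
    filter(!.data$ok)
  if (nrow(nm))
    abort(paste0("non-monotone census dates in plot(s): ",
                 paste(nm$plot_id, collapse = ", ")),
          class = "canopyhazard_validation_error")
  small <- ds$trees |>
    filter(.data$status == "alive", !is.na(.data$d_mm), .data$d_mm < 100)
  if (nrow(small))
    abort(sprintf("alive observation below the 100 mm recruitment threshold (tree %s)",
                  small$tree_id[1]),
          class = "canopyhazard_validation_error")
  bad_mode <- ds$trees |>
    filter(.data$status != "dead", .data$mode_of_death != "not_applicable")
  if (nrow(bad_mode))
    abort(sprintf("mode of death recorded for a non-dead observation (tree %s)",
                  bad_mode$tree_id[1]),
          class = "canopyhazard_validation_error")
  trans <- ds$trees |>
    group_by(.data$plot_id, .data$tree_id) |>
    summarise(
      n_dead = sum(.data$status == "dead"),
      alive_after_dead = any(.data$status == "dead") &&
        any(which(.data$status == "alive") > min(which(.data$status == "dead"))),
      .groups = "drop")
  if (any(trans$n_dead > 1))
    abort(sprintf("tree %s has more than one death record",
                  trans$tree_id[which(trans$n_dead > 1)[1]]),
          class = "canopyhazard_validation_error")
  if (any(trans$alive_after_dead))
    abort(sprintf("tree %s has an alive observation after its death record",
                  trans$tree_id[which(trans$alive_after_dead)[1]]),
          class = "canopyhazard_validation_error")
  invisible(ds)
}

# canonical column names of the census CSV dialect
.census_cols <- c("plot_id", "tree_id", "species", "family", "is_palm",
                  "census_date", "d_mm", "status", "mode_of_death")
.plot_cols <- c("plot_id", "region", "area_ha", "lat", "lon", "elev_m")
.trait_csv_map <- c(species = "species", genus = "genus", family = "family",
                    wood_density = "wd_g_cm3", max_d = "max_d_mm",
                    mean_growth = "mean_growth_mm_yr", wda = "wda_mm")

#' Read census, plot and trait tables from CSV
#'
#' Reads the canonical long-format census table (one row per tree per census)
#' together with the plot table and, optionally, a species-trait table, and
#' returns a validated [census_dataset()]. Dates are decimal years throughout.
#'
#' @param census_path Path to the census CSV with columns `plot_id`,
#'   `tree_id`, `species`, `family`, `is_palm`, `census_date`, `d_mm`,
#'   `status`, `mode_of_death`. Missing diameters are empty fields.
#' @param plot_path Path to the plot CSV with columns `plot_id`, `region`,
#'   `area_ha`, `lat`, `lon`, `elev_m`.
#' @param trait_path Optional path to the traits CSV with columns `species`,
#'   `genus`, `family`, `wd_g_cm3`, `max_d_mm`, `mean_growth_mm_yr`, `wda_mm`.
#' @param dialect Optional named character vector mapping canonical census
#'   column names to the names used in the file, e.g.
#'   `c(plot_id = "PlotCode", d_mm = "DBH")`.
#' @return A validated [census_dataset()].
#' @export
read_census_table <- function(census_path, plot_path, trait_path = NULL,
                              dialect = NULL) {
  trees <- readr::read_csv(census_path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      if (!dialect[[canon]] %in% names(trees))
        abort(sprintf("census file has no column '%s' (mapped to '%s')",
                      dialect[[canon]], canon),
              class = "canopyhazard_format_error")
      names(trees)[names(trees) == dialect[[canon]]] <- canon
    }
  }
  miss <- setdiff(.census_cols, names(trees))
  if (length(miss))
    abort(paste0("census file is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "canopyhazard_format_error")
  plots <- readr::read_csv(plot_path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(.plot_cols, names(plots))
  if (length(miss))
    abort(paste0("plot file is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "canopyhazard_format_error")
  traits <- if (!is.null(trait_path)) read_trait_table(trait_path) else NULL
  trees$is_palm <- as.logical(trees$is_palm)
  census_dataset(plots, trees, traits)
}

#' Read a species-trait table
#'
#' @param path Traits CSV with columns `species`, `genus`, `family`,
#'   `wd_g_cm3` (wood density, g cm^-3), `max_d_mm` (95th-quantile species
#'   diameter, mm), `mean_growth_mm_yr` (species mean diameter growth,
#'   mm yr^-1) and `wda_mm` (water-deficit affiliation, mm; more negative is
#'   more drought-affiliated).
#' @return A tibble with canonical trait column names (`wood_density`,
#'   `max_d`, `mean_growth`, `wda`).
#' @export
read_trait_table <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(unname(.trait_csv_map), names(tr))
  if (length(miss))
    abort(paste0("trait file is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "canopyhazard_format_error")
  tr <- tr[, unname(.trait_csv_map)]
  names(tr) <- names(.trait_csv_map)
  as_tibble(tr)
}

#' Write a census dataset to CSV
#'
#' Inverse of [read_census_table()]: writes the canonical census, plot and
#' (when present) trait CSVs so that reading them back reproduces the dataset.
#'
#' @param ds A [census_dataset()].
#' @param census_path,plot_path,trait_path Output file paths; `trait_path`
#'   only used when the dataset carries traits.
#' @return `ds`, invisibly.
#' @export
write_census_table <- function(ds, census_path, plot_path, trait_path = NULL) {
  readr::write_csv(ds$trees[, .census_cols], census_path, progress = FALSE)
  readr::write_csv(ds$plots[, .plot_cols], plot_path, progress = FALSE)
  if (!is.null(trait_path) && !is.null(ds$traits)) {
    tr <- ds$traits[, names(.trait_csv_map)]
    names(tr) <- unname(.trait_csv_map)
    readr::write_csv(tr, trait_path, progress = FALSE)
  }
  invisible(ds)
}
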