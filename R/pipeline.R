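#' Configuration for a full pipeline run
#'
#' Collects every input path (or a simulation configuration), filter
#' threshold and analysis setting of the end-to-end analysis, with defaults
#' matching the standard protocol: 10-year maximum census gap, 0.5 ha
#' minimum plot area, 1000 m elevation ceiling, 50%/5-tree mode-of-death
#' eligibility, -5% yr^-1 relative-growth floor, 3-census minimum for
#' survival analysis and 10,000 bootstrap replicates.
#'
#' @param census_path,plot_path,trait_path Input CSVs (see
#'   [read_census_table()]); leave `NULL` to simulate instead.
#' @param sim A [sim_config()] used when no input paths are given.
#' @param out_dir Output directory.
#' @param seed Integer master seed for simulation and bootstrap.
#' @param bootstrap_B Bootstrap replicates.
#' @param max_census_gap_yr,min_area_ha,max_elevation_m,merge_km Filters.
#' @param growth_floor Relative-growth exclusion floor (% yr^-1).
#' @param min_censuses_survival Census minimum for the survival subset.
#' @param frailty Fit the hazard models with plot frailty.
#' @param ladder Named list of model specifications
#'   (default [amazon_model_ladder()]).
#' @return A `run_config` list.
#' @export
run_config <- function(census_path = NULL, plot_path = NULL,
                       trait_path = NULL, sim = sim_config(),
                       out_dir = tempfile("canopyhazard_run_"),
                       seed = 1, bootstrap_B = 10000,
                       max_census_gap_yr = 10, min_area_ha = 0.5,
                       max_elevation_m = 1000, merge_km = 1,
                       growth_floor = -5, min_censuses_survival = 3,
                       frailty = FALSE, ladder = amazon_model_ladder()) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full mortality analysis pipeline
#'
#' simulate (or read) -> validate -> merge/filter plots -> mortality rates
#' (plot, regional, basin, mode-specific, Tukey comparisons) -> mode-of-death
#' proportions with census-interval correction and regional model -> survival
#' records -> collinearity screen, model ladder, stepwise selection, regional
#' and mode-specific hazard fits. Every stage's outputs are written as CSV
#' (JSON for the fits) under `cfg$out_dir`, and a machine-readable
#' `manifest.json` records seeds, thresholds, package version, per-stage
#' status and exclusion counts; a failing stage is marked failed and the
#' partial outputs of earlier stages are kept.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with all result objects and the manifest.
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("canopyhazard")),
    seed = cfg$seed, bootstrap_B = cfg$bootstrap_B,
    thresholds = cfg[c("max_census_gap_yr", "min_area_ha", "max_elevation_m",
                       "merge_km", "growth_floor", "min_censuses_survival")],
    stages = list())
  out <- list()
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) e)
    ok <- !inherits(res, "error")
    manifest$stages[[name]] <<- list(
      status = if (ok) "ok" else "failed",
      message = if (ok) NULL else conditionMessage(res))
    if (!ok) {
      warn(sprintf("stage '%s' failed: %s", name, conditionMessage(res)))
      NULL
    } else res
  }

  out$data <- stage("input", {
    if (!is.null(cfg$census_path)) {
      read_census_table(cfg$census_path, cfg$plot_path, cfg$trait_path)
    } else {
      sim <- simulate_forest(cfg$sim, seed = cfg$seed)
      out$truth <- sim$truth
      sim$data
    }
  })
  if (is.null(out$data)) {
    manifest$stages$input$status <- "failed"
    write_manifest(manifest, cfg$out_dir)
    abort("pipeline failed at input/validation",
          class = "canopyhazard_pipeline_error")
  }

  out$filtered <- stage("filter", {
    ds <- merge_nearby_plots(out$data, cfg$merge_km)
    ds <- filter_plots(ds, cfg$max_census_gap_yr, cfg$min_area_ha,
                       cfg$max_elevation_m, min_censuses = 2)
    ds
  })
  if (!is.null(out$filtered))
    manifest$stages$filter$n_excluded <- nrow(exclusion_report(out$filtered))

  out$plot_rates <- stage("rates", {
    pr <- plot_mortality_rate(out$filtered)
    readr::write_csv(pr, file.path(cfg$out_dir, "plot_rates.csv"))
    pr
  })
  out$rate_summary <- stage("rate_summary", {
    rs <- regional_rate_summary(out$plot_rates, B = cfg$bootstrap_B,
                                seed = cfg$seed)
    readr::write_csv(rs, file.path(cfg$out_dir, "regional_rates.csv"))
    rs
  })
  out$region_comparison <- stage("region_comparison",
                                 compare_regions(out$plot_rates))
  out$mode_rates <- stage("mode_rates", {
    mr <- mode_specific_rates(out$filtered)
    readr::write_csv(mr, file.path(cfg$out_dir, "mode_rates.csv"))
    mr
  })

  out$mode_props <- stage("mode_props", {
    mp <- plot_mode_proportions(out$filtered)
    readr::write_csv(mp, file.path(cfg$out_dir, "mode_proportions.csv"))
    mp
  })
  out$cil_fit <- stage("cil_correction", fit_cil_correction(out$mode_props))
  out$regional_modes <- stage("regional_modes", {
    rm_ <- fit_regional_mode_model(out$mode_props)
    readr::write_csv(rm_$estimates,
                     file.path(cfg$out_dir, "regional_modes.csv"))
    rm_
  })

  out$records <- stage("records", {
    ds3 <- filter_plots(out$filtered, cfg$max_census_gap_yr, cfg$min_area_ha,
                        cfg$max_elevation_m,
                        min_censuses = cfg$min_censuses_survival)
    rec <- assemble_survival_records(ds3, growth_floor = cfg$growth_floor,
                                     min_censuses = cfg$min_censuses_survival)
    readr::write_csv(rec, file.path(cfg$out_dir, "survival_records.csv"))
    rec
  })
  if (!is.null(out$records)) {
    manifest$stages$records$n_records <- nrow(out$records)
    manifest$stages$records$n_events <- sum(out$records$event)
    manifest$stages$records$exclusion_counts <-
      as.list(table(exclusion_report(out$records)$rule))
  }

  out$vif <- stage("vif", vif(out$records))
  out$ladder <- stage("ladder", {
    ld <- model_ladder(out$records, cfg$ladder, frailty = cfg$frailty)
    readr::write_csv(ld |> mutate(terms = vapply(.data$terms, paste, "",
                                                 collapse = "+")),
                     file.path(cfg$out_dir, "model_ladder.csv"))
    ld
  })
  out$stepwise <- stage("stepwise", stepwise_aic(out$records,
                                                 frailty = cfg$frailty))
  out$full_fit <- stage("full_fit",
                        fit_cox(out$records, frailty = cfg$frailty))
  out$regional_fits <- stage("regional_fits", {
    purrr::map(split(out$records, out$records$region),
               ~ tryCatch(fit_cox(.x, frailty = cfg$frailty),
                          error = function(e) NULL))
  })
  out$mode_fits <- stage("mode_fits", fit_by_mode(out$records,
                                                  frailty = cfg$frailty))
  stage("fits_json", {
    fits <- list(full = tidy_fit_for_json(out$full_fit),
                 by_region = purrr::map(out$regional_fits,
                                        tidy_fit_for_json),
                 by_mode = purrr::map(unclass(out$mode_fits),
                                      tidy_fit_for_json))
    jsonlite::write_json(fits, file.path(cfg$out_dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  })

  out$manifest <- manifest
  write_manifest(manifest, cfg$out_dir)
  invisible(out)
}

tidy_fit_for_json <- function(f) {
  if (is.null(f)) return(NULL)
  list(terms = f$terms, coef = as.list(f$coefficients),
       se = as.list(f$se), chisq = as.list(f$chisq),
       loglik = f$loglik, aic = f$aic, theta = f$theta,
       n = f$n, nevent = f$nevent, converged = f$converged)
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
}
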