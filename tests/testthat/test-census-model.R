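test_that("reader/writer round-trips the canonical CSV dialect", {
  ds <- tiny_dataset()
  census <- withr::local_tempfile(fileext = ".csv")
  plots <- withr::local_tempfile(fileext = ".csv")
  write_census_table(ds, census, plots)
  back <- read_census_table(census, plots)
  expect_equal(back$plots, ds$plots)
  expect_equal(back$trees, ds$trees)
  expect_equal(nrow(back$plots), 1)
  expect_equal(dplyr::n_distinct(back$trees$tree_id), 2)
  expect_equal(nrow(back$trees), 6)

  # simulated dataset round trip, traits included
  sim <- simulate_forest(test_sim_config(), seed = 42)
  traits <- withr::local_tempfile(fileext = ".csv")
  write_census_table(sim$data, census, plots, traits)
  back <- read_census_table(census, plots, traits)
  expect_equal(back$trees, sim$data$trees)
  expect_equal(back$plots, sim$data$plots, tolerance = 1e-12)
  expect_equal(back$traits, sim$data$traits, tolerance = 1e-12)
})

test_that("column-mapping dialects are honoured and bad headers rejected", {
  ds <- tiny_dataset()
  census <- withr::local_tempfile(fileext = ".csv")
  plots <- withr::local_tempfile(fileext = ".csv")
  write_census_table(ds, census, plots)
  tr <- readr::read_csv(census, show_col_types = FALSE)
  names(tr)[names(tr) == "d_mm"] <- "DBH"
  readr::write_csv(tr, census)
  expect_error(read_census_table(census, plots),
               class = "canopyhazard_format_error")
  back <- read_census_table(census, plots, dialect = c(d_mm = "DBH"))
  expect_equal(back$trees$d_mm, ds$trees$d_mm)
})

test_that("validation catches duplicates, orphans and impossible histories", {
  ds <- tiny_dataset()
  dup <- ds$trees[c(1:6, 1), ]
  expect_error(census_dataset(ds$plots, dup),
               class = "canopyhazard_validation_error")
  expect_error(census_dataset(ds$plots[0, ], ds$trees),
               class = "canopyhazard_validation_error")
  small <- ds$trees
  small$d_mm[1] <- 80
  expect_error(census_dataset(ds$plots, small),
               class = "canopyhazard_validation_error")
  revive <- ds$trees
  revive$status[5:6] <- c("dead", "alive")
  revive$mode_of_death[5:6] <- c("standing", "not_applicable")
  revive$d_mm[5:6] <- c(NA, 204)
  expect_error(census_dataset(ds$plots, revive),
               class = "canopyhazard_validation_error")
  bad_mode <- ds$trees
  bad_mode$mode_of_death[1] <- "standing"
  expect_error(census_dataset(ds$plots, bad_mode),
               class = "canopyhazard_validation_error")
})

test_that("plot filters fire the documented rules and are idempotent", {
  ds <- filter_fixture()
  out <- filter_plots(ds, min_censuses = 2)
  rep <- exclusion_report(out)
  expect_equal(out$plots$plot_id, "OK")
  expect_equal(sort(unique(rep$plot_id)), c("GAP", "HIGH", "ONE", "SMALL"))
  expect_equal(rep$rule[rep$plot_id == "GAP"], "census gap > max")
  expect_equal(rep$rule[rep$plot_id == "SMALL"], "area < min")
  expect_equal(rep$rule[rep$plot_id == "HIGH"], "elevation > max")
  # survival subset rule
  out3 <- filter_plots(ds, min_censuses = 3)
  expect_equal(out3$plots$plot_id, "OK")
  # idempotence and identity on compliant data
  again <- filter_plots(out, min_censuses = 2)
  expect_equal(again$plots, out$plots)
  expect_equal(again$trees, out$trees)
  expect_equal(nrow(exclusion_report(again)), 0)
})

test_that("nearby small plots merge transitively with conserved totals", {
  mk_plot <- function(id, lat, area) tibble::tibble(
    plot_id = id, region = "Western", area_ha = area, lat = lat, lon = -72,
    elev_m = 100)
  mk_trees <- function(id, dates) tibble::tibble(
    plot_id = id, tree_id = paste0(id, "-t", 1:2) |> rep(each = length(dates)),
    species = "Genus1 sp1", family = "Fam1", is_palm = FALSE,
    census_date = rep(dates, 2), d_mm = 150, status = "alive",
    mode_of_death = "not_applicable")
  # 0.8 km apart chain: A-B 0.8km, B-C 0.8km, A-C 1.6km
  dlat <- 0.8 / 111.2
  plots <- dplyr::bind_rows(mk_plot("A", 0, 0.25), mk_plot("B", dlat, 0.25),
                            mk_plot("C", 2 * dlat, 0.3),
                            mk_plot("FAR", 0.5, 1))
  trees <- dplyr::bind_rows(mk_trees("A", c(2000, 2004)),
                            mk_trees("B", c(2000.2, 2004.3)),
                            mk_trees("C", c(2000.1, 2004.2)),
                            mk_trees("FAR", c(2000, 2004)))
  ds <- census_dataset(plots, trees)
  merged <- merge_nearby_plots(ds)
  expect_equal(nrow(merged$plots), 2)
  expect_equal(sum(merged$plots$area_ha), sum(plots$area_ha))
  expect_equal(nrow(merged$trees), nrow(trees))
  expect_equal(merged$plots$area_ha[merged$plots$plot_id == "A+B+C"], 0.8)
  # plots above the threshold stay unchanged
  far2 <- merge_nearby_plots(census_dataset(
    dplyr::bind_rows(mk_plot("A", 0, 0.25), mk_plot("B", 1.2 / 111.2, 0.25)),
    dplyr::bind_rows(mk_trees("A", c(2000, 2004)),
                     mk_trees("B", c(2000, 2004)))))
  expect_equal(sort(far2$plots$plot_id), c("A", "B"))
  # incompatible schedules stay unmerged and are reported
  inc <- merge_nearby_plots(census_dataset(
    dplyr::bind_rows(mk_plot("A", 0, 0.25), mk_plot("B", dlat, 0.25)),
    dplyr::bind_rows(mk_trees("A", c(2000, 2004)),
                     mk_trees("B", c(2001.5, 2005.5)))))
  expect_equal(sort(inc$plots$plot_id), c("A", "B"))
  expect_true(all(c("A", "B") %in% exclusion_report(inc)$plot_id))
  # differing regions abort
  pB <- mk_plot("B", dlat, 0.25); pB$region <- "Southern"
  expect_error(merge_nearby_plots(census_dataset(
    dplyr::bind_rows(mk_plot("A", 0, 0.25), pB),
    dplyr::bind_rows(mk_trees("A", c(2000, 2004)),
                     mk_trees("B", c(2000, 2004))))),
    class = "canopyhazard_validation_error")
})

test_that("mode-assessment eligibility applies the 50%/5-tree rule", {
  mk <- function(pid, n_dead, n_assessed) tibble::tibble(
    plot_id = pid, tree_id = paste0(pid, "-t", seq_len(n_dead + 1)),
    species = "Genus1 sp1", family = "Fam1", is_palm = FALSE,
    census_date = 2000,
    d_mm = c(rep(NA, n_dead), 150), status = c(rep("dead", n_dead), "alive"),
    mode_of_death = c(rep("standing", n_assessed),
                      rep("unassessed", n_dead - n_assessed),
                      "not_applicable"))
  plots <- tibble::tibble(
    plot_id = c("E1", "E2", "E3", "E4"), region = "Northern", area_ha = 1,
    lat = 1:4, lon = -60, elev_m = 100)
  ds <- census_dataset(plots, dplyr::bind_rows(
    mk("E1", 10, 6), mk("E2", 8, 4), mk("E3", 4, 4), mk("E4", 1, 0)))
  el <- mode_assessment_eligibility(ds) |> dplyr::arrange(plot_id)
  expect_equal(el$eligible, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(el$reason[2], "fewer than 5 assessed")
  expect_equal(el$reason[3], "fewer than 5 assessed")
  # permutation invariance: order of rows never matters
  ds2 <- census_dataset(plots, dplyr::bind_rows(
    mk("E1", 10, 6), mk("E2", 8, 4), mk("E3", 4, 4), mk("E4", 1, 0)) |>
      dplyr::slice_sample(prop = 1))
  expect_equal(mode_assessment_eligibility(ds2) |> dplyr::arrange(plot_id),
               el)
})
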