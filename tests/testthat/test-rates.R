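test_that("interval mortality rate matches the closed form", {
  expect_equal(interval_mortality_rate(100, 100, 2), 0)
  expect_equal(interval_mortality_rate(100, 50, 1), 50)
  expect_equal(interval_mortality_rate(100, 81, 2), 10)
  expect_error(interval_mortality_rate(0, 0, 1),
               class = "canopyhazard_validation_error")
  expect_error(interval_mortality_rate(10, 11, 1),
               class = "canopyhazard_validation_error")
  expect_error(interval_mortality_rate(10, 5, 0),
               class = "canopyhazard_validation_error")
})

test_that("splitting an interval leaves the compounded rate unchanged", {
  withr::with_seed(11, {
    for (i in 1:200) {
      n0 <- sample(50:500, 1)
      n1 <- sample(0:n0, 1)
      n2 <- sample(0:n1, 1)
      t1 <- runif(1, 0.5, 5); t2 <- runif(1, 0.5, 5)
      m_full <- interval_mortality_rate(n0, n2, t1 + t2)
      m1 <- interval_mortality_rate(n0, n1, t1)
      m2 <- if (n1 >= 1) interval_mortality_rate(n1, n2, t2) else NA
      if (n1 >= 1) {
        surv <- (1 - m1 / 100)^t1 * (1 - m2 / 100)^t2
        expect_equal((1 - m_full / 100)^(t1 + t2), surv, tolerance = 1e-12)
      }
    }
  })
})

test_that("plot rates are census-interval-weighted means", {
  iv <- tibble::tibble(plot_id = "P", m = c(2, 4), t_yr = c(1, 3))
  expect_equal(plot_mortality_rate(iv)$m_plot, 3.5)
  expect_equal(plot_mortality_rate(iv[1, ])$m_plot, 2)
  iv_eq <- tibble::tibble(plot_id = "P", m = c(2, 4, 6), t_yr = 2)
  expect_equal(plot_mortality_rate(iv_eq)$m_plot, 4)
  expect_error(plot_mortality_rate(iv[0, ]),
               class = "canopyhazard_validation_error")
})

test_that("mode-specific rates partition deaths between modes", {
  n_alive <- 90; n_std <- 5; n_brk <- 5
  plots <- tibble::tibble(plot_id = "M1", region = "Western", area_ha = 1,
                          lat = -4, lon = -70, elev_m = 100)
  mk_tree <- function(i, fate, mode) {
    tibble::tibble(plot_id = "M1", tree_id = sprintf("t%03d", i),
                   species = "Genus1 sp1", family = "Fam1", is_palm = FALSE,
                   census_date = c(2000, 2001),
                   d_mm = if (fate == "alive") c(150, 151) else c(150, NA),
                   status = c("alive", fate),
                   mode_of_death = c("not_applicable", mode))
  }
  trees <- dplyr::bind_rows(
    purrr::map(1:n_alive, ~ mk_tree(.x, "alive", "not_applicable")),
    purrr::map(n_alive + (1:n_std), ~ mk_tree(.x, "dead", "standing")),
    purrr::map(n_alive + n_std + (1:n_brk), ~ mk_tree(.x, "dead",
                                                      "broken_uprooted")))
  ds <- census_dataset(plots, trees)
  mr <- mode_specific_rates(ds)
  expect_equal(mr$m_plot[mr$mode == "standing"],
               interval_mortality_rate(100, 95, 1))
  expect_equal(mr$m_plot[mr$mode == "broken_uprooted"],
               interval_mortality_rate(100, 95, 1))
  expect_equal(plot_mortality_rate(ds)$m_plot,
               interval_mortality_rate(100, 90, 1))
  # exact partition: total survival fraction equals survivors / initial
  # and deaths split by mode reproduce the overall count
  ir <- interval_rates(ds)
  expect_equal(ir$n_t1 / ir$n_t0, 0.9)
  # ineligible plots are skipped and reported
  trees2 <- trees
  trees2$mode_of_death[trees2$mode_of_death %in%
                         c("standing", "broken_uprooted")][1:8] <- "unassessed"
  mr2 <- mode_specific_rates(census_dataset(plots, trees2))
  expect_equal(nrow(mr2), 0)
  expect_equal(exclusion_report(mr2)$plot_id, "M1")
})

test_that("bootstrap summary is deterministic, degenerate-safe and centred", {
  # degenerate landscape: every plot identical -> zero-width interval
  bs <- bootstrap_weighted_mean(rep(2.5, 8), runif(8, 0.5, 2), B = 500,
                                seed = 3)
  expect_equal(bs$mean, 2.5)
  expect_equal(bs$ci_lo, 2.5)
  expect_equal(bs$ci_hi, 2.5)
  # determinism
  v <- c(1.2, 3.4, 2.2, 0.8); w <- c(1, 2, 0.5, 1)
  expect_identical(bootstrap_weighted_mean(v, w, B = 1000, seed = 7),
                   bootstrap_weighted_mean(v, w, B = 1000, seed = 7))
  expect_false(identical(
    bootstrap_weighted_mean(v, w, B = 1000, seed = 7)$mean,
    bootstrap_weighted_mean(v, w, B = 1000, seed = 8)$mean))
  # exhaustive enumeration oracle for two plots: the bootstrap mean over
  # B -> Inf replicates is the mean over the 4 equiprobable resamples
  v2 <- c(1, 3); w2 <- c(1, 3)
  enum <- mean(c(1, 3, (1 * 1 + 3 * 3) / 4, (1 * 1 + 3 * 3) / 4))
  bs2 <- bootstrap_weighted_mean(v2, w2, B = 60000, seed = 5)
  expect_equal(bs2$mean, enum, tolerance = 0.02)
  expect_error(bootstrap_weighted_mean(v2, w2, B = 0),
               class = "canopyhazard_validation_error")
  expect_error(bootstrap_weighted_mean(v2, c(1, -1)),
               class = "canopyhazard_validation_error")
})

test_that("regional Tukey comparisons flag separated groups and letter them", {
  withr::with_seed(5, {
    same <- tibble::tibble(
      region = rep(c("Northern", "Southern"), each = 10),
      m_plot = rep(rnorm(10, 2, 0.3), 2))
  })
  cmp_same <- compare_regions(same)
  expect_gt(cmp_same$pairs$p_adj, 0.99)
  expect_equal(abs(cmp_same$pairs$diff), 0)
  expect_equal(cmp_same$letters$letters, c("a", "a"))

  withr::with_seed(6, {
    sep <- tibble::tibble(
      region = rep(c("Northern", "Southern"), each = 20),
      m_plot = c(rnorm(20, 0, 0.1), rnorm(20, 10, 0.1)))
  })
  cmp_sep <- compare_regions(sep)
  expect_lt(cmp_sep$pairs$p_adj, 1e-6)
  expect_setequal(cmp_sep$letters$letters, c("a", "b"))

  # three groups, one outlier -> unique letter for the outlier
  withr::with_seed(7, {
    three <- tibble::tibble(
      region = rep(c("Northern", "Southern", "Western"), each = 15),
      m_plot = c(rnorm(15, 2, 0.2), rnorm(15, 2.05, 0.2), rnorm(15, 8, 0.2)))
  })
  cmp3 <- compare_regions(three)
  lt <- cmp3$letters
  expect_equal(lt$letters[lt$region == "Western"],
               setdiff(lt$letters, lt$letters[lt$region != "Western"]))
  expect_equal(lt$letters[lt$region == "Northern"],
               lt$letters[lt$region == "Southern"])
  # regions with a single plot are dropped with a warning
  one <- dplyr::bind_rows(three, tibble::tibble(region = "EastCentral",
                                                m_plot = 1))
  expect_warning(compare_regions(one), "fewer than 2 plots")
})

test_that("Tukey adjusted p-values agree with a permutation oracle", {
  withr::with_seed(12, {
    df <- tibble::tibble(
      region = rep(c("Northern", "Southern"), each = 12),
      m_plot = c(rnorm(12, 2, 0.5), rnorm(12, 2.6, 0.5)))
    obs <- abs(diff(tapply(df$m_plot, df$region, mean)))
    perm <- replicate(2000, {
      y <- sample(df$m_plot)
      abs(mean(y[1:12]) - mean(y[13:24]))
    })
    p_perm <- mean(perm >= obs)
  })
  p_tukey <- compare_regions(df)$pairs$p_adj
  # with two groups Tukey reduces to a t-test; permutation agrees closely
  expect_lt(abs(p_tukey - p_perm), 0.05)
})
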