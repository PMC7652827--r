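test_that("partial log-likelihood matches closed forms", {
  # three subjects, distinct death times, beta = 0: risk-set sizes only
  rec3 <- tibble::tibble(tree_id = c("a", "b", "c"), plot_id = "P1",
                         time_at_risk = c(1, 2, 3), event = 1,
                         x1 = c(0.3, -1, 2))
  expect_equal(cox_partial_loglik(rec3, "x1", 0), -(log(3) + log(2) + log(1)))
  # two subjects: loglik(beta) = beta - log(exp(beta) + 1)
  rec2 <- tibble::tibble(tree_id = c("a", "b"), plot_id = "P1",
                         time_at_risk = c(1, 2), event = c(1, 0),
                         x1 = c(1, 0))
  for (b in c(-1, 0, 0.7, 2)) {
    expect_equal(cox_partial_loglik(rec2, "x1", b), b - log(exp(b) + 1))
  }
  expect_equal(cox_partial_loglik(rec2, "x1", 0), -log(2))
  # all censored: zero with a warning
  recc <- rec2; recc$event <- 0
  expect_warning(ll <- cox_partial_loglik(recc, "x1", 0), "censored")
  expect_equal(ll, 0)
  # non-finite linear predictor names the record
  recb <- rec2; recb$x1 <- c(Inf, 0)
  expect_error(cox_partial_loglik(recb, "x1", 1), "record",
               class = "canopyhazard_numeric_error")
})

test_that("tied deaths: Efron and Breslow match hand-expanded formulas", {
  # 4 subjects, 2 tied deaths at t=1 (x = a, b), risk set {a,b,c,d}
  rec <- tibble::tibble(tree_id = letters[1:4], plot_id = "P1",
                        time_at_risk = c(1, 1, 2, 3),
                        event = c(1, 1, 0, 1),
                        x1 = c(0.5, -0.2, 1, -1))
  b <- 0.8
  e <- exp(b * rec$x1)
  s_all <- sum(e); s_d <- e[1] + e[2]
  hand_breslow <- b * (0.5 - 0.2) - 2 * log(s_all) +
    (b * -1 - log(e[4]))
  hand_efron <- b * (0.5 - 0.2) - log(s_all) - log(s_all - 0.5 * s_d) +
    (b * -1 - log(e[4]))
  expect_equal(cox_partial_loglik(rec, "x1", b, ties = "breslow"),
               hand_breslow)
  expect_equal(cox_partial_loglik(rec, "x1", b, ties = "efron"), hand_efron)
  expect_gte(hand_efron, hand_breslow)
})

test_that("engine equals the exhaustive oracle on random micro-datasets", {
  withr::with_seed(41, {
    for (i in 1:60) {
      n <- sample(3:8, 1)
      rec <- random_micro_records(n)
      if (!any(rec$event == 1)) next
      beta <- rnorm(2, 0, 0.7)
      for (ties in c("efron", "breslow")) {
        expect_equal(
          cox_partial_loglik(rec, c("x1", "x2"), beta, ties = ties),
          oracle_partial_loglik(rec$time_at_risk, rec$event,
                                rec[, c("x1", "x2")], beta, ties),
          tolerance = 1e-10)
      }
      # beta = 0 depends only on risk-set sizes (Breslow form)
      risk_sizes <- vapply(rec$time_at_risk[rec$event == 1],
                           function(t) sum(rec$time_at_risk >= t), 0)
      expect_equal(
        cox_partial_loglik(rec, c("x1", "x2"), c(0, 0), ties = "breslow"),
        -sum(log(risk_sizes)), tolerance = 1e-10)
    }
  })
})

test_that("engine gradient matches central finite differences", {
  withr::with_seed(43, {
    rec <- random_micro_records(40)
    beta <- c(0.3, -0.5)
    eps <- 1e-6
    ll <- function(b) cox_partial_loglik(rec, c("x1", "x2"), b)
    fd <- sapply(1:2, function(j) {
      e <- numeric(2); e[j] <- eps
      (ll(beta + e) - ll(beta - e)) / (2 * eps)
    })
    s <- canopyhazard:::sort_for_engine(rec, c("x1", "x2"))
    g <- canopyhazard:::engine_eval(s, integer(0), 0L, beta, numeric(0),
                                    "efron")$grad
    expect_equal(unname(g), fd, tolerance = 1e-6)
  })
})

test_that("fits agree with the reference implementation to 1e-6", {
  skip_if_not_installed("survival")
  withr::with_seed(45, {
    rec <- direct_cox_records(400, c(x1 = 0.5, x2 = -0.3))
  })
  for (ties in c("efron", "breslow")) {
    ours <- fit_cox(rec, c("x1", "x2"), ties = ties)
    ref <- survival::coxph(survival::Surv(time_at_risk, event) ~ x1 + x2,
                           data = rec, ties = ties)
    expect_equal(unname(ours$coefficients), unname(coef(ref)),
                 tolerance = 1e-6)
    expect_equal(unname(ours$se), unname(sqrt(diag(vcov(ref)))),
                 tolerance = 1e-6)
    expect_equal(ours$partial_loglik, ref$loglik[2], tolerance = 1e-8)
  }
})

test_that("null model, AIC accounting and Wald statistics are consistent", {
  withr::with_seed(46, {
    rec <- direct_cox_records(200, c(x1 = 0.4))
  })
  f0 <- fit_cox(rec, character(0))
  expect_equal(f0$loglik, cox_partial_loglik(rec))
  expect_equal(f0$aic, -2 * f0$loglik)
  f1 <- fit_cox(rec, "x1")
  expect_equal(f1$aic, -2 * f1$loglik + 2)
  expect_equal(unname(f1$chisq), unname((f1$coefficients / f1$se)^2))
  # Wald and LR chi-squared agree within 15% on a well-behaved fit
  lr <- term_lr_chisq(rec, f1)
  expect_lt(abs(lr$chisq_wald - lr$chisq_lr) / lr$chisq_lr, 0.15)
})

test_that("coefficients are scale-equivariant", {
  withr::with_seed(47, {
    rec <- direct_cox_records(300, c(x1 = 0.5, x2 = -0.2))
  })
  f <- fit_cox(rec, c("x1", "x2"))
  rec2 <- rec; rec2$x1 <- rec2$x1 * 10
  f2 <- fit_cox(rec2, c("x1", "x2"))
  expect_equal(f2$coefficients[["x1"]], f$coefficients[["x1"]] / 10,
               tolerance = 1e-7)
  expect_equal(f2$loglik, f$loglik, tolerance = 1e-9)
  expect_equal(f2$aic, f$aic, tolerance = 1e-9)
  expect_equal(unname(f2$chisq), unname(f$chisq), tolerance = 1e-6)
})

test_that("frailty fits shrink towards zero when plots are homogeneous", {
  withr::with_seed(48, {
    rec <- direct_cox_records(600, c(x1 = 0.3))
    rec$plot_id <- sample(sprintf("P%02d", 1:20), 600, replace = TRUE)
  })
  f <- fit_cox(rec, "x1", frailty = TRUE)
  expect_lt(f$theta, 0.15)
  expect_equal(f$coefficients[["x1"]],
               fit_cox(rec, "x1")$coefficients[["x1"]], tolerance = 0.05)
  # fixed-theta penalized fit: larger theta lets frailties spread more
  f_small <- fit_cox(rec, "x1", frailty = TRUE, theta = 0.01)
  f_big <- fit_cox(rec, "x1", frailty = TRUE, theta = 5)
  expect_lt(var(f_small$frailty), var(f_big$frailty))
})

test_that("frailty estimation recovers heterogeneous plot effects", {
  withr::with_seed(49, {
    nplot <- 40; per <- 40
    b <- rnorm(nplot, 0, sqrt(0.8))
    rec <- purrr::map_dfr(seq_len(nplot), function(i) {
      x <- rnorm(per)
      t_death <- rexp(per, 0.1 * exp(0.3 * x + b[i]))
      tibble::tibble(tree_id = paste0("p", i, "-", 1:per),
                     plot_id = sprintf("P%02d", i),
                     time_at_risk = pmin(t_death, 8),
                     event = as.integer(t_death <= 8), x1 = x)
    })
  })
  f <- fit_cox(rec, "x1", frailty = TRUE)
  expect_gt(f$theta, 0.2)
  expect_lt(f$theta, 2.5)
  # recovered frailties correlate with the generating ones
  expect_gt(cor(f$frailty[sprintf("P%02d", 1:40)], b), 0.6)
})

test_that("VIF flags collinearity and equals its closed form", {
  withr::with_seed(50, {
    n <- 500
    df <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  })
  v <- vif(df, c("a", "b", "c"))
  expect_true(all(v$vif < 1.1))
  # duplicated predictor: infinite VIF
  df$d <- df$a
  v2 <- vif(df, c("a", "b", "d"))
  expect_true(all(is.infinite(v2$vif[v2$term %in% c("a", "d")])))
  # known R^2 = 0.9 pair gives VIF = 10
  withr::with_seed(51, {
    x <- rnorm(20000)
    y <- x * sqrt(0.9) + rnorm(20000, 0, sqrt(0.1))
  })
  v3 <- vif(tibble::tibble(x = x, y = y), c("x", "y"))
  expect_equal(v3$vif, c(10, 10), tolerance = 0.1)
  expect_error(vif(df, "a"), class = "canopyhazard_validation_error")
})

test_that("stepwise selection respects the size hierarchy and its AIC bound", {
  withr::with_seed(52, {
    rec <- direct_cox_records(800, c(rel_growth = -0.3, mean_growth = 0.4,
                                     wood_density = 0))
    rec$D <- runif(800, 0.1, 0.6); rec$D2 <- rec$D^2
  })
  full <- c("rel_growth", "D", "D2", "mean_growth", "wood_density")
  sw <- stepwise_aic(rec, full)
  expect_lte(sw$aic, fit_cox(rec, full)$aic + 1e-8)
  expect_lte(sw$aic, fit_cox(rec, character(0))$aic + 1e-8)
  expect_true(all(c("rel_growth", "mean_growth") %in% sw$terms))
  # D2 never present without D in any evaluated candidate
  expect_false(any(grepl("(^|\\+)D2", sw$trace$terms) &
                     !grepl("(^|\\+)D($|\\+)", sw$trace$terms)))
})

test_that("the model ladder ranks specifications deterministically", {
  withr::with_seed(53, {
    rec <- direct_cox_records(600, c(rel_growth = -0.3, mean_growth = 0.4))
  })
  specs <- list(full = c("rel_growth", "mean_growth"),
                growth_only = "mean_growth",
                dup = c("rel_growth", "mean_growth"),
                null = character(0))
  ld <- model_ladder(rec, specs)
  expect_equal(ld$delta_aic[1], 0)
  expect_equal(ld$aic[ld$model == "full"], ld$aic[ld$model == "dup"])
  expect_true(all(diff(ld$delta_aic) >= 0))
  expect_equal(nrow(ld), 4)
})

test_that("mode-specific fits censor the other mode and recover its mechanism", {
  withr::with_seed(54, {
    n <- 3000
    x <- rnorm(n)
    t_death <- rexp(n, 0.08 * exp(-0.3 * x))
    event <- as.integer(t_death <= 10)
    # slow growers (low x) die standing more often
    p_standing <- plogis(-0.8 * x)
    mode <- ifelse(event == 1,
                   ifelse(runif(n) < p_standing, "standing",
                          "broken_uprooted"), NA)
    rec <- tibble::tibble(tree_id = paste0("t", 1:n), plot_id = "P1",
                          time_at_risk = pmin(t_death, 10), event = event,
                          mode = mode, rel_growth = x)
  })
  mf <- fit_by_mode(rec, "rel_growth")
  expect_s3_class(mf$standing, "hazard_fit")
  expect_lt(mf$standing$coefficients[["rel_growth"]],
            mf$broken_uprooted$coefficients[["rel_growth"]])
  expect_equal(mf$standing$nevent + mf$broken_uprooted$nevent,
               sum(rec$event))
  # one mode only: the other fit is skipped with a message
  rec1 <- rec; rec1$mode[rec1$event == 1] <- "standing"
  expect_message(mf1 <- fit_by_mode(rec1, "rel_growth"), "skipped")
  expect_null(mf1$broken_uprooted)
})

test_that("tidiers and plots expose the fit sensibly", {
  withr::with_seed(55, {
    rec <- direct_cox_records(300, c(x1 = 0.5))
  })
  f <- fit_cox(rec, "x1")
  td <- tidy(f)
  expect_equal(td$term, "x1")
  expect_true(td$conf.low < td$estimate & td$estimate < td$conf.high)
  gl <- glance(f)
  expect_equal(gl$nevent, f$nevent)
  p <- autoplot(f)
  expect_s3_class(p, "ggplot")
})
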