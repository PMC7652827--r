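#' Plot-level mode-of-death proportions
#'
#' For every plot passing [mode_assessment_eligibility()], computes the
#' proportion of assessed dead trees found standing and broken/uprooted
#' (unassessed deaths are excluded from both numerator and denominator)
#' together with the plot's mean census-interval length, the covariate used
#' by the bias correction.
#'
#' @param ds A [census_dataset()].
#' @return A tibble with one row per eligible plot per mode: `plot_id`,
#'   `region`, `mode`, `p_mod` (proportion in `[0, 1]`), `n_assessed`,
#'   `cil_bar` (mean census-interval length, years). Ineligible plots are
#'   listed in the `"exclusions"` attribute.
#' @export
plot_mode_proportions <- function(ds) {
  elig <- mode_assessment_eligibility(ds)
  keep <- elig$plot_id[elig$eligible]
  cil <- ds$censuses |>
    group_by(.data$plot_id) |>
    summarise(cil_bar = mean(diff(.data$date)), .groups = "drop")
  counts <- ds$trees |>
    filter(.data$plot_id %in% keep, .data$status == "dead",
           .data$mode_of_death %in% c("standing", "broken_uprooted")) |>
    count(.data$plot_id, mode = .data$mode_of_death) |>
    tidyr::complete(plot_id = keep, mode = c("standing", "broken_uprooted"),
                    fill = list(n = 0L)) |>
    group_by(.data$plot_id) |>
    mutate(n_assessed = sum(.data$n), p_mod = .data$n / .data$n_assessed) |>
    ungroup()
  out <- counts |>
    left_join(cil, by = "plot_id") |>
    left_join(ds$plots |> select("plot_id", "region"), by = "plot_id") |>
    select("plot_id", "region", "mode", "p_mod", "n_assessed", "cil_bar")
  attr(out, "exclusions") <- elig |> filter(!.data$eligible) |>
    transmute(.data$plot_id, rule = .data$reason)
  out
}

#' Census-interval-length correction of a mode-of-death proportion
#'
#' The longer a plot goes between censuses, the more standing deaths have
#' broken before they are found, inflating the broken/uprooted proportion.
#' This fits, by ordinary least squares, the plot-level proportion of one
#' mode against the plot's mean census-interval length centred to mean zero;
#' the intercept is then the proportion corrected to the across-plot mean
#' interval, and the slope measures the bias in proportion per year.
#'
#' @param props Output of [plot_mode_proportions()].
#' @param mode Which mode to model (default `"broken_uprooted"`).
#' @return An object of class `cil_fit`: `beta0` (corrected proportion at
#'   the mean interval), `beta1` (proportion per year), `r_squared`,
#'   `p_value` (two-sided, for the slope), `df_residual`, `cil_center` and
#'   the underlying `lm` fit. Out-of-`[0, 1]` corrected proportions are
#'   reported as-is with a warning, never clipped.
#' @export
fit_cil_correction <- function(props, mode = "broken_uprooted") {
  df <- props |> filter(.data$mode == !!mode)
  if (nrow(df) < 3 || n_distinct(df$cil_bar) < 2)
    abort("correction unidentifiable: need >= 3 plots with varying mean census-interval length",
          class = "canopyhazard_validation_error")
  if (var(df$cil_bar) == 0)
    abort("correction unidentifiable: zero variance in census-interval length",
          class = "canopyhazard_validation_error")
  ctr <- mean(df$cil_bar)
  fit <- lm(p_mod ~ I(cil_bar - ctr), data = df)
  sm <- summary(fit)
  beta0 <- unname(coef(fit)[1])
  if (beta0 < 0 || beta0 > 1)
    warn(sprintf("corrected proportion %.3f lies outside [0, 1]", beta0))
  structure(list(
    mode = mode, beta0 = beta0, beta1 = unname(coef(fit)[2]),
    se = unname(sqrt(diag(vcov(fit)))),
    r_squared = sm$r.squared,
    p_value = unname(sm$coefficients[2, 4]),
    df_residual = fit$df.residual,
    cil_center = ctr, n_plots = nrow(df), fit = fit),
    class = "cil_fit")
}

#' @export
print.cil_fit <- function(x, ...) {
  cat(sprintf(
    "CIL-corrected %s proportion: %.3f (SE %.3f)\nslope %.4f yr^-1 (p = %.3g), R^2 = %.3f, n = %d plots\n",
    x$mode, x$beta0, x$se[1], x$beta1, x$p_value, x$r_squared, x$n_plots))
  invisible(x)
}

#' Regional mode-of-death proportions adjusted for census-interval length
#'
#' Fits a linear model of the plot-level mode proportion on the centred mean
#' census-interval length and region, then reports each region's adjusted
#' proportion at the mean interval with a t-based 95% confidence interval,
#' and all pairwise regional contrasts with studentized-range (Tukey)
#' adjusted p-values.
#'
#' @param props Output of [plot_mode_proportions()].
#' @param mode Which mode to model (default `"broken_uprooted"`).
#' @param conf Confidence level (default 0.95).
#' @return An object of class `regional_modes` with `estimates` (tibble:
#'   `region`, `estimate`, `ci_lo`, `ci_hi`, `n_plots`, `mode`) and
#'   `contrasts` (tibble: `region_a`, `region_b`, `diff`, `se`, `t`,
#'   `p_adj`).
#' @export
fit_regional_mode_model <- function(props, mode = "broken_uprooted",
                                    conf = 0.95) {
  df <- props |> filter(.data$mode == !!mode)
  sizes <- df |> count(.data$region)
  singles <- sizes$region[sizes$n < 2]
  if (length(singles)) {
    warn(paste0("region(s) with a single plot dropped: ",
                paste(singles, collapse = ", ")))
    df <- df |> filter(!.data$region %in% singles)
  }
  if (n_distinct(df$region) < 2)
    abort("need at least two regions", class = "canopyhazard_validation_error")
  ctr <- mean(df$cil_bar)
  df$cil_c <- df$cil_bar - ctr
  df$region <- factor(df$region)
  fit <- lm(p_mod ~ cil_c + region, data = df)
  regs <- levels(df$region)
  newd <- tibble(cil_c = 0, region = factor(regs, levels = regs))
  pr <- predict(fit, newdata = newd, se.fit = TRUE)
  tq <- qt(1 - (1 - conf) / 2, fit$df.residual)
  estimates <- tibble(
    region = regs, estimate = unname(pr$fit),
    ci_lo = unname(pr$fit - tq * pr$se.fit),
    ci_hi = unname(pr$fit + tq * pr$se.fit),
    n_plots = as.integer(table(df$region)[regs]), mode = mode)
  # pairwise adjusted-mean contrasts with Tukey (studentized range) p-values
  V <- vcov(fit)
  mm <- stats::model.matrix(~ cil_c + region, data = newd)
  combs <- utils::combn(seq_along(regs), 2)
  contrasts <- purrr::map_dfr(seq_len(ncol(combs)), function(j) {
    i1 <- combs[1, j]; i2 <- combs[2, j]
    L <- mm[i2, ] - mm[i1, ]
    d <- sum(L * coef(fit))
    se <- sqrt(drop(t(L) %*% V %*% L))
    tval <- d / se
    tibble(region_a = regs[i2], region_b = regs[i1], diff = d, se = se,
           t = tval,
           p_adj = ptukey(sqrt(2) * abs(tval), length(regs),
                          fit$df.residual, lower.tail = FALSE))
  })
  structure(list(estimates = estimates, contrasts = contrasts,
                 cil_center = ctr, mode = mode, fit = fit),
            class = "regional_modes")
}

#' @export
print.regional_modes <- function(x, ...) {
  cat(sprintf("Adjusted %s proportions (at mean CIL %.2f yr)\n",
              x$mode, x$cil_center))
  print(x$estimates)
  print(x$contrasts)
  invisible(x)
}
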