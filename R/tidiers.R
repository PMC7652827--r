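#' Tidy a hazard-model fit
#'
#' @param x A `hazard_fit` from [fit_cox()].
#' @param conf.int Add Wald confidence bounds.
#' @param conf.level Confidence level.
#' @param ... Unused.
#' @return A tibble with one row per term: `term`, `estimate`, `std.error`,
#'   `statistic` (Wald chi-squared), `p.value` and optional bounds.
#' @export
tidy.hazard_fit <- function(x, conf.int = TRUE, conf.level = 0.95, ...) {
  out <- tibble(term = x$terms, estimate = unname(x$coefficients),
                std.error = unname(x$se), statistic = unname(x$chisq),
                p.value = unname(x$p_value))
  if (conf.int && nrow(out)) {
    z <- stats::qnorm(1 - (1 - conf.level) / 2)
    out$conf.low <- out$estimate - z * out$std.error
    out$conf.high <- out$estimate + z * out$std.error
  }
  out
}

#' Glance at a hazard-model fit
#'
#' @param x A `hazard_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `nevent`, `logLik`, `AIC`,
#'   `frailty_variance`, `converged`, `iter`.
#' @export
glance.hazard_fit <- function(x, ...) {
  tibble(n = x$n, nevent = x$nevent, logLik = x$loglik, AIC = x$aic,
         frailty_variance = x$theta, converged = x$converged, iter = x$iter)
}

#' @export
tidy.cil_fit <- function(x, ...) {
  tibble(term = c("(corrected proportion)", "cil_slope"),
         estimate = c(x$beta0, x$beta1), std.error = x$se,
         p.value = c(NA_real_, x$p_value))
}

#' @export
glance.cil_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, p.value = x$p_value,
         df.residual = x$df_residual, n_plots = x$n_plots,
         cil_center = x$cil_center)
}

#' @export
tidy.regional_modes <- function(x, ...) x$estimates

#' @export
tidy.region_comparison <- function(x, ...) x$pairs

#' @export
tidy.model_ladder <- function(x, ...) {
  as_tibble(x) |>
    mutate(terms = vapply(.data$terms, paste, "", collapse = " + "))
}

#' @export
tidy.stepwise_fit <- function(x, ...) x$trace

#' @export
logLik.hazard_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, class = "logLik")
}
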