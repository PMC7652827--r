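#' The standard model ladder for tree-mortality risk factors
#'
#' The named set of nested model specifications used to rank risk factors:
#' the full model with tree-level terms (relative growth, diameter and its
#' square) and species-level terms (maximum size, mean growth, wood density,
#' water-deficit affiliation), every single-factor exclusion, the
#' group-only models, and the null model.
#'
#' @return A named list of character vectors of model terms.
#' @export
amazon_model_ladder <- function() {
  tree <- c("rel_growth", "D", "D2")
  spp <- c("max_d", "mean_growth", "wood_density", "wda")
  list(
    "Full model" = c(tree, spp),
    "Excluding WDA" = c(tree, setdiff(spp, "wda")),
    "Linear relationship with size" = c("rel_growth", "D", spp),
    "Excluding WD" = c(tree, setdiff(spp, "wood_density")),
    "Excluding stem size" = c("rel_growth", spp),
    "Excluding stem relative growth" = c("D", "D2", spp),
    "Species-level risk factors only" = spp,
    "Excluding species max size" = c(tree, setdiff(spp, "max_d")),
    "Excluding species mean growth" = c(tree, setdiff(spp, "mean_growth")),
    "Species mean growth only" = "mean_growth",
    "Tree-level risk factors only" = tree,
    "Relative growth only" = "rel_growth",
    "Null model" = character(0))
}

#' Fit and rank a ladder of hazard models by AIC
#'
#' Fits every specification on the same record set and reports the AIC
#' difference to the best model; models within 2 AIC units are considered
#' equivalent.
#'
#' @param records Survival records.
#' @param specs Named list of term vectors (default [amazon_model_ladder()]).
#' @param frailty,ties Passed to [fit_cox()].
#' @return An object of class `model_ladder`: a tibble sorted by ascending
#'   `delta_aic` with columns `model`, `terms` (list), `k`, `loglik`, `aic`,
#'   `delta_aic`, `converged`, and the fits in attribute `"fits"`. Failed
#'   fits are kept with `NA` AIC and noted in `note`.
#' @export
model_ladder <- function(records, specs = amazon_model_ladder(),
                         frailty = FALSE, ties = "efron") {
  fits <- purrr::map(specs, function(tm) {
    tryCatch(fit_cox(records, tm, frailty = frailty, ties = ties),
             error = function(e) e)
  })
  tab <- purrr::imap_dfr(fits, function(f, nm) {
    if (inherits(f, "error"))
      tibble(model = nm, k = NA_integer_, loglik = NA_real_, aic = NA_real_,
             converged = FALSE, note = conditionMessage(f))
    else
      tibble(model = nm, k = f$k, loglik = f$loglik, aic = f$aic,
             converged = f$converged, note = NA_character_)
  })
  tab$terms <- unname(specs)
  tab$delta_aic <- tab$aic - min(tab$aic, na.rm = TRUE)
  tab <- tab |> arrange(.data$delta_aic) |>
    select("model", "terms", "k", "loglik", "aic", "delta_aic",
           "converged", "note")
  attr(tab, "fits") <- fits
  class(tab) <- c("model_ladder", class(tab))
  tab
}

#' Bidirectional stepwise model selection by AIC
#'
#' Starting from the full specification, repeatedly evaluates every
#' single-term removal and addition (the quadratic size term is only added
#' when the linear one is present, and the linear one only removed after the
#' quadratic) and moves to the candidate with the lowest AIC until no move
#' improves it.
#'
#' @param records Survival records.
#' @param full Terms of the starting (full) model.
#' @param scope Terms that may enter the model (default `full`).
#' @param frailty,ties Passed to [fit_cox()].
#' @return A list of class `stepwise_fit`: `terms` (selected), `fit` (its
#'   [fit_cox()] result) and `trace`, a tibble of every candidate AIC
#'   evaluated per step.
#' @export
stepwise_aic <- function(records, full = .term_names, scope = full,
                         frailty = FALSE, ties = "efron") {
  aic_of <- function(tm) fit_cox(records, tm, frailty = frailty,
                                 ties = ties)$aic
  current <- full
  cur_aic <- aic_of(current)
  trace <- list(tibble(step = 0L, move = "<start>",
                       terms = paste(current, collapse = "+"),
                       aic = cur_aic))
  step_i <- 0L
  repeat {
    step_i <- step_i + 1L
    cand <- list()
    for (tm in current) {
      if (tm == "D" && "D2" %in% current) next
      cand[[paste0("- ", tm)]] <- setdiff(current, tm)
    }
    for (tm in setdiff(scope, current)) {
      if (tm == "D2" && !"D" %in% current) next
      cand[[paste0("+ ", tm)]] <- c(current, tm)
    }
    if (!length(cand)) break
    aics <- vapply(cand, aic_of, 0)
    trace[[length(trace) + 1]] <- tibble(
      step = step_i, move = names(cand),
      terms = vapply(cand, paste, "", collapse = "+"), aic = unname(aics))
    if (min(aics) < cur_aic - 1e-8) {
      best <- which.min(aics)
      current <- cand[[best]]
      cur_aic <- aics[best]
    } else break
  }
  # a greedy path can stall above the null model; restart from it if so
  null_aic <- aic_of(character(0))
  if (null_aic < cur_aic - 1e-8) {
    current <- character(0)
    cur_aic <- null_aic
    repeat {
      cand <- list()
      for (tm in setdiff(scope, current)) {
        if (tm == "D2" && !"D" %in% current) next
        cand[[paste0("+ ", tm)]] <- c(current, tm)
      }
      if (!length(cand)) break
      aics <- vapply(cand, aic_of, 0)
      if (min(aics) < cur_aic - 1e-8) {
        current <- cand[[which.min(aics)]]
        cur_aic <- min(aics)
      } else break
    }
  }
  structure(list(terms = current,
                 fit = fit_cox(records, current, frailty = frailty,
                               ties = ties),
                 aic = cur_aic, trace = bind_rows(trace)),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat("Stepwise AIC selection\nselected:",
      if (length(x$terms)) paste(x$terms, collapse = " + ") else "(null)",
      sprintf("\nAIC = %.2f after %d evaluations\n", x$aic, nrow(x$trace)))
  invisible(x)
}

#' Mode-specific hazard fits
#'
#' Refits the risk model separately for standing and for broken/uprooted
#' deaths: for each target mode, deaths of the other mode (and deaths with
#' unassessed mode) are treated as censored at their death time, giving
#' cause-specific hazards.
#'
#' @param records Survival records with a `mode` column on events.
#' @param terms,frailty,ties Passed to [fit_cox()].
#' @return A named list of class `mode_fits` with elements `standing` and
#'   `broken_uprooted` (each a `hazard_fit`, or `NULL` with a message when a
#'   mode has no events).
#' @export
fit_by_mode <- function(records, terms = .term_names, frailty = FALSE,
                        ties = "efron") {
  fit_one <- function(target) {
    rec <- records |>
      mutate(event = as.integer(.data$event == 1 &
                                  !is.na(.data$mode) & .data$mode == target))
    if (!any(rec$event == 1)) {
      inform(sprintf("no %s deaths: fit skipped", target))
      return(NULL)
    }
    fit_cox(rec, terms, frailty = frailty, ties = ties)
  }
  structure(list(standing = fit_one("standing"),
                 broken_uprooted = fit_one("broken_uprooted")),
            class = "mode_fits")
}
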