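# design matrix for a set of hazard-model terms
build_design <- function(records, terms) {
  if ("D2" %in% terms && !"D" %in% terms)
    abort("the quadratic size term requires the linear term",
          class = "canopyhazard_validation_error")
  bad <- setdiff(terms, names(records))
  if (length(bad))
    abort(paste0("unknown model term(s): ", paste(bad, collapse = ", ")),
          class = "canopyhazard_validation_error")
  X <- as.matrix(records[, terms, drop = FALSE])
  if (length(terms)) {
    v <- apply(X, 2, var)
    if (any(v == 0, na.rm = TRUE))
      abort(paste0("term(s) with zero variance: ",
                   paste(terms[v == 0], collapse = ", ")),
            class = "canopyhazard_validation_error")
  }
  storage.mode(X) <- "double"
  X
}

# single evaluation of the engine on pre-sorted data
engine_eval <- function(s, clust, nclust, beta, b, ties, want_info = TRUE) {
  cox_engine_eval(s$time, s$status, s$X, clust, nclust, beta, b, s$offset,
                  identical(ties, "efron"), want_info, s$start, s$rem_ord)
}

# records either carry a duration (`time_at_risk`) or a counting-process
# (start_time, stop_time] interval per row
sort_for_engine <- function(records, terms, offset = NULL) {
  counting <- "stop_time" %in% names(records)
  time <- if (counting) records$stop_time else records$time_at_risk
  start <- if (counting) records$start_time else numeric(0)
  status <- as.integer(records$event)
  if (any(!is.finite(time)))
    abort("non-finite follow-up time", class = "canopyhazard_validation_error")
  if (counting) {
    if (any(start >= time))
      abort("interval start must precede its end",
            class = "canopyhazard_validation_error")
  } else if (any(time <= 0)) {
    abort("non-positive time at risk",
          class = "canopyhazard_validation_error")
  }
  ord <- order(-time)
  X <- build_design(records, terms)[ord, , drop = FALSE]
  if (any(!is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)[1, 1]
    abort(sprintf("non-finite linear predictor (record %s)",
                  records$tree_id[ord[bad]]),
          class = "canopyhazard_numeric_error")
  }
  start <- if (counting) start[ord] else numeric(0)
  rem_ord <- if (counting) order(-start) - 1L else integer(0)
  list(time = time[ord], status = status[ord], X = X,
       start = start, rem_ord = rem_ord,
       plot = records$plot_id[ord],
       offset = if (is.null(offset)) numeric(length(time)) else offset[ord],
       ord = ord)
}

#' Cox partial log-likelihood
#'
#' Evaluates the partial log-likelihood of a proportional-hazards model at a
#' given coefficient vector, with Efron or Breslow handling of tied death
#' times. Per-plot frailty values, if supplied, enter the linear predictor as
#' offsets.
#'
#' @param records Survival records from [assemble_survival_records()] (needs
#'   `time_at_risk`, `event`, the term columns and `plot_id`).
#' @param terms Character vector of model terms (subset of `rel_growth`,
#'   `D`, `D2`, `max_d`, `mean_growth`, `wood_density`, `wda`); empty for
#'   the null model.
#' @param beta Coefficient vector matching `terms`.
#' @param frailty Optional named numeric vector of per-plot log-hazard
#'   offsets.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return The partial log-likelihood (a scalar).
#' @export
cox_partial_loglik <- function(records, terms = character(), beta = numeric(),
                               frailty = NULL, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (length(beta) != length(terms))
    abort("beta must match terms", class = "canopyhazard_validation_error")
  if (!nrow(records)) abort("no records", class = "canopyhazard_validation_error")
  if (!any(records$event == 1)) {
    warn("all records censored: partial log-likelihood is 0")
    return(0)
  }
  offset <- NULL
  if (!is.null(frailty)) offset <- unname(frailty[records$plot_id])
  s <- sort_for_engine(records, terms, offset)
  eta <- drop(s$X %*% beta) + s$offset
  if (any(!is.finite(eta))) {
    bad <- records$tree_id[s$ord[which(!is.finite(eta))[1]]]
    abort(sprintf("non-finite linear predictor (record %s)", bad),
          class = "canopyhazard_numeric_error")
  }
  engine_eval(s, integer(0), 0L, beta, numeric(0), ties,
              want_info = FALSE)$loglik
}

# Newton-Raphson with step halving on the (optionally penalized) partial
# likelihood; theta is the frailty variance, Inf meaning no penalty/frailty
newton_cox <- function(s, theta = NULL, clust = integer(0), nclust = 0L,
                       ties = "efron", beta0 = NULL, b0 = NULL,
                       tol = 1e-9, max_iter = 50) {
  p <- ncol(s$X)
  q <- nclust
  beta <- beta0 %||% numeric(p)
  b <- b0 %||% numeric(q)
  pen <- function(ev, beta, b) {
    ll <- ev$loglik
    if (q > 0) ll <- ll - sum(b^2) / (2 * theta)
    ll
  }
  ev <- engine_eval(s, clust, nclust, beta, b, ties)
  ll <- pen(ev, beta, b)
  if (p + q == 0) {
    return(list(beta = beta, b = b, loglik = ev$loglik, pen_loglik = ll,
                grad = ev$grad, info = ev$info, converged = TRUE, iter = 0L,
                grad_norm = 0, nevent = ev$nevent))
  }
  converged <- FALSE
  iter <- 0
  grad_norm <- NA_real_
  while (iter < max_iter) {
    iter <- iter + 1
    g <- ev$grad
    H <- ev$info
    if (q > 0) {
      g[p + seq_len(q)] <- g[p + seq_len(q)] - b / theta
      diag(H)[p + seq_len(q)] <- diag(H)[p + seq_len(q)] + 1 / theta
    }
    grad_norm <- sqrt(sum(g^2))
    step <- tryCatch(solve(H + diag(1e-10, nrow(H)), g),
                     error = function(e)
                       abort("singular information matrix (possible perfect separation)",
                             class = "canopyhazard_numeric_error"))
    fac <- 1
    repeat {
      beta_new <- beta + fac * step[seq_len(p)]
      b_new <- if (q > 0) b + fac * step[p + seq_len(q)] else b
      ev_new <- engine_eval(s, clust, nclust, beta_new, b_new, ties)
      ll_new <- pen(ev_new, beta_new, b_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      fac <- fac / 2
      if (fac < 1e-8) { ll_new <- ll; beta_new <- beta; b_new <- b
                        ev_new <- ev; break }
    }
    done <- abs(ll_new - ll) < tol * (abs(ll) + 1e-8)
    beta <- beta_new; b <- b_new; ev <- ev_new
    if (done) { converged <- TRUE; ll <- ll_new; break }
    ll <- ll_new
  }
  list(beta = beta, b = b, loglik = ev$loglik, pen_loglik = ll,
       grad = ev$grad, info = ev$info, converged = converged, iter = iter,
       grad_norm = grad_norm, nevent = ev$nevent)
}

# Laplace-approximate marginal log-likelihood profile in theta
laplace_marginal <- function(fit, theta, p, q) {
  Hbb <- fit$info[p + seq_len(q), p + seq_len(q), drop = FALSE]
  K <- Hbb + diag(1 / theta, q)
  ld <- determinant(K, logarithm = TRUE)$modulus
  fit$loglik - sum(fit$b^2) / (2 * theta) - q / 2 * log(theta) - 0.5 * ld
}

#' Fit a Cox proportional-hazards model with optional plot frailty
#'
#' Maximises the partial likelihood by Newton-Raphson (relative
#' log-likelihood tolerance 1e-9, at most 50 iterations, step-halving on
#' overshoot). With `frailty = TRUE` a shared per-plot random intercept with
#' log-normal distribution (mean 1 on the hazard scale) is estimated by
#' penalized partial likelihood, the frailty variance `theta` being chosen
#' by maximising the Laplace-approximate marginal likelihood profile;
#' standard errors come from the observed (penalized) information. AIC is
#' `-2*loglik + 2*k` with `k` the number of fixed-effect terms plus one when
#' `theta` is estimated; for frailty fits the marginal likelihood is used.
#'
#' @inheritParams cox_partial_loglik
#' @param frailty Estimate a per-plot random effect (default `FALSE`).
#' @param theta Fix the frailty variance instead of estimating it
#'   (optional).
#' @param theta_max Upper bound of the profile search (default 25).
#' @return An object of class `hazard_fit` with coefficients, standard
#'   errors, per-term Wald chi-squared, log-likelihoods, AIC, the estimated
#'   frailty variance and per-plot frailty values, counts and convergence
#'   diagnostics. Supports [tidy()], [glance()] and [autoplot()].
#' @export
fit_cox <- function(records, terms = .term_names, frailty = FALSE,
                    ties = c("efron", "breslow"), theta = NULL,
                    theta_max = 25) {
  ties <- match.arg(ties)
  if (!any(records$event == 1))
    abort("no events in the records", class = "canopyhazard_validation_error")
  s <- sort_for_engine(records, terms)
  p <- ncol(s$X)
  n <- length(s$time)

  if (!frailty) {
    fit <- newton_cox(s, ties = ties)
    ll0 <- engine_eval(s, integer(0), 0L, numeric(p), numeric(0), ties,
                       FALSE)$loglik
    var_beta <- if (p > 0) solve(fit$info) else matrix(0, 0, 0)
    theta_hat <- 0
    b_hat <- NULL
    loglik_used <- fit$loglik
    k <- p
  } else {
    plots <- sort(unique(s$plot))
    clust <- match(s$plot, plots) - 1L
    q <- length(plots)
    profile_fit <- function(th, start = NULL) {
      newton_cox(s, theta = th, clust = clust, nclust = q, ties = ties,
                 beta0 = start$beta, b0 = start$b)
    }
    if (is.null(theta)) {
      last <- NULL
      obj <- function(lth) {
        f <- profile_fit(exp(lth), last)
        last <<- f
        laplace_marginal(f, exp(lth), p, q)
      }
      # coarse grid then golden-section refinement
      grid <- log(c(1e-4, 0.01, 0.05, 0.15, 0.4, 1, 2.5, 6, theta_max))
      vals <- vapply(grid, obj, 0)
      i <- which.max(vals)
      lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
      opt <- optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-3)
      theta_hat <- exp(opt$maximum)
    } else theta_hat <- theta
    fit <- profile_fit(theta_hat)
    marg <- laplace_marginal(fit, theta_hat, p, q)
    Hpen <- fit$info
    diag(Hpen)[p + seq_len(q)] <- diag(Hpen)[p + seq_len(q)] + 1 / theta_hat
    var_all <- solve(Hpen)
    var_beta <- var_all[seq_len(p), seq_len(p), drop = FALSE]
    b_hat <- setNames(fit$b, plots)
    loglik_used <- marg
    k <- p + if (is.null(theta)) 1 else 0
    ll0 <- engine_eval(s, integer(0), 0L, numeric(p), numeric(0), ties,
                       FALSE)$loglik
  }

  se <- if (p > 0) sqrt(diag(var_beta)) else numeric(0)
  beta <- setNames(fit$beta, terms)
  chisq <- if (p > 0) (beta / se)^2 else numeric(0)
  structure(list(
    coefficients = beta, se = setNames(se, terms),
    chisq = setNames(chisq, terms),
    p_value = setNames(pchisq(chisq, 1, lower.tail = FALSE), terms),
    var = var_beta,
    loglik = loglik_used, partial_loglik = fit$loglik, loglik_null = ll0,
    aic = -2 * loglik_used + 2 * k, k = k,
    theta = if (frailty) theta_hat else 0, frailty = b_hat,
    n = n, nevent = fit$nevent, terms = terms, ties = ties,
    converged = fit$converged, iter = fit$iter, grad_norm = fit$grad_norm),
    class = "hazard_fit")
}

#' @export
print.hazard_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Cox proportional-hazards fit (%s ties)%s\n", x$ties,
              if (x$theta > 0) sprintf(", plot frailty theta = %.3f", x$theta)
              else ""))
  cat(sprintf("n = %d, events = %d, loglik = %.3f, AIC = %.2f%s\n",
              x$n, x$nevent, x$loglik, x$aic,
              if (!x$converged) " (NOT converged)" else ""))
  if (length(x$coefficients)) {
    print(data.frame(coef = signif(x$coefficients, digits),
                     se = signif(x$se, digits),
                     chisq = signif(x$chisq, digits),
                     p = signif(x$p_value, digits)))
  } else cat("(null model)\n")
  invisible(x)
}

#' Likelihood-ratio chi-squared per term
#'
#' Refits the model dropping one term at a time (respecting the D/D^2
#' hierarchy) and reports `2 * (loglik_full - loglik_reduced)` for each term,
#' a likelihood-ratio counterpart to the Wald chi-squared in the fit.
#'
#' @param records Survival records.
#' @param fit A [fit_cox()] result on those records.
#' @return A tibble with `term`, `chisq_wald`, `chisq_lr`.
#' @export
term_lr_chisq <- function(records, fit) {
  purrr::map_dfr(fit$terms, function(tm) {
    drop <- if (tm == "D") c("D", "D2") else tm
    red <- setdiff(fit$terms, drop)
    f2 <- fit_cox(records, red, frailty = !is.null(fit$frailty),
                  ties = fit$ties)
    tibble(term = tm, chisq_wald = fit$chisq[[tm]],
           chisq_lr = 2 * (fit$partial_loglik - f2$partial_loglik))
  })
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing term `j` on
#' the remaining terms; values above 10 indicate problematic collinearity.
#' Exact collinearity yields `Inf`.
#'
#' @param records Survival records (or any data frame with the term columns).
#' @param terms Model terms (>= 2).
#' @return A tibble with `term`, `vif`, `flagged` (`vif > 10`).
#' @export
vif <- function(records, terms = .term_names) {
  if (length(terms) < 2)
    abort("need at least two terms", class = "canopyhazard_validation_error")
  X <- as.matrix(records[, terms, drop = FALSE])
  if (nrow(X) <= length(terms))
    abort("need more records than terms",
          class = "canopyhazard_validation_error")
  v <- vapply(seq_along(terms), function(j) {
    fit <- lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) /
      sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  tibble(term = terms, vif = v, flagged = v > 10)
}
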