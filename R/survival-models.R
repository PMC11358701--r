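#' Fit one candidate parametric distribution to pseudo-IPD
#'
#' Right-censored maximum-likelihood fit of a single distribution family via
#' [flexsurv::flexsurvreg()], with AIC/BIC bookkeeping. Non-convergence is
#' reported as a flagged fit rather than an error so that model selection can
#' exclude it with a log entry.
#'
#' @param ipd A [pseudo_ipd()] with at least 10 records and at least 1 event.
#' @param distribution One of [supported_distributions()].
#' @return A `parametric_fit`: list with `distribution`, `params` (natural
#'   scale), `loglik`, `aic`, `bic`, `n`, `n_events`, `converged`, and the
#'   underlying `flexsurvreg` object as `fit`.
#' @export
fit_distribution <- function(ipd, distribution) {
  stopifnot(inherits(ipd, "pseudo_ipd"))
  if (nrow(ipd) < 10) stop("need at least 10 records to fit", call. = FALSE)
  if (sum(ipd$event) < 1) stop("need at least 1 event to fit", call. = FALSE)
  entry <- .dist_entry(distribution)
  dat <- data.frame(time = pmax(ipd$time, 1e-8), event = ipd$event)
  fit <- tryCatch(
    flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = dat,
                          dist = entry$flexsurv),
    error = function(e) e
  )
  if (inherits(fit, "error") || any(!is.finite(fit$res[, "est"]))) {
    return(structure(list(distribution = distribution, params = NULL,
                          loglik = NA_real_, aic = NA_real_, bic = NA_real_,
                          n = nrow(ipd), n_events = sum(ipd$event),
                          converged = FALSE, fit = NULL,
                          message = conditionMessage(
                            if (inherits(fit, "error")) fit else
                              simpleError("non-finite estimates"))),
                     class = "parametric_fit"))
  }
  params <- fit$res[, "est"]
  names(params) <- entry$pars   # flexsurv row order matches the registry
  k <- length(params)
  ll <- fit$loglik
  structure(list(distribution = distribution, params = params, loglik = ll,
                 aic = 2 * k - 2 * ll, bic = k * log(nrow(ipd)) - 2 * ll,
                 n = nrow(ipd), n_events = sum(ipd$event),
                 converged = TRUE, fit = fit),
            class = "parametric_fit")
}

#' @export
print.parametric_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("<parametric_fit> %s: DID NOT CONVERGE (%s)\n",
                x$distribution, x$message))
  } else {
    cat(sprintf("<parametric_fit> %s: loglik %.2f, AIC %.2f, BIC %.2f (n = %d, events = %d)\n",
                x$distribution, x$loglik, x$aic, x$bic, x$n, x$n_events))
    print(round(x$params, 4))
  }
  invisible(x)
}

#' Fit all seven candidate distributions
#'
#' @inheritParams fit_distribution
#' @param distributions Subset of [supported_distributions()] to fit.
#' @return Named list of `parametric_fit` objects.
#' @export
fit_all_distributions <- function(ipd, distributions = supported_distributions()) {
  fits <- lapply(distributions, function(d) fit_distribution(ipd, d))
  names(fits) <- distributions
  fits
}

#' Summarize a list of fits as a table
#'
#' @param fits Named list of `parametric_fit` objects.
#' @param selected Optional name of the selected distribution (flag column).
#' @return Data frame with distribution, parameters, loglik, AIC, BIC and a
#'   selected flag, sorted by AIC.
#' @export
fit_table <- function(fits, selected = NULL) {
  rows <- lapply(fits, function(f) {
    data.frame(
      distribution = f$distribution,
      params = if (f$converged)
        paste(sprintf("%s=%.4g", names(f$params), f$params), collapse = "; ")
      else NA_character_,
      loglik = f$loglik, aic = f$aic, bic = f$bic,
      converged = f$converged,
      selected = identical(f$distribution, selected)
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$aic), , drop = FALSE]
}

#' Survival function of a fitted distribution
#'
#' @param fit A converged `parametric_fit`.
#' @return A vectorized function `t -> S(t)` (t in months).
#' @export
surv_fn <- function(fit) {
  stopifnot(inherits(fit, "parametric_fit"), fit$converged)
  dist <- fit$distribution; params <- fit$params
  function(t) surv_prob(t, dist, params)
}

#' Select the best-fitting distribution under plausibility constraints
#'
#' Mirrors the selection rule used in trial-based economic models: order
#' converged fits by AIC and return the first one that passes two plausibility
#' filters on the model horizon grid — (i) an ordering filter against
#' companion curves (e.g. a PFS candidate may never exceed the OS curve), and
#' (ii) a tail filter rejecting extrapolations whose survival at the horizon
#' stays above a ceiling. Ties (AIC within `tie_tol`) are broken by BIC, then
#' by fewer parameters.
#'
#' @param fits Named list of `parametric_fit` objects.
#' @param horizon_months Horizon for the evaluation grid (months).
#' @param grid_months Spacing of the evaluation grid (months).
#' @param upper_fn Optional function `t -> S(t)` that the candidate must not
#'   exceed (beyond `tol`) anywhere on the grid (e.g. OS above PFS).
#' @param lower_fn Optional function the candidate must not fall below.
#' @param tail_ceiling Maximum allowed extrapolated survival at the horizon
#'   (default 0.40).
#' @param tol Ordering slack on the probability scale.
#' @param tie_tol AIC difference treated as a tie.
#' @return The selected `parametric_fit`, with an attribute `selection_log`
#'   (data frame of per-fit filter outcomes).
#' @export
select_best_fit <- function(fits, horizon_months, grid_months = 0.6899,
                            upper_fn = NULL, lower_fn = NULL,
                            tail_ceiling = 0.40, tol = 0.02, tie_tol = 1e-9) {
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (!length(conv)) stop("no converged fits to select from", call. = FALSE)
  grid <- seq(0, horizon_months, by = grid_months)
  up <- if (!is.null(upper_fn)) upper_fn(grid) else NULL
  lo <- if (!is.null(lower_fn)) lower_fn(grid) else NULL
  status <- lapply(conv, function(f) {
    s <- surv_fn(f)(grid)
    viol <- character(0)
    if (!is.null(up) && any(s > up + tol)) viol <- c(viol, "crosses above companion curve")
    if (!is.null(lo) && any(s < lo - tol)) viol <- c(viol, "falls below companion curve")
    if (s[length(s)] > tail_ceiling) {
      viol <- c(viol, sprintf("tail: S(horizon) = %.3f > ceiling %.2f",
                              s[length(s)], tail_ceiling))
    }
    viol
  })
  ok <- names(conv)[vapply(status, length, integer(1)) == 0]
  log_df <- data.frame(
    distribution = names(conv),
    aic = vapply(conv, `[[`, numeric(1), "aic"),
    bic = vapply(conv, `[[`, numeric(1), "bic"),
    passes = vapply(status, length, integer(1)) == 0,
    violations = vapply(status, paste, character(1), collapse = "; ")
  )
  if (!length(ok)) {
    stop("no fit passes the plausibility filters:\n",
         paste(sprintf("  %s: %s", log_df$distribution, log_df$violations),
               collapse = "\n"), call. = FALSE)
  }
  cand <- conv[ok]
  aic <- vapply(cand, `[[`, numeric(1), "aic")
  bic <- vapply(cand, `[[`, numeric(1), "bic")
  npar <- vapply(cand, function(f) length(f$params), numeric(1))
  best_aic <- min(aic)
  tied <- which(aic <= best_aic + tie_tol)
  pick <- tied[order(bic[tied], npar[tied])][1]
  out <- cand[[pick]]
  attr(out, "selection_log") <- log_df
  out
}

#' Select one distribution jointly across trial arms for an endpoint
#'
#' When the same endpoint is fitted in both arms, economic models commonly
#' unify the distribution family across arms so that differences between
#' strategies are not artifacts of differing extrapolation shapes. The family
#' is chosen by the sum of per-arm AICs among families converged in every arm
#' and passing the plausibility filters in every arm.
#'
#' @param fits_by_arm Named list (one element per arm) of named fit lists as
#'   returned by [fit_all_distributions()].
#' @param ... Passed to [select_best_fit()] filter arguments; `upper_fn` /
#'   `lower_fn` may be lists named by arm.
#' @inheritParams select_best_fit
#' @return Character scalar: the selected distribution family.
#' @export
select_unified_family <- function(fits_by_arm, horizon_months,
                                  grid_months = 0.6899,
                                  upper_fn = NULL, lower_fn = NULL,
                                  tail_ceiling = 0.40, tol = 0.02) {
  arms <- names(fits_by_arm)
  grid <- seq(0, horizon_months, by = grid_months)
  fam_ok <- function(fam) {
    for (a in arms) {
      f <- fits_by_arm[[a]][[fam]]
      if (is.null(f) || !isTRUE(f$converged)) return(NA_real_)
      s <- surv_fn(f)(grid)
      up <- if (is.list(upper_fn)) upper_fn[[a]] else upper_fn
      lo <- if (is.list(lower_fn)) lower_fn[[a]] else lower_fn
      if (!is.null(up) && any(s > up(grid) + tol)) return(NA_real_)
      if (!is.null(lo) && any(s < lo(grid) - tol)) return(NA_real_)
      if (s[length(s)] > tail_ceiling) return(NA_real_)
    }
    sum(vapply(arms, function(a) fits_by_arm[[a]][[fam]]$aic, numeric(1)))
  }
  fams <- Reduce(intersect, lapply(fits_by_arm, names))
  score <- vapply(fams, fam_ok, numeric(1))
  if (all(is.na(score))) {
    stop("no distribution family passes the filters in every arm", call. = FALSE)
  }
  fams[which.min(score)]
}

#' Apply a hazard ratio to a survival function
#'
#' Under proportional hazards a hazard ratio `hr` transforms a baseline
#' survival function `S(t)` into `S(t)^hr` (it scales the cumulative hazard
#' by `hr`).
#'
#' @param base A function `t -> S(t)`.
#' @param hr Positive hazard-ratio point estimate.
#' @return A function `t -> S(t)^hr`.
#' @export
#' @examples
#' f <- apply_hazard_ratio(function(t) rep(0.5, length(t)), 0.75)
#' f(1)  # 0.5^0.75 = 0.5946
apply_hazard_ratio <- function(base, hr) {
  stopifnot(is.function(base))
  if (!is.numeric(hr) || length(hr) != 1 || !is.finite(hr) || hr <= 0) {
    stop("hazard ratio must be a positive number", call. = FALSE)
  }
  function(t) base(t)^hr
}

#' Hazard ratio with confidence interval
#'
#' @param point Point estimate (> 0).
#' @param ci_low,ci_high Confidence bounds with `0 < ci_low <= point <= ci_high`.
#' @return Object of class `hazard_ratio`.
#' @export
hazard_ratio <- function(point, ci_low = point, ci_high = point) {
  stopifnot(ci_low > 0, ci_low <= point, point <= ci_high)
  structure(list(point = point, ci_low = ci_low, ci_high = ci_high),
            class = "hazard_ratio")
}

#' Bundle the three survival functions driving the Markov model
#'
#' @param P Function: first-line progression-free survival \eqn{P(t)}.
#' @param P2 Function: second progression-free survival \eqn{P_2(t)}.
#' @param S Function: overall survival \eqn{S(t)}.
#' @param arm Arm label.
#' @return Object of class `survival_function_set`.
#' @export
survival_function_set <- function(P, P2, S, arm = "arm") {
  stopifnot(is.function(P), is.function(P2), is.function(S))
  structure(list(P = P, P2 = P2, S = S, arm = arm),
            class = "survival_function_set")
}
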