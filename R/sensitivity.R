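#' Sensitivity-analysis parameter definitions
#'
#' Builds the parameter table driving the deterministic and probabilistic
#' sensitivity analyses from a [ce_parameters()] set. Each row carries the
#' baseline value, deterministic low/high bounds, the sampling distribution
#' family and a role. Bounds follow the standard rules — costs, body surface
#' area, creatinine clearance and weight vary by +/-25%; proportions and
#' utilities by +/-10% (capped at 1); the discount rate spans 0 to 0.08; the
#' overall-survival hazard ratio uses its confidence interval (0.57-0.97).
#' Sampling families: gamma for costs, beta for proportions and utilities,
#' normal for patient measures, lognormal (from the CI) for the hazard ratio,
#' uniform for the discount rate.
#'
#' @param params A [ce_parameters()] list.
#' @return Data frame of class `parameter_defs` with columns `name`,
#'   `baseline`, `low`, `high`, `distribution`, `role`.
#' @export
parameter_defs <- function(params = ce_parameters()) {
  rows <- list()
  add <- function(name, dist, role, low = NA_real_, high = NA_real_) {
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, baseline = as.numeric(params[[name]]),
      low = low, high = high, distribution = dist, role = role)
  }
  for (nm in names(params)[startsWith(names(params), "cost_")]) {
    add(nm, "gamma", "cost")
  }
  for (nm in c("disc_osimertinib_oc", "disc_platinum_oc", "disc_pemetrexed_oc",
               "disc_osimertinib_o", "disc_subsequent",
               "risk_anemia_o", "risk_neutropenia_o", "risk_thrombocytopenia_o",
               "risk_anemia_oc", "risk_neutropenia_oc",
               "risk_thrombocytopenia_oc")) {
    add(nm, "beta", "proportion")
  }
  for (nm in c("u_pfs", "u_pfs2", "u_pd",
               "du_anemia", "du_neutropenia", "du_thrombocytopenia")) {
    add(nm, "beta", "utility")
  }
  for (nm in c("weight", "bsa", "ccr")) add(nm, "normal", "clinical")
  add("discount", "uniform", "discount", low = 0, high = 0.08)
  add("hr_os", "lognormal", "clinical", low = 0.57, high = 0.97)
  out <- do.call(rbind, rows)
  db <- t(vapply(seq_len(nrow(out)), function(i) dsa_bounds(out[i, ]), numeric(2)))
  out$low <- db[, 1]; out$high <- db[, 2]
  class(out) <- c("parameter_defs", "data.frame")
  out
}

#' Deterministic bounds for one parameter
#'
#' Explicit bounds in the definition override the role-derived rules:
#' costs and patient measures (BSA, Ccr, weight) +/-25%; proportions and
#' utilities +/-10% capped at 1; discount rate 0 to 0.08.
#'
#' @param def One row of a [parameter_defs()] table (or a list with fields
#'   `baseline`, `low`, `high`, `role`).
#' @return Numeric `c(low, high)`.
#' @export
#' @examples
#' dsa_bounds(list(baseline = 7.08, low = NA, high = NA, role = "cost"))
dsa_bounds <- function(def) {
  b <- def$baseline
  if (!is.na(def$low) && !is.na(def$high)) return(c(def$low, def$high))
  switch(def$role,
    cost = ,
    clinical = c(0.75 * b, 1.25 * b),
    proportion = ,
    utility = c(0.9 * b, min(1.1 * b, 1)),
    discount = c(0, 0.08),
    stop("unknown parameter role '", def$role, "'", call. = FALSE)
  )
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-evaluates the full model with one parameter at its low and then its
#' high bound, all others at baseline, and ranks parameters by the spread of
#' the resulting ICERs. A model failure or an undefined ICER at a bound is
#' flagged on the entry rather than dropped.
#'
#' @param model A closure `function(overrides)` re-running the pipeline with
#'   the named parameter overrides applied and returning a `ce_result`.
#' @param defs A [parameter_defs()] table.
#' @return Data frame (class `tornado_table`) with `parameter`, `low`,
#'   `high`, `icer_at_low`, `icer_at_high`, `inmb_at_low`, `inmb_at_high`,
#'   `spread`, `flagged`, sorted by spread descending. The base-case
#'   `ce_result` is attached as attribute `base`.
#' @export
run_dsa <- function(model, defs) {
  base <- model(numeric(0))
  eval_at <- function(name, value) {
    ov <- stats::setNames(value, name)
    tryCatch(model(ov), error = function(e) e)
  }
  rows <- lapply(seq_len(nrow(defs)), function(i) {
    d <- defs[i, ]
    lo <- eval_at(d$name, d$low)
    hi <- eval_at(d$name, d$high)
    bad <- inherits(lo, "error") || inherits(hi, "error")
    icer_lo <- if (!inherits(lo, "error")) lo$icer else NA_real_
    icer_hi <- if (!inherits(hi, "error")) hi$icer else NA_real_
    data.frame(parameter = d$name, low = d$low, high = d$high,
               icer_at_low = icer_lo, icer_at_high = icer_hi,
               inmb_at_low = if (!inherits(lo, "error")) lo$inmb else NA_real_,
               inmb_at_high = if (!inherits(hi, "error")) hi$inmb else NA_real_,
               spread = abs(icer_hi - icer_lo),
               flagged = bad || is.na(icer_lo) || is.na(icer_hi))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread, out$parameter), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tornado_table", "data.frame")
  attr(out, "base") <- base
  out
}

#' Draw one probabilistic parameter set
#'
#' Samples every parameter from its assigned family with mean at baseline and
#' standard deviation `sd_frac` of baseline (the hazard ratio is drawn
#' lognormally with log-sd derived from its confidence interval; the discount
#' rate uniformly over its bounds). With `sd_frac = 0` every draw degenerates
#' to the baseline. Beta parameters whose moments are infeasible (mean too
#' close to 0 or 1 for the requested sd) fall back to a +/-10% uniform draw.
#'
#' @param defs A [parameter_defs()] table.
#' @param sd_frac Standard deviation as a fraction of baseline (default 0.1).
#' @return Named numeric vector of sampled values.
#' @export
sample_parameters <- function(defs, sd_frac = 0.1) {
  draw_one <- function(d) {
    m <- d$baseline
    sd <- sd_frac * abs(m)
    if (sd == 0 && !(d$distribution %in% c("lognormal", "uniform"))) return(m)
    switch(d$distribution,
      gamma = {
        shape <- (m / sd)^2
        stats::rgamma(1, shape = shape, rate = shape / m)
      },
      beta = {
        v <- sd^2
        if (m <= 0 || m >= 1 || v >= m * (1 - m)) {
          # infeasible moments: fall back to +/-10% uniform, clamped to [0,1]
          return(stats::runif(1, max(0, 0.9 * m), min(1, 1.1 * m)))
        }
        nu <- m * (1 - m) / v - 1
        stats::rbeta(1, shape1 = m * nu, shape2 = (1 - m) * nu)
      },
      normal = stats::rnorm(1, mean = m, sd = sd),
      lognormal = {
        sdlog <- if (sd_frac == 0) 0 else (log(d$high) - log(d$low)) / (2 * stats::qnorm(0.975))
        stats::rlnorm(1, meanlog = log(m), sdlog = sdlog)
      },
      uniform = if (sd_frac == 0) m else stats::runif(1, d$low, d$high),
      stop("unknown sampling distribution '", d$distribution, "'", call. = FALSE)
    )
  }
  stats::setNames(
    vapply(seq_len(nrow(defs)), function(i) draw_one(defs[i, ]), numeric(1)),
    defs$name)
}

#' Probabilistic sensitivity analysis
#'
#' Runs `n_reps` Monte-Carlo replicates: each replicate draws all parameters
#' jointly and independently via [sample_parameters()], re-evaluates the full
#' model, and records the incremental cost and QALY pair. The
#' cost-effectiveness acceptability curve is the fraction of replicates with
#' positive incremental net monetary benefit at each willingness-to-pay
#' value. Failed replicates are recorded and excluded.
#'
#' @inheritParams run_dsa
#' @param n_reps Number of Monte-Carlo replicates (default 1000).
#' @param wtp_grid Willingness-to-pay grid for the CEAC ($/QALY).
#' @param seed Integer seed.
#' @param sd_frac Passed to [sample_parameters()].
#' @return A `psa_result`: list with `samples` (data frame `rep`,
#'   `delta_cost`, `delta_qaly`, `cost_int`, `cost_comp`, `qaly_int`,
#'   `qaly_comp`), `ceac` (data frame `wtp`, `probability`), `n_reps`,
#'   `n_failed`.
#' @export
run_psa <- function(model, defs, n_reps = 1000,
                    wtp_grid = seq(0, 300000, by = 10000), seed = 1,
                    sd_frac = 0.1) {
  stopifnot(n_reps >= 1)
  set.seed(as.integer(seed))
  rows <- vector("list", n_reps)
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    draw <- sample_parameters(defs, sd_frac = sd_frac)
    res <- tryCatch(model(draw), error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      next
    }
    rows[[r]] <- data.frame(rep = r, delta_cost = res$delta_cost,
                            delta_qaly = res$delta_qaly,
                            cost_int = res$intervention$cost,
                            cost_comp = res$comparator$cost,
                            qaly_int = res$intervention$qaly,
                            qaly_comp = res$comparator$qaly)
  }
  samples <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  structure(list(samples = samples,
                 ceac = ceac_from_samples(samples$delta_cost,
                                          samples$delta_qaly, wtp_grid),
                 n_reps = n_reps, n_failed = n_failed),
            class = "psa_result")
}

#' Cost-effectiveness acceptability curve from PSA samples
#'
#' @param delta_cost,delta_qaly Incremental outcome samples.
#' @param wtp_grid Willingness-to-pay values.
#' @return Data frame `wtp`, `probability` where probability is the fraction
#'   of samples with `wtp * delta_qaly - delta_cost > 0`.
#' @export
ceac_from_samples <- function(delta_cost, delta_qaly, wtp_grid) {
  data.frame(
    wtp = wtp_grid,
    probability = vapply(wtp_grid, function(w) {
      mean(w * delta_qaly - delta_cost > 0)
    }, numeric(1))
  )
}

#' Probability cost-effective at one threshold
#'
#' @param psa A `psa_result`.
#' @param wtp Willingness-to-pay threshold.
#' @return Fraction of replicates with positive INMB at `wtp`.
#' @export
prob_cost_effective <- function(psa, wtp = 150000) {
  mean(wtp * psa$samples$delta_qaly - psa$samples$delta_cost > 0)
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d replicates (%d failed)\n", x$n_reps, x$n_failed))
  cat(sprintf("  delta cost: median $%s;  delta QALY: median %.4f\n",
              format(round(stats::median(x$samples$delta_cost), 2), big.mark = ","),
              stats::median(x$samples$delta_qaly)))
  cat(sprintf("  P(cost-effective at $150,000/QALY) = %.3f\n",
              prob_cost_effective(x, 150000)))
  invisible(x)
}
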