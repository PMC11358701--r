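#' Reconstruct pseudo individual-patient data from a digitized KM curve
#'
#' Implements the standard interval-wise reconstruction algorithm for
#' published Kaplan-Meier curves with numbers-at-risk tables (Guyot-type).
#' Within each risk-table interval the number censored is estimated from the
#' discrepancy between the coordinate-implied survival drop and the observed
#' change in numbers at risk, censoring times are spread uniformly over the
#' interval, event counts at each coordinate drop are chosen to keep the
#' running product-limit estimate on the digitized curve, and the censoring
#' count is iterated until the reconstructed number at risk matches the table
#' at the next risk time. Patients remaining after the last coordinate are
#' administratively censored at the end of follow-up.
#'
#' @param curve A [digitized_curve()].
#' @param use_total_events If `TRUE` and the curve carries `total_events`,
#'   calibrate the final-interval event count toward the reported total by
#'   converting end-of-follow-up censorings to events (or vice versa).
#'   Default `FALSE`: no global event-count calibration.
#' @return A [pseudo_ipd()] with exactly `n_risk[1]` records. The attribute
#'   `reconstruction_log` records per-interval censoring counts and any
#'   clamped (negative implied censoring) intervals.
#' @export
reconstruct_ipd <- function(curve, use_total_events = FALSE) {
  stopifnot(inherits(curve, "digitized_curve"))
  tt <- curve$coords$time
  ss <- pmin(pmax(curve$coords$surv, 0), 1)
  trisk <- curve$risk_table$time
  nrisk <- round(curve$risk_table$n_risk)
  K <- length(tt); J <- length(trisk)
  if (J < 2) stop("risk table needs at least 2 entries", call. = FALSE)

  t_end <- max(tt[K], trisk[J])
  ev_times <- numeric(0); cen_times <- numeric(0)
  log_rows <- list()

  n_run <- nrisk[1]
  km_run <- 1

  # coordinate indices in [trisk[j], trisk[j+1]) per interval; last is open-ended
  idx_in <- function(j) {
    hi <- if (j < J) trisk[j + 1] else Inf
    which(tt >= trisk[j] - 1e-9 & tt < hi - 1e-9)
  }

  # process one interval given a censoring count; returns updated state
  pass_interval <- function(ks, c_j, lo_t, hi_t, n0, km0) {
    cen_t <- if (c_j > 0) lo_t + seq_len(c_j) * (hi_t - lo_t) / (c_j + 1) else numeric(0)
    used <- logical(c_j)
    n <- n0; km <- km0
    d_all <- integer(0); d_at <- numeric(0)
    for (k in ks) {
      pre <- which(!used & cen_t < tt[k])
      used[pre] <- TRUE
      n <- n - length(pre)
      if (tt[k] <= 0 || n <= 0) next
      d_k <- round(n * (1 - ss[k] / km))
      d_k <- max(0L, min(as.integer(d_k), n))
      if (d_k > 0) {
        km <- km * (1 - d_k / n)
        n <- n - d_k
        d_all <- c(d_all, d_k); d_at <- c(d_at, tt[k])
      }
    }
    n <- n - sum(!used)
    list(n = n, km = km, events = rep(d_at, d_all), cens = cen_t)
  }

  for (j in seq_len(J - 1)) {
    ks <- idx_in(j)
    lo_t <- trisk[j]; hi_t <- trisk[j + 1]
    target <- nrisk[j + 1]
    # initial censoring guess from survival-implied vs observed attrition
    s_next <- if (length(idx_in(j + 1))) ss[idx_in(j + 1)[1]] else ss[max(c(ks, 1))]
    c_j <- if (km_run > 0) round(n_run * s_next / km_run) - target else n_run - target
    c_j <- max(0L, min(as.integer(c_j), n_run))
    best <- NULL; best_c <- c_j
    for (iter in 1:60) {
      res <- pass_interval(ks, c_j, lo_t, hi_t, n_run, km_run)
      gap <- res$n - target
      if (is.null(best) || abs(gap) < abs(best$n - target)) {
        best <- res; best_c <- c_j
      }
      if (gap == 0) break
      c_new <- max(0L, min(c_j + gap, n_run))
      if (c_new == c_j) break
      c_j <- c_new
    }
    clamped <- best$n != target
    if (clamped) {
      warning(sprintf(
        "interval %d (%.3g-%.3g months): risk table inconsistent with coordinates; censoring clamped (residual %d)",
        j, lo_t, hi_t, best$n - target), call. = FALSE)
    }
    log_rows[[j]] <- data.frame(interval = j, t_low = lo_t, t_high = hi_t,
                                n_censored = best_c, n_events = length(best$events),
                                clamped = clamped)
    ev_times <- c(ev_times, best$events)
    cen_times <- c(cen_times, best$cens)
    n_run <- best$n
    km_run <- best$km
  }

  # last interval: no further risk-table information, no interior censoring
  ks <- idx_in(J)
  res <- pass_interval(ks, 0L, trisk[J], t_end, n_run, km_run)
  ev_times <- c(ev_times, res$events)
  n_run <- res$n
  log_rows[[J]] <- data.frame(interval = J, t_low = trisk[J], t_high = t_end,
                              n_censored = 0L, n_events = length(res$events),
                              clamped = FALSE)

  if (isTRUE(use_total_events) && !is.null(curve$total_events)) {
    deficit <- curve$total_events - length(ev_times)
    if (deficit > 0 && n_run > 0) {
      extra <- min(deficit, n_run)
      ev_times <- c(ev_times, rep(t_end, extra))
      n_run <- n_run - extra
    } else if (deficit < 0) {
      # convert the latest reconstructed events back to end-of-follow-up censorings
      drop <- min(-deficit, length(ev_times))
      ord <- order(ev_times)
      keep <- ord[seq_len(length(ev_times) - drop)]
      n_run <- n_run + drop
      ev_times <- ev_times[sort(keep)]
    }
  }

  cen_times <- c(cen_times, rep(t_end, n_run))
  out <- pseudo_ipd(
    time = c(ev_times, cen_times),
    event = c(rep(1L, length(ev_times)), rep(0L, length(cen_times))),
    arm = curve$arm, endpoint = curve$endpoint
  )
  out <- out[order(out$time, -out$event), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pseudo_ipd", "data.frame")
  attr(out, "arm") <- curve$arm
  attr(out, "endpoint") <- curve$endpoint
  attr(out, "reconstruction_log") <- do.call(rbind, log_rows)
  out
}

#' Sup-norm distance between a digitized curve and the KM of reconstructed IPD
#'
#' Evaluates the product-limit estimate of `ipd` at each coordinate time of
#' `curve` and returns the maximum absolute difference from the digitized
#' survival values — the round-trip fidelity measure for reconstruction.
#'
#' @param curve A [digitized_curve()].
#' @param ipd A [pseudo_ipd()], typically from [reconstruct_ipd()].
#' @return Scalar sup-norm distance.
#' @export
km_sup_distance <- function(curve, ipd) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  sf <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  max(abs(sf(curve$coords$time) - curve$coords$surv))
}
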