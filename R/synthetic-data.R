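#' Specify a synthetic trial arm
#'
#' Defines the ground truth for one arm of a simulated trial endpoint: the
#' event-time distribution, the sample size, an exponential random-censoring
#' rate and an administrative follow-up cutoff. Times are in months.
#'
#' @param label Arm name, e.g. `"osimertinib"`.
#' @param distribution One of [supported_distributions()].
#' @param params Named parameter vector for `distribution` (months).
#' @param n_patients Number of patients (>= 1).
#' @param censor_rate Exponential random-censoring rate per month (0 = none).
#' @param admin_censor_time Administrative censoring time in months (> 0).
#' @return An object of class `arm_spec`.
#' @export
#' @examples
#' arm_spec("mono", "weibull", c(shape = 1.3, scale = 26.5), 278,
#'          censor_rate = 0.005, admin_censor_time = 36)
arm_spec <- function(label, distribution, params, n_patients,
                     censor_rate = 0, admin_censor_time = 60) {
  params <- .check_params(distribution, params)
  stopifnot(length(n_patients) == 1, n_patients >= 1, n_patients == round(n_patients),
            censor_rate >= 0, admin_censor_time > 0)
  structure(
    list(label = label, distribution = distribution, params = params,
         n_patients = as.integer(n_patients), censor_rate = censor_rate,
         admin_censor_time = admin_censor_time),
    class = "arm_spec"
  )
}

#' Simulate individual patient data for one arm
#'
#' Draws event times from the arm's distribution and censoring times from an
#' exponential distribution, truncates both at the administrative cutoff, and
#' returns right-censored records. This is the ground-truth generator that the
#' digitization and reconstruction stages are validated against.
#'
#' @param spec An [arm_spec()].
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return A `pseudo_ipd` data frame with columns `time` (months) and `event`
#'   (1 = event observed, 0 = censored), and attributes `arm` and `endpoint`.
#' @export
simulate_ipd <- function(spec, seed) {
  stopifnot(inherits(spec, "arm_spec"))
  set.seed(as.integer(seed))
  n <- spec$n_patients
  t_event <- rsurv(n, spec$distribution, spec$params)
  t_cens <- if (spec$censor_rate > 0) stats::rexp(n, rate = spec$censor_rate) else rep(Inf, n)
  time <- pmin(t_event, t_cens, spec$admin_censor_time)
  event <- as.integer(t_event <= t_cens & t_event <= spec$admin_censor_time)
  pseudo_ipd(time, event, arm = spec$label)
}

#' Construct a pseudo individual-patient-data object
#'
#' @param time Non-negative event/censoring times (months).
#' @param event 0/1 event indicators.
#' @param arm Arm label.
#' @param endpoint Endpoint label (`"PFS"`, `"PFS2"` or `"OS"`).
#' @return Data frame of class `pseudo_ipd`.
#' @export
pseudo_ipd <- function(time, event, arm = "arm", endpoint = "PFS") {
  stopifnot(length(time) == length(event), all(time >= 0),
            all(event %in% c(0L, 1L)))
  out <- data.frame(time = as.numeric(time), event = as.integer(event))
  attr(out, "arm") <- arm
  attr(out, "endpoint") <- endpoint
  class(out) <- c("pseudo_ipd", "data.frame")
  out
}

#' Render a digitized Kaplan-Meier curve from individual patient data
#'
#' Computes the product-limit estimate of `ipd`, takes its step coordinates
#' (prepending the (0, 1) origin), optionally perturbs them with truncated
#' Gaussian noise on the probability scale followed by an isotonic
#' non-increasing projection (a surrogate for figure-digitization error), and
#' tabulates exact numbers at risk at the requested times.
#'
#' @param ipd A [pseudo_ipd()] object.
#' @param risk_times Sorted times (months) for the numbers-at-risk table;
#'   should start at 0.
#' @param jitter_sd Standard deviation of the digitization noise on the
#'   probability scale (0 = exact coordinates).
#' @param seed Optional seed used only when `jitter_sd > 0`.
#' @param endpoint Endpoint label stored on the curve.
#' @return A `digitized_curve` object: list with `coords` (data frame
#'   `time`, `surv`), `risk_table` (data frame `time`, `n_risk`),
#'   `total_events`, `arm`, `endpoint`.
#' @export
render_km <- function(ipd, risk_times = NULL, jitter_sd = 0, seed = NULL,
                      endpoint = attr(ipd, "endpoint")) {
  stopifnot(inherits(ipd, "pseudo_ipd"), nrow(ipd) > 0)
  if (is.null(risk_times)) {
    risk_times <- seq(0, max(ipd$time), by = 3)
  }
  stopifnot(!is.unsorted(risk_times))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  drop_idx <- fit$n.event > 0
  times <- c(0, fit$time[drop_idx])
  surv <- c(1, fit$surv[drop_idx])
  if (jitter_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    noisy <- surv + stats::rnorm(length(surv), sd = jitter_sd)
    noisy[1] <- 1                       # the origin is read exactly
    noisy <- pmin(pmax(noisy, 0), 1)
    # isotonic non-increasing projection: fit -s as non-decreasing
    iso <- stats::isoreg(seq_along(noisy), -noisy)
    surv <- pmin(pmax(-iso$yf, 0), 1)
    surv[1] <- 1
  }
  n_risk <- vapply(risk_times, function(tt) sum(ipd$time >= tt), numeric(1))
  digitized_curve(
    coords = data.frame(time = times, surv = surv),
    risk_table = data.frame(time = risk_times, n_risk = n_risk),
    total_events = sum(ipd$event),
    arm = attr(ipd, "arm"), endpoint = endpoint
  )
}

#' Construct (and validate) a digitized Kaplan-Meier curve object
#'
#' @param coords Data frame with columns `time` (strictly increasing, first
#'   row at 0) and `surv` (non-increasing probabilities in `[0,1]`, first 1).
#' @param risk_table Data frame with columns `time` and `n_risk`
#'   (non-increasing counts).
#' @param total_events Optional observed event count.
#' @param arm,endpoint Labels.
#' @return Object of class `digitized_curve`.
#' @export
digitized_curve <- function(coords, risk_table, total_events = NULL,
                            arm = "arm", endpoint = "PFS") {
  stopifnot(is.data.frame(coords), all(c("time", "surv") %in% names(coords)),
            is.data.frame(risk_table), all(c("time", "n_risk") %in% names(risk_table)))
  if (coords$time[1] != 0 || abs(coords$surv[1] - 1) > 1e-12) {
    stop("first coordinate must be (0, 1)", call. = FALSE)
  }
  if (any(diff(coords$time) <= 0)) stop("coordinate times must be strictly increasing",
                                        call. = FALSE)
  if (any(coords$surv < -1e-12) || any(coords$surv > 1 + 1e-12)) {
    stop("survival probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(diff(coords$surv) > 1e-9)) stop("survival coordinates must be non-increasing",
                                          call. = FALSE)
  if (any(diff(risk_table$n_risk) > 0)) stop("numbers at risk must be non-increasing",
                                             call. = FALSE)
  structure(
    list(coords = coords, risk_table = risk_table,
         total_events = total_events, arm = arm, endpoint = endpoint),
    class = "digitized_curve"
  )
}

#' @export
print.digitized_curve <- function(x, ...) {
  cat(sprintf("<digitized_curve> %s / %s: %d coordinates, %d risk-table rows, n0 = %d\n",
              x$endpoint, x$arm, nrow(x$coords), nrow(x$risk_table),
              as.integer(x$risk_table$n_risk[1])))
  invisible(x)
}

#' Write / read digitized-curve and pseudo-IPD CSV files
#'
#' The curve dialect is two CSVs: coordinates (`time_months`, `survival`) and
#' a companion risk table (`time_months`, `n_risk`). Pseudo-IPD is one CSV
#' (`time_months`, `event`, `arm`).
#'
#' @param curve A `digitized_curve`.
#' @param coords_path,risk_path File paths for the two CSVs.
#' @return `write_curve` returns the paths invisibly; `read_curve` returns a
#'   `digitized_curve`.
#' @export
write_curve <- function(curve, coords_path, risk_path) {
  stopifnot(inherits(curve, "digitized_curve"))
  utils::write.csv(
    data.frame(time_months = curve$coords$time, survival = curve$coords$surv),
    coords_path, row.names = FALSE)
  utils::write.csv(
    data.frame(time_months = curve$risk_table$time, n_risk = curve$risk_table$n_risk),
    risk_path, row.names = FALSE)
  invisible(c(coords_path, risk_path))
}

#' @rdname write_curve
#' @param arm,endpoint Labels attached on read.
#' @param total_events Optional event count attached on read.
#' @export
read_curve <- function(coords_path, risk_path, arm = "arm", endpoint = "PFS",
                       total_events = NULL) {
  co <- utils::read.csv(coords_path)
  ri <- utils::read.csv(risk_path)
  digitized_curve(
    coords = data.frame(time = co$time_months, surv = co$survival),
    risk_table = data.frame(time = ri$time_months, n_risk = ri$n_risk),
    total_events = total_events, arm = arm, endpoint = endpoint
  )
}

#' @rdname write_curve
#' @param ipd A `pseudo_ipd`.
#' @param path CSV path.
#' @export
write_ipd <- function(ipd, path) {
  utils::write.csv(
    data.frame(time_months = ipd$time, event = ipd$event,
               arm = attr(ipd, "arm")),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_ipd <- function(path, endpoint = "PFS") {
  df <- utils::read.csv(path)
  pseudo_ipd(df$time_months, df$event,
             arm = if ("arm" %in% names(df)) df$arm[1] else "arm",
             endpoint = endpoint)
}
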