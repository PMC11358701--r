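#' Candidate parametric survival distributions
#'
#' The seven distribution families used throughout the package for simulating
#' event times and for extrapolating fitted survival curves: exponential,
#' Weibull, log-logistic, log-normal, gamma, generalized gamma and Gompertz.
#' Parameterizations follow the conventional survival-analysis forms as
#' implemented in \pkg{flexsurv} (Gompertz hazard \eqn{a e^{bt}} with the
#' shape \eqn{b} allowed negative; generalized gamma in the
#' location/scale/shape \eqn{(\mu, \sigma, Q)} form).
#'
#' @return Character vector of the supported distribution names.
#' @export
supported_distributions <- function() {
  names(.dist_registry)
}

# name -> flexsurvreg dist string, parameter names, r/p functions.
# All time arguments are in months.
.dist_registry <- list(
  exponential = list(
    flexsurv = "exp", pars = "rate",
    rfun = function(n, p) stats::rexp(n, rate = p[["rate"]]),
    sfun = function(q, p) stats::pexp(q, rate = p[["rate"]], lower.tail = FALSE)
  ),
  weibull = list(
    flexsurv = "weibull", pars = c("shape", "scale"),
    rfun = function(n, p) stats::rweibull(n, shape = p[["shape"]], scale = p[["scale"]]),
    sfun = function(q, p) stats::pweibull(q, shape = p[["shape"]], scale = p[["scale"]],
                                          lower.tail = FALSE)
  ),
  loglogistic = list(
    flexsurv = "llogis", pars = c("shape", "scale"),
    rfun = function(n, p) flexsurv::rllogis(n, shape = p[["shape"]], scale = p[["scale"]]),
    sfun = function(q, p) flexsurv::pllogis(q, shape = p[["shape"]], scale = p[["scale"]],
                                            lower.tail = FALSE)
  ),
  lognormal = list(
    flexsurv = "lnorm", pars = c("meanlog", "sdlog"),
    rfun = function(n, p) stats::rlnorm(n, meanlog = p[["meanlog"]], sdlog = p[["sdlog"]]),
    sfun = function(q, p) stats::plnorm(q, meanlog = p[["meanlog"]], sdlog = p[["sdlog"]],
                                        lower.tail = FALSE)
  ),
  gamma = list(
    flexsurv = "gamma", pars = c("shape", "rate"),
    rfun = function(n, p) stats::rgamma(n, shape = p[["shape"]], rate = p[["rate"]]),
    sfun = function(q, p) stats::pgamma(q, shape = p[["shape"]], rate = p[["rate"]],
                                        lower.tail = FALSE)
  ),
  gengamma = list(
    flexsurv = "gengamma", pars = c("mu", "sigma", "Q"),
    rfun = function(n, p) flexsurv::rgengamma(n, mu = p[["mu"]], sigma = p[["sigma"]],
                                              Q = p[["Q"]]),
    sfun = function(q, p) flexsurv::pgengamma(q, mu = p[["mu"]], sigma = p[["sigma"]],
                                              Q = p[["Q"]], lower.tail = FALSE)
  ),
  gompertz = list(
    flexsurv = "gompertz", pars = c("shape", "rate"),
    rfun = function(n, p) flexsurv::rgompertz(n, shape = p[["shape"]], rate = p[["rate"]]),
    sfun = function(q, p) flexsurv::pgompertz(q, shape = p[["shape"]], rate = p[["rate"]],
                                              lower.tail = FALSE)
  )
)

.dist_entry <- function(distribution) {
  entry <- .dist_registry[[distribution]]
  if (is.null(entry)) {
    stop("unknown distribution '", distribution, "'; supported: ",
         paste(supported_distributions(), collapse = ", "), call. = FALSE)
  }
  entry
}

.check_params <- function(distribution, params) {
  entry <- .dist_entry(distribution)
  pars <- entry$pars
  if (is.null(names(params))) {
    if (length(params) != length(pars)) {
      stop("distribution '", distribution, "' needs parameters ",
           paste(pars, collapse = ", "), call. = FALSE)
    }
    names(params) <- pars
  }
  missing <- setdiff(pars, names(params))
  if (length(missing)) {
    stop("missing parameter(s) for '", distribution, "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  params <- params[pars]
  # scale/rate-type parameters must be positive; location (mu, meanlog) and the
  # Gompertz/gengamma shapes may take any sign
  positive <- setdiff(pars, c("mu", "meanlog", "Q"))
  if (distribution == "gompertz") positive <- "rate"
  bad <- positive[vapply(positive, function(nm) !is.finite(params[[nm]]) || params[[nm]] <= 0,
                         logical(1))]
  if (length(bad)) {
    stop("parameter(s) must be positive for '", distribution, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  params
}

#' Evaluate a parametric survival function
#'
#' @param t Vector of times (months), non-negative.
#' @param distribution One of [supported_distributions()].
#' @param params Named numeric vector of parameters in the registry order.
#' @return Survival probabilities \eqn{S(t)} in `[0, 1]`.
#' @export
#' @examples
#' surv_prob(13.86, "exponential", c(rate = 0.05))  # ~0.5
surv_prob <- function(t, distribution, params) {
  entry <- .dist_entry(distribution)
  params <- .check_params(distribution, params)
  entry$sfun(t, as.list(params))
}

#' Draw random event times from a parametric survival distribution
#'
#' @inheritParams surv_prob
#' @param n Number of draws.
#' @return Numeric vector of event times (months).
#' @export
rsurv <- function(n, distribution, params) {
  entry <- .dist_entry(distribution)
  params <- .check_params(distribution, params)
  entry$rfun(n, as.list(params))
}
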