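# shared fixtures built in code

# survival-function set whose members return tabulated values at exact
# cycle boundaries (t in months = cycle * 21/30.4375)
grid_funcs <- function(P, P2, S, arm = "toy") {
  vec_fn <- function(v) {
    function(t) v[round(t / markovcea:::MONTHS_PER_CYCLE) + 1]
  }
  survival_function_set(vec_fn(P), vec_fn(P2), vec_fn(S), arm = arm)
}

no_mortality <- function() natural_mortality(annual_probability = 0)

# a consistent partitioned set of survival vectors over n cycles:
# exponential-family curves ordered P <= P2 <= S
ordered_surv_vectors <- function(n_cycles, r_p = 0.06, r_p2 = 0.04, r_s = 0.03) {
  tm <- (0:n_cycles) * markovcea:::MONTHS_PER_CYCLE
  list(P = exp(-r_p * tm), P2 = exp(-r_p2 * tm), S = exp(-r_s * tm))
}

# parameter set with SAE burden switched off (for closed-form QALY checks)
params_no_sae <- function(...) {
  ce_parameters(risk_anemia_o = 0, risk_neutropenia_o = 0,
                risk_thrombocytopenia_o = 0, risk_anemia_oc = 0,
                risk_neutropenia_oc = 0, risk_thrombocytopenia_oc = 0, ...)
}

# ground-truth parameters used for simulation-based checks, one per family
truth_params <- list(
  exponential = c(rate = 0.04),
  weibull = c(shape = 1.3, scale = 25),
  loglogistic = c(shape = 1.8, scale = 20),
  lognormal = c(meanlog = 3, sdlog = 0.8),
  gamma = c(shape = 1.6, rate = 0.07),
  gengamma = c(mu = 3, sigma = 0.7, Q = 0.9),
  gompertz = c(shape = 0.03, rate = 0.02)
)

# toy two-parameter model with analytic ICER: delta cost = a, delta QALY = b
toy_model <- function(base_a = 100000, base_b = 1, wtp = 150000) {
  function(overrides = numeric(0)) {
    a <- if ("a" %in% names(overrides)) overrides[["a"]] else base_a
    b <- if ("b" %in% names(overrides)) overrides[["b"]] else base_b
    compare_strategies(list(cost = a, qaly = 1 + b),
                       list(cost = 0, qaly = 1), wtp = wtp)
  }
}

toy_defs <- function(rows) {
  out <- do.call(rbind, lapply(rows, as.data.frame))
  class(out) <- c("parameter_defs", "data.frame")
  out
}
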