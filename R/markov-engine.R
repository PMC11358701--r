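CYCLE_DAYS <- 21
DAYS_PER_MONTH <- 30.4375
DAYS_PER_YEAR <- 365.25
MONTHS_PER_CYCLE <- CYCLE_DAYS / DAYS_PER_MONTH    # 0.68993...
YEARS_PER_CYCLE <- CYCLE_DAYS / DAYS_PER_YEAR      # 0.05749...

STATES <- c("PFS", "PFS2", "PD", "Death")

#' Number of 21-day cycles in a horizon of whole years
#'
#' @param years Horizon length in years (default 20).
#' @return Integer cycle count, `round(years * 365.25 / 21)` (348 for 20 y).
#' @export
horizon_cycles <- function(years = 20) {
  as.integer(round(years * DAYS_PER_YEAR / CYCLE_DAYS))
}

#' Background ("natural") mortality specification
#'
#' Either a constant annual death probability or an age-indexed life table.
#' The annual probability is converted to the 21-day cycle scale as
#' \eqn{p_{cycle} = 1 - (1 - p_{annual})^{21/365.25}}.
#'
#' @param mode `"constant"` or `"life_table"`.
#' @param annual_probability Annual death probability (constant mode).
#' @param life_table Data frame with columns `age` (years, ascending) and
#'   `annual_probability` (life-table mode).
#' @param baseline_age Age in years at model start (used to index the table).
#' @return Object of class `natural_mortality`.
#' @export
natural_mortality <- function(mode = c("constant", "life_table"),
                              annual_probability = 0.0197,
                              life_table = NULL, baseline_age = 65) {
  mode <- match.arg(mode)
  if (mode == "constant") {
    stopifnot(annual_probability >= 0, annual_probability <= 1)
  } else {
    stopifnot(is.data.frame(life_table),
              all(c("age", "annual_probability") %in% names(life_table)),
              !is.unsorted(life_table$age),
              all(life_table$annual_probability >= 0),
              all(life_table$annual_probability <= 1))
  }
  structure(list(mode = mode, annual_probability = annual_probability,
                 life_table = life_table, baseline_age = baseline_age),
            class = "natural_mortality")
}

#' Per-cycle natural mortality probability
#'
#' @param nm A [natural_mortality()].
#' @param cycle Cycle index (0-based); vectorized.
#' @return Per-cycle death probabilities.
#' @export
#' @examples
#' natural_mortality_per_cycle(natural_mortality(annual_probability = 0.02), 0)
#' # 1 - 0.98^(21/365.25) = 0.0011614
natural_mortality_per_cycle <- function(nm, cycle) {
  stopifnot(inherits(nm, "natural_mortality"))
  annual <- if (nm$mode == "constant") {
    rep(nm$annual_probability, length(cycle))
  } else {
    age <- nm$baseline_age + cycle * YEARS_PER_CYCLE
    idx <- findInterval(age, nm$life_table$age)
    over <- idx > nrow(nm$life_table)
    idx[idx < 1] <- 1
    idx[idx > nrow(nm$life_table)] <- nrow(nm$life_table)
    if (any(age > max(nm$life_table$age) + 1)) {
      # beyond the table: last row carried forward
      message("life table exhausted at age ", round(max(age), 1),
              "; last row carried forward")
    }
    nm$life_table$annual_probability[idx]
  }
  1 - (1 - annual)^(CYCLE_DAYS / DAYS_PER_YEAR)
}

#' Build the 4x4 transition matrix for one cycle
#'
#' Transition probabilities among \{PFS, PFS-2, PD, Death\} at cycle `t` from
#' the three survival functions:
#' \deqn{P_{PFS \to PFS2} = (P(t) - P(t+1))/P(t) - P_{Nat}}
#' \deqn{P_{PFS2 \to PD} = (P_2(t) - P_2(t+1))/P_2(t) - P_{Nat}}
#' \deqn{P_{PD \to Death} = (S(t) - S(t+1))/(S(t) - P_2(\cdot)) - P_{Nat}}
#' where the PD denominator uses \eqn{P_2(t+1)} (`"lead"`, the default) or
#' \eqn{P_2(t)} (`"lag"`). Deaths from PFS and PFS-2 equal the natural rate;
#' diagonals are the complements; Death is absorbing. Probabilities falling
#' outside `[0, 1]` are clipped, and if a row's off-diagonal mass exceeds 1 it
#' is rescaled so the row stays stochastic.
#'
#' Time is in cycles: the survival functions are evaluated at
#' `t * 21/30.4375` months.
#'
#' @param funcs A [survival_function_set()] (time argument in months).
#' @param p_nat Per-cycle natural mortality probability.
#' @param t Cycle index (0-based).
#' @param pd_denominator `"lead"` or `"lag"`.
#' @return 4x4 row-stochastic matrix with dimnames `STATES`.
#' @export
build_transition_matrix <- function(funcs, p_nat, t,
                                    pd_denominator = c("lead", "lag")) {
  pd_denominator <- match.arg(pd_denominator)
  m0 <- t * MONTHS_PER_CYCLE
  m1 <- (t + 1) * MONTHS_PER_CYCLE
  P0 <- funcs$P(m0); P1 <- funcs$P(m1)
  Q0 <- funcs$P2(m0); Q1 <- funcs$P2(m1)
  S0 <- funcs$S(m0); S1 <- funcs$S(m1)

  clip01 <- function(x) min(max(x, 0), 1)
  p_pfs_pfs2 <- if (P0 > 0) clip01((P0 - P1) / P0 - p_nat) else 0
  p_pfs2_pd <- if (Q0 > 0) clip01((Q0 - Q1) / Q0 - p_nat) else 0
  denom <- if (pd_denominator == "lead") S0 - Q1 else S0 - Q0
  p_pd_death <- if (denom > 0) clip01((S0 - S1) / denom - p_nat) else 0

  M <- matrix(0, 4, 4, dimnames = list(STATES, STATES))
  M["PFS", "PFS2"] <- p_pfs_pfs2
  M["PFS", "Death"] <- p_nat
  M["PFS2", "PD"] <- p_pfs2_pd
  M["PFS2", "Death"] <- p_nat
  M["PD", "Death"] <- p_pd_death
  M["Death", "Death"] <- 1
  for (s in c("PFS", "PFS2", "PD")) {
    off <- sum(M[s, ])
    if (off > 1) M[s, ] <- M[s, ] / off   # keep the row stochastic after clipping
    M[s, s] <- 1 - sum(M[s, setdiff(STATES, s)])
  }
  M
}

#' Run the four-state cohort trace
#'
#' Starts the whole cohort in PFS and iterates
#' `occupancy[t+1] = occupancy[t] %*% M(t)` over `n_cycles` 21-day cycles.
#'
#' @inheritParams build_transition_matrix
#' @param nm A [natural_mortality()].
#' @param n_cycles Number of cycles (>= 1), e.g. [horizon_cycles()].
#' @return A `markov_trace`: list with `occupancy` (matrix `(n_cycles+1) x 4`,
#'   rows t = 0..n_cycles), `incident_deaths` and `incident_progressions`
#'   (length `n_cycles`, inflow during cycle t), `arm`.
#' @export
run_trace <- function(funcs, nm, n_cycles,
                      pd_denominator = c("lead", "lag")) {
  stopifnot(inherits(funcs, "survival_function_set"), n_cycles >= 1)
  pd_denominator <- match.arg(pd_denominator)
  tms <- (0:n_cycles) * MONTHS_PER_CYCLE
  P <- funcs$P(tms); Q <- funcs$P2(tms); S <- funcs$S(tms)
  p_nat <- natural_mortality_per_cycle(nm, seq_len(n_cycles) - 1)

  # per-cycle transition probabilities, vectorized over t = 0..n_cycles-1;
  # same arithmetic, clipping and row-renormalization as
  # build_transition_matrix()
  i0 <- seq_len(n_cycles); i1 <- i0 + 1
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  p12 <- ifelse(P[i0] > 0, clip01((P[i0] - P[i1]) / P[i0] - p_nat), 0)
  p2pd <- ifelse(Q[i0] > 0, clip01((Q[i0] - Q[i1]) / Q[i0] - p_nat), 0)
  denom <- if (pd_denominator == "lead") S[i0] - Q[i1] else S[i0] - Q[i0]
  ppd <- ifelse(denom > 0, clip01((S[i0] - S[i1]) / denom - p_nat), 0)
  nat1 <- p_nat; nat2 <- p_nat
  off1 <- p12 + nat1
  scl <- off1 > 1
  p12[scl] <- p12[scl] / off1[scl]; nat1[scl] <- nat1[scl] / off1[scl]
  off2 <- p2pd + nat2
  scl <- off2 > 1
  p2pd[scl] <- p2pd[scl] / off2[scl]; nat2[scl] <- nat2[scl] / off2[scl]

  occ <- matrix(0, n_cycles + 1, 4, dimnames = list(NULL, STATES))
  occ[1, "PFS"] <- 1
  inc_death <- numeric(n_cycles)
  inc_prog <- numeric(n_cycles)
  for (t in seq_len(n_cycles)) {
    a <- occ[t, 1]; b <- occ[t, 2]; c_ <- occ[t, 3]; d <- occ[t, 4]
    occ[t + 1, 1] <- a * (1 - p12[t] - nat1[t])
    occ[t + 1, 2] <- b * (1 - p2pd[t] - nat2[t]) + a * p12[t]
    occ[t + 1, 3] <- c_ * (1 - ppd[t]) + b * p2pd[t]
    occ[t + 1, 4] <- d + a * nat1[t] + b * nat2[t] + c_ * ppd[t]
    inc_death[t] <- occ[t + 1, 4] - d
    inc_prog[t] <- a * p12[t]
  }
  structure(list(occupancy = occ, incident_deaths = inc_death,
                 incident_progressions = inc_prog, arm = funcs$arm,
                 n_cycles = n_cycles),
            class = "markov_trace")
}

#' @export
print.markov_trace <- function(x, ...) {
  n <- x$n_cycles
  cat(sprintf("<markov_trace> %s: %d cycles (%.1f years)\n", x$arm, n,
              n * YEARS_PER_CYCLE))
  show <- unique(pmin(c(0, 26, 52, 104, 174, 348, n), n)) + 1
  print(round(x$occupancy[show, , drop = FALSE], 4))
  invisible(x)
}

#' Export a trace as a data frame
#'
#' @param x A `markov_trace`.
#' @param ... Unused.
#' @return Data frame with cycle, state occupancies and incident deaths.
#' @export
as.data.frame.markov_trace <- function(x, ...) {
  data.frame(cycle = 0:x$n_cycles,
             pfs = x$occupancy[, "PFS"], pfs2 = x$occupancy[, "PFS2"],
             pd = x$occupancy[, "PD"], death = x$occupancy[, "Death"],
             incident_deaths = c(NA, x$incident_deaths))
}
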