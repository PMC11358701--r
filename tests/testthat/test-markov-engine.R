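test_that("natural mortality converts annual probabilities to the cycle scale", {
  expect_equal(natural_mortality_per_cycle(no_mortality(), 0), 0)
  nm <- natural_mortality(annual_probability = 0.02)
  expect_equal(natural_mortality_per_cycle(nm, 0),
               1 - 0.98^(21 / 365.25), tolerance = 1e-10)  # 0.0011614
  # a single-row life table behaves like constant mode
  lt1 <- natural_mortality("life_table",
                           life_table = data.frame(age = 65, annual_probability = 0.02),
                           baseline_age = 65)
  expect_equal(natural_mortality_per_cycle(lt1, c(0, 100, 300)),
               natural_mortality_per_cycle(nm, c(0, 100, 300)))
  # age indexing walks the table; beyond it the last row is carried forward
  lt <- natural_mortality("life_table",
                          life_table = data.frame(age = c(65, 70, 75),
                                                  annual_probability = c(0.01, 0.02, 0.05)),
                          baseline_age = 65)
  p <- natural_mortality_per_cycle(lt, c(0, horizon_cycles(6), horizon_cycles(11)))
  expect_equal(p, 1 - (1 - c(0.01, 0.02, 0.05))^(21 / 365.25))
})

test_that("transition matrices implement the printed equations with clipping", {
  fn <- grid_funcs(P = c(0.8, 0.72), P2 = c(0.9, 0.85), S = c(0.95, 0.93))
  M <- build_transition_matrix(fn, p_nat = 0, t = 0)
  expect_equal(M["PFS", "PFS2"], (0.8 - 0.72) / 0.8)           # 0.1
  expect_equal(M["PFS2", "PD"], (0.9 - 0.85) / 0.9)
  # "lead" denominator S(t) - P2(t+1); "lag" uses P2(t)
  expect_equal(M["PD", "Death"], (0.95 - 0.93) / (0.95 - 0.85))
  Mlag <- build_transition_matrix(fn, 0, 0, pd_denominator = "lag")
  expect_equal(Mlag["PD", "Death"], (0.95 - 0.93) / (0.95 - 0.9))
  # rows are stochastic, Death absorbing
  expect_equal(unname(rowSums(M)), rep(1, 4), tolerance = 1e-12)
  expect_equal(unname(M["Death", ]), c(0, 0, 0, 1))

  # no OS drop -> no PD deaths; negative formula values clip to 0
  fn2 <- grid_funcs(P = c(0.8, 0.8), P2 = c(0.9, 0.9), S = c(0.95, 0.95))
  M2 <- build_transition_matrix(fn2, p_nat = 0.004, t = 0)
  expect_equal(M2["PD", "Death"], 0)       # 0 - 0.004 clipped to 0
  expect_equal(M2["PFS", "PFS2"], 0)
  expect_equal(M2["PFS", "Death"], 0.004)  # natural mortality persists
  # degenerate denominator (S <= P2) zeroes the transition, never crashes
  fn3 <- grid_funcs(P = c(0.5, 0.4), P2 = c(0.9, 0.8), S = c(0.7, 0.6))
  expect_equal(build_transition_matrix(fn3, 0, 0, "lag")["PD", "Death"], 0)
})

test_that("run_trace reproduces explicit matrix products", {
  # identity chain: flat curves, no mortality -> occupancy never moves
  n <- 10
  v1 <- rep(1, n + 1)
  tr <- run_trace(grid_funcs(0.6 * v1, 0.8 * v1, 0.9 * v1), no_mortality(), n)
  expect_equal(tr$occupancy[n + 1, ], c(PFS = 1, PFS2 = 0, PD = 0, Death = 0))

  # 2-cycle hand example against brute-force matrix multiplication
  P <- c(1, 0.8, 0.6); P2 <- c(1, 0.92, 0.8); S <- c(1, 0.97, 0.9)
  fn <- grid_funcs(P, P2, S)
  nm <- natural_mortality(annual_probability = 0.0197)
  tr2 <- run_trace(fn, nm, 2)
  p_nat <- natural_mortality_per_cycle(nm, 0:1)
  occ <- c(1, 0, 0, 0)
  occ <- occ %*% build_transition_matrix(fn, p_nat[1], 0)
  expect_equal(unname(tr2$occupancy[2, ]), as.numeric(occ), tolerance = 1e-12)
  occ <- occ %*% build_transition_matrix(fn, p_nat[2], 1)
  expect_equal(unname(tr2$occupancy[3, ]), as.numeric(occ), tolerance = 1e-12)
})

test_that("traces conserve mass and death is monotone for random valid inputs", {
  set.seed(71)
  n <- horizon_cycles(20)
  expect_equal(n, 348)
  for (rep in 1:5) {
    r_s <- runif(1, 0.01, 0.04)
    v <- ordered_surv_vectors(n, r_p = r_s + runif(1, 0.02, 0.06),
                              r_p2 = r_s + runif(1, 0.005, 0.02), r_s = r_s)
    nm <- natural_mortality(annual_probability = runif(1, 0, 0.05))
    tr <- run_trace(grid_funcs(v$P, v$P2, v$S), nm, n)
    expect_lt(max(abs(rowSums(tr$occupancy) - 1)), 1e-9)
    expect_true(all(diff(tr$occupancy[, "Death"]) >= -1e-12))
    expect_true(all(tr$occupancy >= -1e-12))
    expect_equal(unname(tr$occupancy[1, ]), c(1, 0, 0, 0))
  }
})

test_that("with no background mortality the trace tracks the generating curves", {
  n <- horizon_cycles(20)
  # state-consistent configuration: first-line progression resolves quickly
  # relative to the later transitions, so state occupancies stay close to the
  # survival-curve partition and cohort mortality reproduces the OS input
  v <- ordered_surv_vectors(n, r_p = 3, r_p2 = 0.01, r_s = 0.008)
  for (dd in c("lead", "lag")) {
    tr <- run_trace(grid_funcs(v$P, v$P2, v$S), no_mortality(), n,
                    pd_denominator = dd)
    expect_lt(max(abs(tr$occupancy[, "Death"] - (1 - v$S))), 0.02)
  }

  # PFS occupancy always equals P(t) exactly, and incident deaths are the
  # per-cycle death increments
  v2 <- ordered_surv_vectors(n)
  tr2 <- run_trace(grid_funcs(v2$P, v2$P2, v2$S), no_mortality(), n)
  expect_lt(max(abs(tr2$occupancy[, "PFS"] - v2$P)), 1e-9)
  expect_equal(tr2$incident_deaths, diff(tr2$occupancy[, "Death"]))
  # when PFS and PFS-2 overlap heavily the equations under-propagate the
  # cohort, so model mortality can only lag the OS input, never outrun it
  expect_true(all(tr2$occupancy[, "Death"] <= 1 - v2$S + 1e-9))
})

test_that("horizon length changes trace length only", {
  v <- ordered_surv_vectors(400)
  fn <- grid_funcs(v$P, v$P2, v$S)
  nm <- natural_mortality(annual_probability = 0.0197)
  short <- run_trace(fn, nm, 100)
  long <- run_trace(fn, nm, 400)
  expect_equal(short$occupancy, long$occupancy[1:101, ])
})
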