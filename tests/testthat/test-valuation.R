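test_that("dosing rules reproduce reference-patient doses", {
  pp <- patient_profile()  # 70 kg, 1.86 m2, Ccr 70
  expect_equal(drug_dose_mg("per_m2", 500, pp), 930)     # pemetrexed
  expect_equal(drug_dose_mg("calvert", 5, pp), 475)      # carboplatin AUC 5
  expect_equal(drug_dose_mg("per_m2", 75, pp), 139.5)    # cisplatin
  expect_equal(drug_dose_mg("flat", 80, pp), 80)
  expect_equal(drug_dose_mg("per_kg", 15, pp), 1050)     # bevacizumab
  expect_error(drug_dose_mg("per_vial", 1, pp), "unknown dosing rule")
})

test_that("per-cycle drug and administration costs follow the price table", {
  # osimertinib with no discontinuation: 80 mg/day x 21 days x $7.08/mg
  p <- ce_parameters(disc_osimertinib_oc = 0, disc_pemetrexed_oc = 0,
                     disc_platinum_oc = 0)
  s <- ce_settings()
  sc <- strategy_state_costs("oc", p, s, n_cycles = 6)
  osi <- 80 * 21 * 7.08                      # 11894.40
  pem <- 930 * 0.32                          # 297.60
  carb <- 475 * 0.28                         # 133.00
  infusion_induction <- 132.16 + 28.47       # 160.63
  recurring <- 542.65 * 21 / 30.4375 + 114.54 * 21 / (3 * 30.4375)
  expect_equal(sc$pfs[1], osi + pem + carb + infusion_induction + recurring)
  # maintenance (cycle 5+): platinum dropped, single-agent infusion hour
  expect_equal(sc$pfs[6], osi + pem + 132.16 + recurring)

  # discontinuation scales each agent's expected cost
  p2 <- ce_parameters()
  sc2 <- strategy_state_costs("oc", p2, s, n_cycles = 6)
  expect_equal(sc2$pfs[1],
               osi * (1 - 0.4420) + pem * (1 - 0.7536) + carb * (1 - 0.2319) +
                 infusion_induction + recurring)
  # monotherapy arm: osimertinib only, no infusion
  sc3 <- strategy_state_costs("o", p2, s, n_cycles = 6)
  expect_equal(sc3$pfs[1], osi * (1 - 0.5527) + recurring)

  # second-line basket attenuates with the per-cycle discontinuation
  basket0 <- sc2$pfs2[1] - recurring
  expect_equal(sc2$pfs2[4] - recurring, basket0 * 0.97^3)
  # PD state carries best supportive care
  expect_equal(sc2$pd, rep(3006.28, 6))
  # one-time costs: EGFR testing plus expected SAE management
  sae <- 0.003 * 2053.86 + 0.01 * 1295.15 + 0 * 2252.54
  expect_equal(sc2$one_time, 1199.53 + sae)
  expect_error(ce_parameters(cost_osimertinib = -1), "non-negative")
})

test_that("accumulation matches closed forms", {
  n <- horizon_cycles(20)
  yrs <- 21 / 365.25
  # constant PFS occupancy, zero discount, no SAE: QALY = 0.71 * 348 * 21/365.25
  tr <- run_trace(grid_funcs(rep(1, n + 1), rep(1, n + 1), rep(1, n + 1)),
                  no_mortality(), n)
  p <- params_no_sae(discount = 0)
  out <- accumulate(tr, "o", p)
  expect_equal(out$qaly, 0.71 * n * yrs)  # 14.205

  # discounting: a flow one year out is divided by 1.03
  p3 <- params_no_sae(discount = 0.03)
  cycles_per_year <- 1 / yrs
  df_at_1y <- (1 + 0.03)^(-round(cycles_per_year) * yrs)
  expect_equal(100 * df_at_1y, 100 / 1.03, tolerance = 1e-3)

  # doubling every unit cost doubles the total cost (homogeneity)
  v <- ordered_surv_vectors(n)
  tr2 <- run_trace(grid_funcs(v$P, v$P2, v$S),
                   natural_mortality(annual_probability = 0.0197), n)
  base <- accumulate(tr2, "oc", ce_parameters())
  pd <- ce_parameters()
  for (nm in names(pd)[startsWith(names(pd), "cost_")]) pd[[nm]] <- 2 * pd[[nm]]
  doubled <- accumulate(tr2, "oc", pd)
  expect_equal(doubled$cost, 2 * base$cost, tolerance = 1e-12)
  expect_equal(doubled$qaly, base$qaly)
})

test_that("with all utilities at 1 QALYs equal discounted life expectancy", {
  n <- horizon_cycles(20)
  v <- ordered_surv_vectors(n)
  tr <- run_trace(grid_funcs(v$P, v$P2, v$S), no_mortality(), n)
  p <- params_no_sae(u_pfs = 1, u_pfs2 = 1, u_pd = 1)
  out <- accumulate(tr, "o", p)
  yrs <- 21 / 365.25
  df <- (1 + p$discount)^(-(0:(n - 1)) * yrs)
  alive <- 1 - tr$occupancy[1:n, "Death"]
  expect_equal(out$qaly, sum(df * alive) * yrs, tolerance = 1e-12)
})

test_that("totals are monotone in horizon and decreasing in discount rate", {
  v <- ordered_surv_vectors(400)
  fn <- grid_funcs(v$P, v$P2, v$S)
  nm <- natural_mortality(annual_probability = 0.0197)
  p <- ce_parameters()
  tr_short <- run_trace(fn, nm, 200)
  tr_long <- run_trace(fn, nm, 400)
  expect_lt(accumulate(tr_short, "oc", p)$cost, accumulate(tr_long, "oc", p)$cost)
  expect_lt(accumulate(tr_short, "oc", p)$qaly, accumulate(tr_long, "oc", p)$qaly)
  q <- sapply(c(0, 0.03, 0.08), function(r) {
    out <- accumulate(tr_long, "oc", ce_parameters(discount = r))
    c(out$cost, out$qaly)
  })
  expect_true(all(diff(q[1, ]) < 0) && all(diff(q[2, ]) < 0))
  # everything stays non-negative and finite
  expect_true(all(is.finite(q)) && all(q > 0))
})

test_that("the SAE swap flag exchanges the two arms' adverse-event burdens", {
  n <- 50
  v <- ordered_surv_vectors(n)
  tr <- run_trace(grid_funcs(v$P, v$P2, v$S), no_mortality(), n)
  p <- ce_parameters()
  plain_oc <- accumulate(tr, "oc", p, ce_settings(sae_swap = FALSE))
  swapped_oc <- accumulate(tr, "oc", p, ce_settings(sae_swap = TRUE))
  swapped_o <- accumulate(tr, "o", p, ce_settings(sae_swap = TRUE))
  plain_o <- accumulate(tr, "o", p, ce_settings(sae_swap = FALSE))
  # swapping moves the monotherapy SAE bundle onto the combination arm
  sae_o <- 0.17 * 2053.86 + 0.13 * 1295.15 + 0.07 * 2252.54
  sae_oc <- 0.003 * 2053.86 + 0.01 * 1295.15
  expect_equal(swapped_oc$cost - plain_oc$cost, sae_o - sae_oc)
  expect_equal(swapped_o$cost - plain_o$cost, sae_oc - sae_o)
})
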