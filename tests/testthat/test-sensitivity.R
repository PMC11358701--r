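test_that("deterministic bounds follow the role rules and explicit ranges", {
  expect_equal(dsa_bounds(list(baseline = 7.08, low = NA, high = NA, role = "cost")),
               c(5.31, 8.85))
  expect_equal(dsa_bounds(list(baseline = 0.71, low = NA, high = NA, role = "utility")),
               c(0.639, 0.781))
  # proportions near 1 are capped
  expect_equal(dsa_bounds(list(baseline = 0.95, low = NA, high = NA,
                               role = "proportion"))[2], 1)
  defs <- parameter_defs()
  hr <- defs[defs$name == "hr_os", ]
  expect_equal(c(hr$low, hr$high), c(0.57, 0.97))   # explicit CI overrides
  disc <- defs[defs$name == "discount", ]
  expect_equal(c(disc$low, disc$high), c(0, 0.08))
  bsa <- defs[defs$name == "bsa", ]
  expect_equal(c(bsa$low, bsa$high), c(1.86 * 0.75, 1.86 * 1.25))
})

test_that("tornado spreads match a closed-form toy model and flag inert inputs", {
  model <- toy_model(base_a = 100000, base_b = 1)
  defs <- toy_defs(list(
    list(name = "a", baseline = 1e5, low = 8e4, high = 1.2e5,
         distribution = "gamma", role = "cost"),
    list(name = "b", baseline = 1, low = 0.8, high = 1.25,
         distribution = "beta", role = "utility"),
    list(name = "inert", baseline = 5, low = 2, high = 9,
         distribution = "gamma", role = "cost")))
  tor <- run_dsa(model, defs)
  # ICER = a / b: spreads are |high - low| / b and a * |1/low - 1/high|
  expect_equal(tor$spread[tor$parameter == "a"], 40000)
  expect_equal(tor$spread[tor$parameter == "b"], 1e5 / 0.8 - 1e5 / 1.25)
  expect_equal(tor$spread[tor$parameter == "inert"], 0)
  expect_false(any(tor$flagged))
  # sorted by influence
  expect_equal(tor$parameter, c("b", "a", "inert"))
  expect_equal(attr(tor, "base")$icer, 1e5)
  # raising an intervention-only cost raises the ICER monotonically
  expect_gt(tor$icer_at_high[tor$parameter == "a"],
            tor$icer_at_low[tor$parameter == "a"])
})

test_that("parameter sampling matches its distribution specifications", {
  defs <- parameter_defs()
  set.seed(91)
  draws <- replicate(8000, sample_parameters(defs))
  rownames(draws) <- defs$name
  # gamma cost: mean within 1% of baseline, all positive
  osi <- draws["cost_osimertinib", ]
  expect_equal(mean(osi), 7.08, tolerance = 0.01)
  expect_equal(sd(osi), 0.708, tolerance = 0.05)
  expect_true(all(osi > 0))
  # beta utility: support respected, mean at baseline
  u <- draws["u_pfs", ]
  expect_true(all(u >= 0 & u <= 1))
  expect_equal(mean(u), 0.71, tolerance = 0.01)
  # lognormal hazard ratio: log-sd from the CI width
  hr <- draws["hr_os", ]
  expect_equal(median(hr), 0.75, tolerance = 0.02)
  expect_equal(sd(log(hr)), (log(0.97) - log(0.57)) / (2 * qnorm(0.975)),
               tolerance = 0.05)
  # uniform discount spans its bounds
  expect_true(all(draws["discount", ] >= 0 & draws["discount", ] <= 0.08))
  # degenerate point mass at zero (risk_thrombocytopenia_oc baseline 0)
  expect_true(all(draws["risk_thrombocytopenia_oc", ] == 0))
  # sd 0 collapses every draw onto the baseline
  expect_equal(unname(sample_parameters(defs, sd_frac = 0)), defs$baseline)
})

test_that("PSA is reproducible, degenerates to the base case, and matches an analytic CEAC", {
  model <- toy_model(base_a = 120000, base_b = 1)
  defs <- toy_defs(list(
    list(name = "a", baseline = 1.2e5, low = 0.9e5, high = 1.5e5,
         distribution = "normal", role = "clinical")))

  # sd -> 0: every replicate reproduces the base case; CEAC is a step at the ICER
  psa0 <- run_psa(model, defs, n_reps = 50, wtp_grid = c(1e5, 119999, 120001, 2e5),
                  seed = 4, sd_frac = 0)
  expect_true(all(psa0$samples$delta_cost == 1.2e5))
  expect_equal(psa0$ceac$probability, c(0, 0, 1, 1))

  # fixed seed: bit-reproducible; stored samples re-derive the CEAC
  psa1 <- run_psa(model, defs, n_reps = 200, seed = 7)
  psa2 <- run_psa(model, defs, n_reps = 200, seed = 7)
  expect_identical(psa1$samples, psa2$samples)
  expect_identical(psa1$ceac,
                   ceac_from_samples(psa1$samples$delta_cost,
                                     psa1$samples$delta_qaly, psa1$ceac$wtp))

  # analytic oracle: INMB = w - a with a ~ N(120000, 12000);
  # P(cost-effective) = pnorm((w - 120000)/12000), within 3 binomial SE
  psa <- run_psa(model, defs, n_reps = 1000, wtp_grid = c(110000, 120000, 140000),
                 seed = 11)
  for (i in 1:3) {
    w <- psa$ceac$wtp[i]
    p_true <- pnorm((w - 120000) / 12000)
    se <- sqrt(p_true * (1 - p_true) / 1000)
    expect_lt(abs(psa$ceac$probability[i] - p_true), 3 * se + 1e-12)
  }
  # limit behaviour: as wtp grows the CEAC approaches P(delta QALY > 0) = 1
  big <- ceac_from_samples(psa$samples$delta_cost, psa$samples$delta_qaly, 1e9)
  expect_equal(big$probability, mean(psa$samples$delta_qaly > 0))
})

test_that("failed replicates are excluded and counted", {
  flaky <- local({
    k <- 0
    function(overrides = numeric(0)) {
      k <<- k + 1
      if (k %% 5 == 0) stop("replicate failure")
      toy_model()(overrides)
    }
  })
  defs <- toy_defs(list(list(name = "a", baseline = 1e5, low = 9e4, high = 1.1e5,
                             distribution = "normal", role = "clinical")))
  psa <- run_psa(flaky, defs, n_reps = 20, seed = 2)
  expect_equal(psa$n_failed, 4)
  expect_equal(nrow(psa$samples), 16)
})
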