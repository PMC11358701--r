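#' Reference patient profile for dosing
#'
#' @param weight Body weight (kg).
#' @param bsa Body surface area (m^2).
#' @param ccr Creatinine clearance (mL/min).
#' @param age Age (years).
#' @return Object of class `patient_profile`.
#' @export
patient_profile <- function(weight = 70, bsa = 1.86, ccr = 70, age = 65) {
  stopifnot(weight > 0, bsa > 0, ccr > 0, age > 0)
  structure(list(weight = weight, bsa = bsa, ccr = ccr, age = age),
            class = "patient_profile")
}

#' Dose of one agent for a reference patient
#'
#' Three dosing rules: `"flat"` (mg per day, returned as-is), `"per_m2"`
#' (mg/m^2 scaled by BSA, per administration), `"per_kg"` (mg/kg scaled by
#' weight), and `"calvert"` (carboplatin: dose in mg = AUC x (GFR + 25) with
#' GFR approximated by the creatinine clearance).
#'
#' @param rule One of `"flat"`, `"per_m2"`, `"per_kg"`, `"calvert"`.
#' @param value Dose coefficient: mg/day, mg/m^2, mg/kg, or target AUC.
#' @param profile A [patient_profile()].
#' @return Dose in mg (per day for `"flat"`, else per administration).
#' @export
#' @examples
#' drug_dose_mg("per_m2", 500, patient_profile())   # pemetrexed: 930 mg
#' drug_dose_mg("calvert", 5, patient_profile())    # carboplatin: 475 mg
drug_dose_mg <- function(rule, value, profile = patient_profile()) {
  stopifnot(inherits(profile, "patient_profile"), value >= 0)
  switch(rule,
    flat = value,
    per_m2 = value * profile$bsa,
    per_kg = value * profile$weight,
    calvert = value * (profile$ccr + 25),
    stop("unknown dosing rule '", rule, "'", call. = FALSE)
  )
}

#' Default model parameters
#'
#' The full parameter set of the cost-effectiveness model as a flat named
#' list: reference-patient measures, the overall-survival hazard ratio,
#' discontinuation proportions, 2023 US unit costs (per mg drug prices, CPT
#' infusion fees, imaging, best supportive care, end-of-life bundle,
#' follow-up, EGFR testing, severe-adverse-event management), health-state
#' utilities, SAE disutilities and per-arm SAE risks, the annual discount
#' rate and the willingness-to-pay threshold. Any entry can be overridden by
#' the sensitivity-analysis machinery.
#'
#' @param ... Named overrides of individual entries.
#' @return Named list of parameter values.
#' @export
ce_parameters <- function(...) {
  p <- list(
    # clinical / patient
    weight = 70, bsa = 1.86, ccr = 70, age = 65,
    discount = 0.03, wtp = 150000,
    hr_os = 0.75,
    p_natural_annual = 0.0197,
    # discontinuation proportions (first line) and per-cycle (subsequent)
    disc_osimertinib_oc = 0.4420,
    disc_platinum_oc = 0.2319,
    disc_pemetrexed_oc = 0.7536,
    disc_osimertinib_o = 0.5527,
    disc_subsequent = 0.03,
    # drug prices, $/mg
    cost_osimertinib = 7.08,
    cost_pemetrexed = 0.32,
    cost_cisplatin = 0.22,
    cost_carboplatin = 0.28,
    cost_nab_paclitaxel = 14.79,
    cost_gefitinib = 1.09,
    cost_afatinib = 9.76,
    cost_bevacizumab = 7.38,
    cost_pembrolizumab = 56.41,
    # administration (CPT), $ per infusion hour type
    cost_infusion_first_hour = 132.16,
    cost_infusion_additional_hour = 28.47,
    cost_infusion_subsequent_hour = 65.06,
    # other direct medical costs, $
    cost_imaging_3monthly = 114.54,
    cost_bsc_per_cycle = 3006.28,
    cost_end_of_life = 40708.33,
    cost_followup_monthly = 542.65,
    cost_egfr_testing = 1199.53,
    # SAE management, $ per event
    cost_sae_anemia = 2053.86,
    cost_sae_neutropenia = 1295.15,
    cost_sae_thrombocytopenia = 2252.54,
    # utilities and disutilities
    u_pfs = 0.71, u_pfs2 = 0.74, u_pd = 0.58, u_death = 0,
    du_anemia = 0.07, du_neutropenia = 0.46, du_thrombocytopenia = 0.25,
    # SAE risks per arm (as tabulated; see `sae_swap` in ce_settings)
    risk_anemia_o = 0.17, risk_neutropenia_o = 0.13,
    risk_thrombocytopenia_o = 0.07,
    risk_anemia_oc = 0.003, risk_neutropenia_oc = 0.01,
    risk_thrombocytopenia_oc = 0
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown)) stop("unknown parameter(s): ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    p[names(dots)] <- dots
  }
  neg <- names(p)[startsWith(names(p), "cost_")]
  if (any(unlist(p[neg]) < 0)) stop("costs must be non-negative", call. = FALSE)
  p
}

#' Structural model settings
#'
#' @param horizon_years Time horizon (years).
#' @param induction_cycles Number of first-line chemotherapy induction cycles
#'   (platinum given only in these cycles).
#' @param platinum `"carboplatin"` (Calvert AUC 5) or `"cisplatin"`
#'   (75 mg/m^2).
#' @param pd_denominator Denominator form for the PD-to-Death transition
#'   (see [build_transition_matrix()]).
#' @param sae_swap If `TRUE`, swap the two arms' SAE risk vectors (the input
#'   table's arm labelling of SAE risks is carried verbatim by default; the
#'   flag lets the user assert the opposite assignment).
#' @param subsequent_shares Named market shares of the second-line basket;
#'   must sum to 1.
#' @return Named list of settings.
#' @export
ce_settings <- function(horizon_years = 20, induction_cycles = 4,
                        platinum = c("carboplatin", "cisplatin"),
                        pd_denominator = c("lead", "lag"),
                        sae_swap = FALSE,
                        subsequent_shares = c(platinum_doublet = 0.25,
                                              tki = 0.25,
                                              bevacizumab_regimen = 0.25,
                                              pembrolizumab = 0.25)) {
  platinum <- match.arg(platinum)
  pd_denominator <- match.arg(pd_denominator)
  stopifnot(abs(sum(subsequent_shares) - 1) < 1e-9)
  list(horizon_years = horizon_years, induction_cycles = induction_cycles,
       platinum = platinum, pd_denominator = pd_denominator,
       sae_swap = sae_swap, subsequent_shares = subsequent_shares)
}

# per-cycle shares of recurring non-drug costs
.followup_per_cycle <- function(p) p$cost_followup_monthly * CYCLE_DAYS / DAYS_PER_MONTH
.imaging_per_cycle <- function(p) p$cost_imaging_3monthly * CYCLE_DAYS / (3 * DAYS_PER_MONTH)

# expected SAE cost / disutility bundles per arm ("oc" or "o")
.sae_bundle <- function(p, settings, arm) {
  suffix <- if (identical(arm, "oc")) "_oc" else "_o"
  if (isTRUE(settings$sae_swap)) suffix <- if (suffix == "_oc") "_o" else "_oc"
  risks <- c(anemia = p[[paste0("risk_anemia", suffix)]],
             neutropenia = p[[paste0("risk_neutropenia", suffix)]],
             thrombocytopenia = p[[paste0("risk_thrombocytopenia", suffix)]])
  costs <- c(anemia = p$cost_sae_anemia, neutropenia = p$cost_sae_neutropenia,
             thrombocytopenia = p$cost_sae_thrombocytopenia)
  dus <- c(anemia = p$du_anemia, neutropenia = p$du_neutropenia,
           thrombocytopenia = p$du_thrombocytopenia)
  list(expected_cost = sum(risks * costs),
       expected_disutility = sum(risks * dus))
}

#' Per-person state costs for a strategy over the horizon
#'
#' Computes the undiscounted cost per person-cycle of occupying each health
#' state under one strategy. First-line drug costs in PFS apply each agent's
#' price to its dose for the reference patient, scaled by the complement of
#' its discontinuation proportion; the platinum component stops after the
#' induction cycles; infusion administration is billed per CPT hour structure
#' (first hour for the primary infusion, an additional hour for a concurrent
#' platinum). The second-line (PFS-2) cost is a market-share-weighted basket
#' attenuated by the per-cycle subsequent-treatment discontinuation
#' probability compounded over model time. PD carries best supportive care.
#'
#' @param strategy `"oc"` (combination) or `"o"` (monotherapy).
#' @param params [ce_parameters()].
#' @param settings [ce_settings()].
#' @param n_cycles Number of cycles.
#' @return List with vectors `pfs`, `pfs2`, `pd` (length `n_cycles`, cost at
#'   cycles t = 0..n_cycles-1), scalars `one_time` (t = 0) and
#'   `end_of_life` (per incident death), and the SAE `disutility_once`.
#' @export
strategy_state_costs <- function(strategy = c("oc", "o"), params, settings,
                                 n_cycles) {
  strategy <- match.arg(strategy)
  p <- params
  profile <- patient_profile(p$weight, p$bsa, p$ccr, p$age)
  cyc <- seq_len(n_cycles) - 1          # 0-based cycle index

  osi_cycle <- drug_dose_mg("flat", 80, profile) * CYCLE_DAYS * p$cost_osimertinib
  pem_dose <- drug_dose_mg("per_m2", 500, profile)
  plat_dose <- if (settings$platinum == "carboplatin") {
    drug_dose_mg("calvert", 5, profile)
  } else {
    drug_dose_mg("per_m2", 75, profile)
  }
  plat_price <- if (settings$platinum == "carboplatin") p$cost_carboplatin else p$cost_cisplatin

  if (strategy == "oc") {
    osi <- osi_cycle * (1 - p$disc_osimertinib_oc)
    pem <- pem_dose * p$cost_pemetrexed * (1 - p$disc_pemetrexed_oc)
    plat <- plat_dose * plat_price * (1 - p$disc_platinum_oc)
    induction <- cyc < settings$induction_cycles
    admin <- ifelse(induction,
                    p$cost_infusion_first_hour + p$cost_infusion_additional_hour,
                    p$cost_infusion_first_hour)
    drug <- osi + pem + ifelse(induction, plat, 0)
  } else {
    osi <- osi_cycle * (1 - p$disc_osimertinib_o)
    admin <- 0
    drug <- rep(osi, n_cycles)
  }
  pfs <- drug + admin + .followup_per_cycle(p) + .imaging_per_cycle(p)

  # second-line basket (per cycle, before attenuation)
  doublet <- plat_dose * plat_price + pem_dose * p$cost_pemetrexed +
    p$cost_infusion_first_hour + p$cost_infusion_additional_hour
  tki <- drug_dose_mg("flat", 250, profile) * CYCLE_DAYS * p$cost_gefitinib
  bev <- drug_dose_mg("per_kg", 15, profile) * p$cost_bevacizumab + doublet +
    p$cost_infusion_subsequent_hour
  pembro <- 200 * p$cost_pembrolizumab + p$cost_infusion_first_hour
  basket <- sum(settings$subsequent_shares *
                  c(platinum_doublet = doublet, tki = tki,
                    bevacizumab_regimen = bev, pembrolizumab = pembro))
  pfs2 <- basket * (1 - p$disc_subsequent)^cyc +
    .followup_per_cycle(p) + .imaging_per_cycle(p)

  pd <- rep(p$cost_bsc_per_cycle, n_cycles)

  sae <- .sae_bundle(p, settings, strategy)
  list(pfs = as.numeric(pfs), pfs2 = as.numeric(pfs2), pd = pd,
       one_time = p$cost_egfr_testing + sae$expected_cost,
       end_of_life = p$cost_end_of_life,
       disutility_once = sae$expected_disutility * YEARS_PER_CYCLE)
}

#' Accumulate discounted cost and QALY for one strategy
#'
#' State membership is valued at cycle start (no half-cycle correction).
#' Cycle t contributes at discount factor `(1 + r)^(-t * 21/365.25)`; the
#' QALY contribution is occupancy times utility times the cycle length in
#' years; end-of-life cost attaches to incident deaths during cycle t;
#' EGFR testing, expected SAE management cost and expected SAE disutility
#' are booked once at t = 0.
#'
#' @param trace A [run_trace()] result.
#' @param strategy `"oc"` or `"o"`.
#' @param params [ce_parameters()].
#' @param settings [ce_settings()].
#' @return A `strategy_outcome`: list with `cost`, `qaly`, `strategy`, and a
#'   `breakdown` of cost components.
#' @export
accumulate <- function(trace, strategy, params, settings = ce_settings()) {
  stopifnot(inherits(trace, "markov_trace"))
  n <- trace$n_cycles
  sc <- strategy_state_costs(strategy, params, settings, n)
  cyc <- seq_len(n) - 1
  df <- (1 + params$discount)^(-cyc * YEARS_PER_CYCLE)
  occ <- trace$occupancy[seq_len(n), , drop = FALSE]   # rows t = 0..n-1

  state_cost <- occ[, "PFS"] * sc$pfs + occ[, "PFS2"] * sc$pfs2 +
    occ[, "PD"] * sc$pd
  eol_cost <- trace$incident_deaths * sc$end_of_life
  cost <- sum(df * (state_cost + eol_cost)) + sc$one_time

  u <- c(PFS = params$u_pfs, PFS2 = params$u_pfs2, PD = params$u_pd,
         Death = params$u_death)
  qaly <- sum(df * (occ %*% u)) * YEARS_PER_CYCLE - sc$disutility_once

  structure(list(cost = cost, qaly = qaly, strategy = strategy,
                 breakdown = list(
                   drug_and_state = sum(df * state_cost),
                   end_of_life = sum(df * eol_cost),
                   one_time = sc$one_time)),
            class = "strategy_outcome")
}

#' @export
print.strategy_outcome <- function(x, ...) {
  cat(sprintf("<strategy_outcome> %s: cost $%s, QALY %.4f\n", x$strategy,
              format(round(x$cost, 2), big.mark = ","), x$qaly))
  invisible(x)
}
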