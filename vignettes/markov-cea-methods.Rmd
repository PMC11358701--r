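---
title: "Methods: a four-state Markov cost-effectiveness model from digitized survival curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a four-state Markov cost-effectiveness model from digitized survival curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`markovcea` implements a trial-based cost-effectiveness analysis of
first-line osimertinib plus platinum–pemetrexed chemotherapy ("oc") versus
osimertinib monotherapy ("o") in EGFR-mutated advanced non-small cell lung
cancer, from the United States health-system perspective. The pipeline runs
from digitized Kaplan–Meier curves through a cohort Markov model to
ICER/INMB/INHB and full deterministic and probabilistic sensitivity
analysis. This vignette documents the model, its assumptions, and the design
decisions that were genuinely open.

## Model structure

Four health states: progression-free on first-line therapy (PFS),
progression-free on second-line therapy after a first progression (PFS-2),
progressed disease after a second progression (PD), and Death (absorbing).
The whole cohort starts in PFS. The model runs on 21-day cycles over a
20-year horizon — `round(20 * 365.25 / 21) = 348` cycles — with costs and
QALYs discounted at 3% per year, and a willingness-to-pay threshold of
$150,000 per QALY.

Transitions at cycle $t$ are driven by three survival functions evaluated at
cycle boundaries — first-line progression-free survival $P(t)$, second
progression-free survival $P_2(t)$, and overall survival $S(t)$ — plus a
per-cycle background ("natural") mortality $p_{Nat}$:

$$P_{PFS \to PFS2} = \frac{P(t) - P(t+1)}{P(t)} - p_{Nat}, \qquad
  P_{PFS2 \to PD} = \frac{P_2(t) - P_2(t+1)}{P_2(t)} - p_{Nat},$$

$$P_{PD \to Death} = \frac{S(t) - S(t+1)}{S(t) - P_2(\cdot)} - p_{Nat},$$

with deaths from PFS and PFS-2 at the natural rate and diagonals as
complements. Two published forms of the PD→Death denominator exist —
$S(t) - P_2(t)$ and $S(t) - P_2(t+1)$; both are implemented
(`pd_denominator = "lag"` / `"lead"`) with `"lead"` as the default, since
that is the more explicit tabulated form. Probabilities falling outside
$[0,1]$ are clipped, and if a row's off-diagonal mass then exceeds 1 the row
is rescaled so it stays stochastic — plain clipping alone would break mass
conservation.

**Consistency caveat.** These equations apply each endpoint's *marginal*
per-cycle hazard to the current *state occupancy*. That is exactly
self-consistent for PFS (its occupancy equals $P(t)$ by construction), but
only approximately so for PFS-2 and PD: when $P$ and $P_2$ decline over the
same period, the PFS-2 state holds less mass than $P_2(t)$ assumes and the
cohort under-progresses, so modeled cumulative mortality *lags* the fitted
OS curve — it can never outrun it. The trace-versus-OS agreement tests
therefore use a state-consistent configuration (first-line progression
resolving quickly relative to the later transitions), where the lag is below
0.02; under heavily overlapping curves the lag is larger and is an inherent
property of this model family, not of the implementation.

**Background mortality** is an explicit input: a constant annual death
probability (default 0.0197, roughly a general-population 65-year-old) or a
user-supplied age-indexed life table, converted per cycle as
$1 - (1-p_{annual})^{21/365.25}$. No external database is queried.

No half-cycle correction is applied; state membership is valued at cycle
start. With 21-day cycles the correction is well below the other
uncertainties in the model.

## From digitized curves to survival functions

**Synthetic trial artifacts.** `synthetic_trial_curves()` generates the
study conditions: two arms of 279/278 patients; gamma event-time
distributions sharing one shape (1.6) so the partitioned-survival ordering
$P \le P_2 \le S$ holds identically; PFS medians 29.4 vs 19.9 months
(the published first-line combination-vs-monotherapy effect); monotherapy OS
median 38.6 months (the mature monotherapy OS the base case borrows);
second-PFS medians 40 vs 30 months and a combination OS median of 46 months
(chosen as clinically plausible values — they are not published quantities);
light random censoring (0.002/month) plus administrative cutoffs of 42/48/60
months by endpoint; numbers at risk every 3 months. Digitization error can
be emulated by truncated Gaussian noise on the probability scale followed by
an isotonic non-increasing projection. The generator emulates the *shape* of
published trial artifacts; it does not emulate informative censoring,
non-proportional hazards, or reporting granularity coarser than the event
grid, so passing tests demonstrate correctness of the machinery, not
fidelity to any specific trial.

**Pseudo-IPD reconstruction** (`reconstruct_ipd()`) is the standard
interval-wise algorithm for published curves with numbers-at-risk tables:
within each risk interval, censoring counts are inferred from the difference
between coordinate-implied attrition and the observed change in numbers at
risk, censoring times are spread uniformly, event counts at each coordinate
drop keep the running product-limit estimate on the curve, and the censoring
count iterates to integer consistency with the next risk-table entry.
Event counts use sequential product-limit-consistent rounding, which keeps
the running estimate on the digitized curve (on integer-consistent curves it
coincides with largest-remainder apportionment). Patients remaining after
the last coordinate are censored at the end of follow-up. Inconsistent
tables (implied negative censoring) are clamped at zero with a warning and a
per-interval log. Calibration to a reported total event count is available
(`use_total_events`) but off by default, since reported-event calibration is
not part of the base design. Round-trip fidelity — the sup-norm between the
input coordinates and the KM estimate of the reconstruction — is below 0.02
for jitter-free curves across all seven candidate families at n = 300, and
typically below 0.001.

**Parametric fitting** uses right-censored maximum likelihood via
`flexsurv::flexsurvreg()` for the seven candidate families in their
conventional survival-analysis parameterizations:

| family | parameters |
|---|---|
| exponential | rate |
| Weibull | shape, scale |
| log-logistic | shape, scale |
| log-normal | meanlog, sdlog |
| gamma | shape, rate |
| generalized gamma | $\mu$, $\sigma$, $Q$ (location/scale/shape) |
| Gompertz | shape (may be negative), rate |

**Selection** orders converged fits by AIC and takes the first that passes
two plausibility filters on the horizon grid: (i) the candidate may not
cross above its companion curve (a PFS or PFS-2 extrapolation sitting above
OS is biologically impossible), and (ii) a tail filter rejects
extrapolations whose survival at the 20-year horizon exceeds a ceiling
(default 0.40 — "tailing"). The ceiling and the ordering slack
(0.02 on the probability scale, tolerating small-sample and digitization
noise in curves that genuinely sit close together) are explicit, configurable
numbers precisely so the rule is testable. AIC ties break by BIC, then by
fewer parameters. By default one family is selected *jointly per endpoint
across arms* (minimum summed AIC among families admissible in every arm), so
that between-strategy differences are not artifacts of differing
extrapolation shapes; `unify_distributions = FALSE` relaxes this.

**Comparator OS derivation.** In the base-case design the combination arm's
OS is not fitted from its own (immature) curve: the monotherapy OS is fitted
and the combination arm derived by the proportional-hazards transform
$S_{oc}(t) = S_o(t)^{HR}$ with HR = 0.75 (95% CI 0.57–0.97). The scenario
design (`os_source = "direct"`) instead fits both arms' own OS curves.
Time-varying hazard ratios are out of scope.

## Valuation

Unit costs are 2023 US dollars. Dosing uses a reference patient (70 kg, BSA
1.86 m², creatinine clearance 70 mL/min, age 65): osimertinib 80 mg/day;
pemetrexed 500 mg/m² (930 mg) every 21 days; carboplatin by the Calvert
formula at AUC 5 — $5 \times (70 + 25) = 475$ mg (cisplatin 75 mg/m² is
available as an alternative platinum); bevacizumab 15 mg/kg;
pembrolizumab 200 mg flat. No vial rounding or wastage: prices are per mg.

Open design points, resolved as follows:

- **Discontinuation.** The trial reports cumulative discontinuation
  proportions per first-line agent (osimertinib 0.4420 / 0.5527 by arm,
  platinum 0.2319, pemetrexed 0.7536) without time-to-discontinuation
  curves. Each agent's per-cycle cost is scaled by the constant expected
  multiplier $(1 - \text{rate})$ across the PFS state — the simplest reading
  consistent with a cumulative proportion, and a sensitivity parameter
  either way. Second-line treatment instead attenuates by a per-cycle
  discontinuation probability of 0.03 compounded over model time.
- **Second-line basket.** PFS-2 drug cost is a market-share-weighted basket
  over a platinum doublet (carboplatin + pemetrexed), a first-generation
  TKI (gefitinib 250 mg/day), a bevacizumab-containing regimen, and
  pembrolizumab, with equal default shares — an explicit assumption, since
  subsequent-therapy proportions are referenced but not printed. The
  nab-paclitaxel, afatinib and (under carboplatin) cisplatin prices in the
  parameter table are carried but priced into neither arm by default, which
  also provides natural inert parameters for the tornado contract.
- **Administration.** CPT-style infusion billing: first hour $132.16,
  additional hour $28.47, subsequent-infusion hour $65.06. The primary
  infusion of a visit bills the first-hour code, a concurrent platinum the
  additional hour (induction visits: $160.63), and further concurrent
  agents the subsequent-infusion hour. Hour assignments are configuration,
  not data.
- **Recurring care.** Follow-up $542.65 is monthly (monthly physician
  visits) and imaging $114.54 per 3 months; both convert to per-cycle shares
  by 21/30.4375 and 21/91.3125. Best supportive care $3,006.28 per cycle
  applies in PD.
- **One-time flows.** EGFR testing ($1,199.53) and the expected SAE
  management cost (risk x unit cost, summed over anemia, neutropenia,
  thrombocytopenia) are booked at cycle 0; end-of-life care ($40,708.33,
  a six-month terminal bundle) attaches once per incident death.
- **SAE burden.** Expected SAE disutility (risk x disutility x one cycle
  length) is subtracted once at baseline; severe events are treated as
  short-lived. The input table's per-arm SAE risks are carried verbatim
  (monotherapy: anemia 0.17, neutropenia 0.13, thrombocytopenia 0.07;
  combination: 0.003, 0.01, 0) even though that assignment looks swapped
  relative to the clinical expectation that the combination causes more
  severe toxicity; `ce_settings(sae_swap = TRUE)` asserts the opposite
  assignment without changing any other input. With these small numbers the
  choice is immaterial to the headline results.

Utilities: PFS 0.71, PFS-2 0.74, PD 0.58, death 0. QALYs accrue as
occupancy x utility x cycle length (21/365.25 years), discounted per cycle
at $(1+r)^{-t \cdot 21/365.25}$.

## Outcomes

`compare_strategies()` reports $\Delta C$, $\Delta E$, the ICER
$\Delta C/\Delta E$, and net benefits INMB $= \lambda\Delta E - \Delta C$
and INHB $= \Delta E - \Delta C/\lambda$, which satisfy
INMB $= \lambda \cdot$ INHB identically. The ICER is reported only in the
northeast/southwest quadrants; dominance is a label, never a signed ratio.

## Sensitivity analysis

**Deterministic (tornado).** One parameter at a time at its bounds, all else
at baseline: costs, BSA, creatinine clearance and weight ±25%; proportions
and utilities ±10% (capped at 1); discount rate 0–0.08; the OS hazard ratio
over its CI (0.57–0.97). Entries are ranked by ICER spread; failures at a
bound are flagged, not dropped.

**Probabilistic.** 1000 Monte-Carlo replicates with joint independent draws:
gamma for costs, beta for proportions and utilities, normal for patient
measures, uniform for the discount rate — each with mean at baseline and SD
at 10% of baseline (method-of-moments hyperparameters; the exact
hyperparameterization is this package's documented choice). The hazard
ratio is drawn lognormally with log-SD $(\ln 0.97 - \ln 0.57)/3.92$ from its
CI rather than mean ± 10%. Beta parameters whose moments are infeasible
(mean too near 0 or 1) fall back to a ±10% uniform draw. The CEAC is the
fraction of replicates with positive INMB per willingness-to-pay value.
Survival-fit coefficient uncertainty is *not* sampled — the PSA covers the
tabulated parameters only — a known limitation shared with the underlying
design. Replicate evaluations reuse cached Markov traces whenever the drawn
hazard ratio is unchanged; traces are rebuilt whenever it moves.

## Numerical choices and problem sizes

All times upstream of the engine are months; the engine converts to 21-day
cycles (1 cycle = 21/30.4375 months). Randomness is always explicit: every
simulating function takes a seed, and the PSA is bit-reproducible given one.
Trace row sums are conserved to 1e-9 over 348 cycles. The test suite
exercises: round trips for all seven families at n = 300; parameter
recovery at n = 2000 over three seeds; fuzzing of the net-benefit identities
at 10^4 draws; a 1000-replicate PSA against a closed-form acceptability
curve; and a complete end-to-end run at the preset's trial-sized arms
(279/278) with a 100-replicate PSA — sizes chosen to keep the whole suite in
the low minutes on a single core while leaving Monte-Carlo error well inside
the asserted tolerances.

## Known limitations

- The transition equations inherit the partitioned-survival/Markov
  approximation discussed above; mortality lags the fitted OS when PFS and
  PFS-2 overlap heavily.
- Pseudo-IPD reconstruction assumes non-informative censoring uniform
  within risk intervals and no covariates; no competing risks.
- The second-line basket composition and infusion-hour assignments are
  assumptions surfaced as configuration.
- No societal-perspective costs, no price-inflation engine, no
  efficiency-frontier analysis beyond two strategies, no EVPI.
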