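Package: markovcea
Title: Markov Cohort Cost-Effectiveness Analysis from Digitized Survival Curves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A four-state (progression-free, second progression-free,
    progressed disease, death) Markov cohort model for cost-effectiveness
    analysis of first-line regimens in EGFR-mutated advanced non-small cell
    lung cancer, driven by digitized Kaplan-Meier curves. Provides pseudo
    individual-patient-data reconstruction from step-curve coordinates and
    numbers-at-risk tables, parametric survival fitting over seven candidate
    distributions with AIC/BIC plus plausibility-constrained selection,
    hazard-ratio derivation of a comparator overall-survival curve,
    time-dependent transition probabilities with background mortality,
    discounted cost and QALY valuation, ICER/INMB/INHB outcomes, and
    deterministic (tornado) and probabilistic (Monte Carlo, CEAC) sensitivity
    analysis. A synthetic trial-data generator with known ground truth makes
    the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    flexsurv,
    survival,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
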