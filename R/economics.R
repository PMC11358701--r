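#' Compare two strategies: ICER, INMB, INHB and dominance
#'
#' Computes incremental outcomes of an intervention against a comparator:
#' \deqn{ICER = \Delta C / \Delta E, \quad INMB = \lambda \Delta E - \Delta C,
#'   \quad INHB = \Delta E - \Delta C / \lambda}
#' at willingness-to-pay \eqn{\lambda}. The ICER is only reported in the
#' northeast/southwest quadrants; dominance (\eqn{\Delta C < 0, \Delta E > 0}
#' or the reverse) and \eqn{\Delta E = 0} are flagged instead of producing a
#' signed, uninterpretable ratio.
#'
#' @param intervention,comparator `strategy_outcome` objects (or lists with
#'   `cost` and `qaly`).
#' @param wtp Willingness-to-pay threshold in $ per QALY (> 0).
#' @return A `ce_result`: list with per-strategy cost/QALY, `delta_cost`,
#'   `delta_qaly`, `icer` (NA when flagged), `icer_status` (`"defined"`,
#'   `"dominant"`, `"dominated"`, `"undefined"`), `inmb`, `inhb`, `wtp`.
#' @export
#' @examples
#' compare_strategies(list(cost = 984917.42, qaly = 3.911),
#'                    list(cost = 785941.09, qaly = 3.022), wtp = 150000)
compare_strategies <- function(intervention, comparator, wtp = 150000) {
  stopifnot(wtp > 0)
  dc <- intervention$cost - comparator$cost
  de <- intervention$qaly - comparator$qaly
  status <- if (de == 0) {
    "undefined"
  } else if (dc <= 0 && de > 0) {
    "dominant"
  } else if (dc >= 0 && de < 0) {
    "dominated"
  } else {
    "defined"
  }
  icer <- if (status == "defined") dc / de else NA_real_
  structure(list(
    intervention = list(cost = intervention$cost, qaly = intervention$qaly,
                        strategy = intervention$strategy %||% "intervention"),
    comparator = list(cost = comparator$cost, qaly = comparator$qaly,
                      strategy = comparator$strategy %||% "comparator"),
    delta_cost = dc, delta_qaly = de,
    icer = icer, icer_status = status,
    inmb = wtp * de - dc,
    inhb = de - dc / wtp,
    wtp = wtp
  ), class = "ce_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ce_result <- function(x, ...) {
  fmt <- function(v) format(round(v, 2), big.mark = ",", scientific = FALSE)
  cat(sprintf("<ce_result> %s vs %s (WTP $%s/QALY)\n",
              x$intervention$strategy, x$comparator$strategy, fmt(x$wtp)))
  cat(sprintf("  cost: $%s vs $%s (delta $%s)\n", fmt(x$intervention$cost),
              fmt(x$comparator$cost), fmt(x$delta_cost)))
  cat(sprintf("  QALY: %.4f vs %.4f (delta %.4f)\n", x$intervention$qaly,
              x$comparator$qaly, x$delta_qaly))
  if (x$icer_status == "defined") {
    cat(sprintf("  ICER: $%s/QALY;  INMB: $%s;  INHB: %.4f QALY\n",
                fmt(x$icer), fmt(x$inmb), x$inhb))
  } else {
    cat(sprintf("  ICER: %s;  INMB: $%s;  INHB: %.4f QALY\n",
                x$icer_status, fmt(x$inmb), x$inhb))
  }
  invisible(x)
}

#' Results table in the standard base-case layout
#'
#' @param x A `ce_result`.
#' @return Data frame with one row per strategy: cost, incremental cost,
#'   QALY, incremental QALY, INMB, INHB, ICER.
#' @export
ce_table <- function(x) {
  stopifnot(inherits(x, "ce_result"))
  data.frame(
    treatment = c(x$intervention$strategy, x$comparator$strategy),
    cost = c(x$intervention$cost, x$comparator$cost),
    incremental_cost = c(x$delta_cost, NA),
    qaly = c(x$intervention$qaly, x$comparator$qaly),
    incremental_qaly = c(x$delta_qaly, NA),
    inmb = c(x$inmb, NA),
    inhb = c(x$inhb, NA),
    icer = c(if (x$icer_status == "defined") x$icer else NA, NA),
    icer_status = c(x$icer_status, NA)
  )
}
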