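## Portfolio totals and paired-scenario comparison metrics.
##
## Reporting units (matching the published summary scales): total cost in
## currency millions, total benefit in thousands of benefit units,
## cost-effectiveness ratios in thousands of currency per benefit unit,
## NHB in thousands of benefit units.

.quadrant_levels <- c("cost_up_benefit_down", "cost_up_benefit_up",
                      "cost_down_benefit_down", "cost_down_benefit_up")

#' Totals of a funded portfolio
#'
#' Sums population-scaled costs and benefits over the funded interventions:
#' `total_cost = sum(P*C)` (reported in currency millions),
#' `total_benefit = sum(P*Q)` (thousands of benefit units), the funded
#' count, and the cost-effectiveness ratio of the portfolio against doing
#' nothing, `cer = total_cost / total_benefit` (thousands of currency per
#' benefit unit; `NA` for an empty or zero-benefit portfolio).
#'
#' @param candidates a `"candidate_set"`.
#' @param portfolio a `"portfolio"` from the same candidate set.
#' @return An object of class `"scenario_outcome"`: a list with
#'   `total_cost`, `total_benefit`, `funded_count`, `cer`, `rule_id`.
#' @export
portfolio_totals <- function(candidates, portfolio) {
  stopifnot(inherits(portfolio, "portfolio"),
            length(portfolio$funded) == nrow(candidates))
  f <- portfolio$funded
  cost_m <- sum(intervention_cost(candidates$P, candidates$C)[f]) / 1000
  benefit_k <- sum((candidates$P * candidates$Q)[f])
  structure(
    list(total_cost = cost_m, total_benefit = benefit_k,
         funded_count = sum(f),
         cer = if (benefit_k > 0) cost_m / benefit_k else NA_real_,
         rule_id = portfolio$rule_id),
    class = "scenario_outcome")
}

#' @export
print.scenario_outcome <- function(x, ...) {
  cat(sprintf("Scenario [%s]: cost %.1f M, benefit %.1f k, %d funded, CER %s\n",
              x$rule_id, x$total_cost, x$total_benefit, x$funded_count,
              format(x$cer, digits = 4)))
  invisible(x)
}

#' Compare an active scenario against its counterfactual
#'
#' Computes the paired-comparison metrics between the threshold-based
#' (PSI-active) and counterfactual (PSI-absent) portfolios evaluated on the
#' same candidate set: the cost increment `delta_cost` (currency millions),
#' the benefit increment `delta_benefit` (thousands of benefit units), the
#' net health benefit `nhb = delta_benefit - delta_cost / t` with the cost
#' increment valued at the threshold `t` (unit-harmonised; result in
#' thousands of benefit units), the between-scenario ICER
#' `delta_cost / delta_benefit` (thousands of currency per benefit unit;
#' `NA` when `delta_benefit == 0`), and the sign quadrant used in the
#' cost-effectiveness-plane classification (`delta >= 0` counts as a
#' positive increment).
#'
#' @param active,counterfactual `"scenario_outcome"` objects (see
#'   [portfolio_totals()]).
#' @param t cost-effectiveness threshold (currency per benefit unit).
#' @return An object of class `"comparison"`: a list with `delta_cost`,
#'   `delta_benefit`, `nhb`, `icer`, `quadrant`.
#' @export
compare_outcomes <- function(active, counterfactual, t) {
  stopifnot(inherits(active, "scenario_outcome"),
            inherits(counterfactual, "scenario_outcome"), t > 0)
  d_cost <- active$total_cost - counterfactual$total_cost
  d_benefit <- active$total_benefit - counterfactual$total_benefit
  ## d_cost millions -> thousands of currency, / t -> thousands of benefit units
  nhb <- d_benefit - d_cost * 1000 / t
  quadrant <- if (d_cost >= 0) {
    if (d_benefit < 0) "cost_up_benefit_down" else "cost_up_benefit_up"
  } else {
    if (d_benefit < 0) "cost_down_benefit_down" else "cost_down_benefit_up"
  }
  structure(
    list(delta_cost = d_cost, delta_benefit = d_benefit, nhb = nhb,
         icer = if (d_benefit != 0) d_cost / d_benefit else NA_real_,
         quadrant = quadrant),
    class = "comparison")
}

#' @export
print.comparison <- function(x, ...) {
  cat(sprintf("dCost %.1f M, dBenefit %.1f k, NHB %.1f k, ICER %s [%s]\n",
              x$delta_cost, x$delta_benefit, x$nhb,
              format(x$icer, digits = 4), x$quadrant))
  invisible(x)
}

#' Quadrant classification table
#'
#' Cross-classifies per-simulation comparisons by the signs of the cost and
#' benefit increments, as percentages of all simulations. Rows are the cost
#' increment (`>= 0` first, then `< 0`), columns the benefit increment
#' (`< 0` first, then `>= 0`); percentages sum to 100.
#'
#' @param quadrants character vector of quadrant labels (from
#'   [compare_outcomes()]) or a data frame of simulation records with a
#'   `quadrant` column.
#' @return A 2 x 2 numeric matrix of percentages with dimnames
#'   `cost = c(">=0", "<0")`, `benefit = c("<0", ">=0")`.
#' @export
quadrant_table <- function(quadrants) {
  if (is.data.frame(quadrants)) quadrants <- quadrants$quadrant
  if (length(quadrants) == 0L) stop("no comparison records supplied")
  bad <- setdiff(unique(quadrants), .quadrant_levels)
  if (length(bad)) stop("unknown quadrant label(s): ", paste(bad, collapse = ", "))
  counts <- table(factor(quadrants, levels = .quadrant_levels))
  pct <- 100 * as.numeric(counts) / length(quadrants)
  matrix(pct[c(1, 2, 3, 4)], nrow = 2, byrow = TRUE,
         dimnames = list(cost = c(">=0", "<0"), benefit = c("<0", ">=0")))
}

#' Add health-technology-assessment overhead to a scenario
#'
#' Adds the running cost of the assessments themselves --
#' `unit_cost * n_assessments`, unit-harmonised from natural currency to
#' millions -- to a scenario's total cost, leaving benefits and counts
#' unchanged. Off by default in the engine (`hta_unit_cost = 0` in the
#' configuration) since the headline comparison excludes it.
#'
#' @param outcome a `"scenario_outcome"`.
#' @param unit_cost cost of one assessment (natural currency units).
#' @param n_assessments number of assessments performed in the cycle.
#' @return The adjusted `"scenario_outcome"` (CER recomputed).
#' @export
apply_hta_overhead <- function(outcome, unit_cost, n_assessments) {
  stopifnot(inherits(outcome, "scenario_outcome"), unit_cost >= 0,
            n_assessments >= 0)
  outcome$total_cost <- outcome$total_cost + unit_cost * n_assessments / 1e6
  outcome$cer <- if (outcome$total_benefit > 0)
    outcome$total_cost / outcome$total_benefit else NA_real_
  outcome
}
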