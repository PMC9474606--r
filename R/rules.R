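## Funding decision rules. All rules scan candidates in arrival (sampling)
## order. Budget-limited rules use skip-and-continue scanning: a rejected
## intervention consumes no budget and later, cheaper candidates may still
## be funded. Budgets and cumulative spend are tracked over the
## population-scaled costs (P*C) of FUNDED interventions only.

#' Population-scaled intervention cost
#'
#' The budget impact of funding one intervention: `P * C`, with `P` in
#' thousands of cases and `C` in currency per case, hence thousands of
#' currency units ("cost units"). All budget-limited rules compare
#' cumulative funded cost in these units; [`.budget_cost_units`][country_config]
#' conversion is applied to the configured budget (millions) by the engine.
#'
#' @param P impacted population (thousands of cases); vectorised.
#' @param C incremental cost per case (currency); vectorised.
#' @return `P * C` in thousands of currency units.
#' @export
intervention_cost <- function(P, C) P * C

.new_portfolio <- function(funded, rule_id, spent) {
  structure(list(funded = funded, rule_id = rule_id, spent = spent),
            class = "portfolio")
}

#' @export
print.portfolio <- function(x, ...) {
  cat(sprintf("Portfolio [%s]: %d of %d funded, spent %g (cost units)\n",
              x$rule_id, sum(x$funded), length(x$funded), x$spent))
  invisible(x)
}

## shared budget scan: `eligible[i]` says whether candidate i may be funded
## at all (threshold verdict or TRUE); returns the funded mask under
## skip-and-continue with budget in cost units.
.budget_scan <- function(cost, eligible, budget) {
  n <- length(cost)
  funded <- logical(n)
  spent <- 0
  for (i in seq_len(n)) {
    if (eligible[i] && spent + cost[i] <= budget) {
      funded[i] <- TRUE
      spent <- spent + cost[i]
    }
  }
  funded
}

#' Funding decision rules
#'
#' The two counterfactual (PSI-absent) and four threshold-based (PSI-active)
#' rules. Each takes a [candidate set][sample_candidates] and returns a
#' `"portfolio"`: a funded mask aligned to arrival order, the rule id, and
#' the cumulative funded cost `spent` (in cost units, thousands of
#' currency; see [intervention_cost()]).
#'
#' * `rule_fcfs_count(cs, n)`: fund the first `min(n, N)` arrivals.
#' * `rule_fcfs_budget(cs, budget)`: fund each arrival in turn iff its
#'   population-scaled cost still fits within `budget`.
#' * `rule_threshold(cs, t)`: fund iff the cost-effectiveness ratio
#'   `C/Q <= t`; no budget limit.
#' * `rule_threshold_budget(cs, t, budget)`: fund iff `C/Q <= t` and the
#'   cost fits within `budget`.
#' * `rule_threshold_partial(cs, t, budget, capacity_pct)`: interventions
#'   whose population-scaled cost is at or above the
#'   `(100 - capacity_pct)`-th percentile of the candidate costs (the
#'   highest budget-impact `capacity_pct` percent) are assessed against the
#'   threshold; the rest are funded first-come-first-served; one shared
#'   budget.
#' * `rule_threshold_phased(cs, t, budget, phase_target_pct, year,
#'   phase_years)`: as `rule_threshold_partial` with the reviewed
#'   percentage `r = phase_target_pct * year / phase_years` for the current
#'   cycle of a phased PSI build-up.
#'
#' `budget` is in cost units; ties at the threshold (`C/Q == t`) are
#' funded; ties at the percentile cutoff count as high budget impact.
#'
#' @param candidates a `"candidate_set"` (or data frame with columns
#'   `P`, `C`, `Q`).
#' @param n number of interventions the count-based counterfactual funds.
#' @param budget budget limit in cost units (thousands of currency).
#' @param t cost-effectiveness threshold (currency per benefit unit).
#' @param capacity_pct percentage of highest budget-impact interventions
#'   assessed, in `[0, 100]`.
#' @param phase_target_pct,year,phase_years phased run-in schedule: target
#'   percentage in the final year, current cycle (1-based) and horizon.
#' @return A `"portfolio"` object.
#' @name funding_rules
#' @examples
#' cs <- sample_candidates(psi_preset("uk"), rho = 0.5, seed = 7)
#' rule_threshold(cs, t = 20000)
NULL

#' @rdname funding_rules
#' @export
rule_fcfs_count <- function(candidates, n) {
  stopifnot(n >= 0)
  N <- nrow(candidates)
  funded <- seq_len(N) <= n
  .new_portfolio(funded, "fcfs_count",
                 sum(intervention_cost(candidates$P, candidates$C)[funded]))
}

#' @rdname funding_rules
#' @export
rule_fcfs_budget <- function(candidates, budget) {
  stopifnot(budget >= 0)
  cost <- intervention_cost(candidates$P, candidates$C)
  funded <- .budget_scan(cost, rep(TRUE, length(cost)), budget)
  .new_portfolio(funded, "fcfs_budget", sum(cost[funded]))
}

#' @rdname funding_rules
#' @export
rule_threshold <- function(candidates, t) {
  stopifnot(t > 0)
  funded <- candidates$C / candidates$Q <= t
  .new_portfolio(funded, "threshold",
                 sum(intervention_cost(candidates$P, candidates$C)[funded]))
}

#' @rdname funding_rules
#' @export
rule_threshold_budget <- function(candidates, t, budget) {
  stopifnot(t > 0, budget >= 0)
  cost <- intervention_cost(candidates$P, candidates$C)
  funded <- .budget_scan(cost, candidates$C / candidates$Q <= t, budget)
  .new_portfolio(funded, "threshold_budget", sum(cost[funded]))
}

#' High budget-impact percentile cutoff
#'
#' The `(100 - pct)`-th percentile of the population-scaled candidate
#' costs, under the nearest-rank convention: with distinct values exactly
#' `ceiling(pct * N / 100)` candidates sit at or above the returned cutoff.
#' `pct = 0` returns `Inf` (no candidate selected); `pct = 100` returns the
#' minimum (all selected).
#'
#' @param costs numeric vector of population-scaled costs (`P * C`).
#' @param pct percentage of highest-cost candidates to select, in
#'   `[0, 100]`.
#' @return The cutoff value (scalar).
#' @export
high_value_cutoff <- function(costs, pct) {
  stopifnot(is.numeric(costs), length(costs) >= 1L, pct >= 0, pct <= 100)
  k <- ceiling(pct * length(costs) / 100)
  if (k == 0) return(Inf)
  sort(costs, decreasing = TRUE)[k]
}

#' @rdname funding_rules
#' @export
rule_threshold_partial <- function(candidates, t, budget, capacity_pct) {
  stopifnot(t > 0, budget >= 0, capacity_pct >= 0, capacity_pct <= 100)
  cost <- intervention_cost(candidates$P, candidates$C)
  cutoff <- high_value_cutoff(cost, capacity_pct)
  reviewed <- cost >= cutoff
  eligible <- !reviewed | candidates$C / candidates$Q <= t
  funded <- .budget_scan(cost, eligible, budget)
  .new_portfolio(funded, "threshold_partial", sum(cost[funded]))
}

#' @rdname funding_rules
#' @export
rule_threshold_phased <- function(candidates, t, budget, phase_target_pct,
                                  year, phase_years) {
  stopifnot(phase_years >= 1, year >= 1, year <= phase_years,
            phase_target_pct >= 0, phase_target_pct <= 100)
  p <- rule_threshold_partial(candidates, t, budget,
                              phase_target_pct * year / phase_years)
  p$rule_id <- "threshold_phased"
  p
}

#' Apply a funding rule by identifier
#'
#' Dispatches on the string rule ids used in configurations and on the
#' command line: `"fcfs_count"`, `"fcfs_budget"`, `"threshold"`,
#' `"threshold_budget"`, `"threshold_partial"`, `"threshold_phased"`.
#' Parameters are drawn from `config` (`year` is only needed for the phased
#' rule).
#'
#' @param candidates a `"candidate_set"`.
#' @param rule rule identifier string.
#' @param config a `"country_config"` supplying `t`, `budget`, `n_funded`,
#'   `capacity_pct` and the phase schedule.
#' @param year current cycle for `"threshold_phased"` (default 1).
#' @return A `"portfolio"`.
#' @export
apply_rule <- function(candidates, rule, config, year = 1L) {
  budget <- .budget_cost_units(config)
  switch(match.arg(rule, c("fcfs_count", "fcfs_budget", "threshold",
                           "threshold_budget", "threshold_partial",
                           "threshold_phased")),
    fcfs_count = rule_fcfs_count(candidates, config$n_funded),
    fcfs_budget = rule_fcfs_budget(candidates, budget),
    threshold = rule_threshold(candidates, config$threshold),
    threshold_budget = rule_threshold_budget(candidates, config$threshold, budget),
    threshold_partial = rule_threshold_partial(candidates, config$threshold,
                                               budget, config$capacity_pct),
    threshold_phased = rule_threshold_phased(candidates, config$threshold,
                                             budget, config$phase_target_pct,
                                             year, config$phase_years))
}
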