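## Simulation engine: pairs a PSI-active rule with its PSI-absent
## counterfactual on identical candidate sets, over many seeded funding
## cycles and a sweep of cost-benefit correlation levels.

.case_rules <- list(
  i   = c(active = "threshold",         counterfactual = "fcfs_count"),
  ii  = c(active = "threshold_budget",  counterfactual = "fcfs_budget"),
  iii = c(active = "threshold_partial", counterfactual = "fcfs_budget"),
  iv  = c(active = "threshold_phased",  counterfactual = "fcfs_budget"))

## counter-based seed derivation: any (rho level, simulation, cycle) cell is
## reproducible in isolation from the master seed
.derive_seed <- function(master, ...) {
  x <- abs(as.double(master)) %% 2147483647
  for (k in c(...))
    x <- (x * 48271 + (as.double(k) + 1) * 2654435761) %% 2147483647
  as.integer(x %% 2147483646) + 1L
}

## reviewed-intervention count for the HTA-overhead option
.n_reviewed <- function(candidates, rule, config, year) {
  switch(rule,
    threshold = ,
    threshold_budget = nrow(candidates),
    threshold_partial = {
      cost <- intervention_cost(candidates$P, candidates$C)
      sum(cost >= high_value_cutoff(cost, config$capacity_pct))
    },
    threshold_phased = {
      cost <- intervention_cost(candidates$P, candidates$C)
      r <- config$phase_target_pct * year / config$phase_years
      sum(cost >= high_value_cutoff(cost, r))
    },
    0L)
}

#' Run a paired priority-setting simulation
#'
#' The main entry point. For each correlation level in `rho` and each of
#' `n_sims` simulated funding cycles, a fresh candidate set is sampled and
#' both the PSI-active rule and its PSI-absent counterfactual are applied
#' to that identical set:
#'
#' * case `"i"`: threshold rule vs. count-based first-come-first-served;
#' * case `"ii"`: threshold + budget limit vs. budget-limited FCFS;
#' * case `"iii"`: threshold applied only to the `capacity_pct` percent of
#'   highest budget-impact interventions (budget-limited) vs. budget-limited
#'   FCFS;
#' * case `"iv"`: phased run-in -- `phase_years` consecutive cycles with the
#'   reviewed percentage growing linearly to `phase_target_pct`, costs and
#'   benefits summed across the cycles of one simulation before comparison
#'   -- vs. budget-limited FCFS.
#'
#' If `config$hta_unit_cost > 0` the running cost of the assessments
#' themselves is added to the active scenario's total cost
#' (see [apply_hta_overhead()]).
#'
#' @param config a `"country_config"` (e.g. from [psi_preset()]).
#' @param case comparison case, one of `"i"`, `"ii"`, `"iii"`, `"iv"`.
#' @param n_sims number of simulated funding cycles per correlation level.
#' @param rho correlation levels between untransformed cost and benefit per
#'   case; default the standard low/medium/high sweep.
#' @param seed master seed; every candidate set's seed is derived from it,
#'   so identical calls reproduce identical results.
#' @param phase_detail for case `"iv"`: also keep per-cycle records
#'   (component `cycle_records`).
#' @return An object of class `"psi_sim"`: a list with `records` (one row
#'   per correlation level and simulation: scenario totals, increments,
#'   NHB, ICER, quadrant), `config`, `case`, `rules`, `n_sims`, `rho`,
#'   `seed`, `call`. Methods: `print`, `summary`, `plot`,
#'   `as.data.frame`.
#' @examples
#' fit <- psi_sim(psi_preset("uk"), case = "i", n_sims = 50, rho = 0.2, seed = 1)
#' summary(fit)
#' @export
psi_sim <- function(config, case = c("i", "ii", "iii", "iv"),
                    n_sims = 1000, rho = c(0.2, 0.5, 0.8), seed = 1L,
                    phase_detail = FALSE) {
  stopifnot(inherits(config, "country_config"), n_sims >= 1,
            length(rho) >= 1, all(rho >= -1 & rho <= 1))
  case <- match.arg(case)
  rules <- .case_rules[[case]]
  cycles <- if (case == "iv") config$phase_years else 1L
  overhead <- config$hta_unit_cost > 0

  rows <- vector("list", length(rho) * n_sims)
  cycle_rows <- if (phase_detail && case == "iv") list() else NULL
  k <- 0L
  for (ri in seq_along(rho)) {
    for (s in seq_len(n_sims)) {
      act_cost <- act_ben <- act_n <- 0
      cf_cost <- cf_ben <- cf_n <- 0
      for (y in seq_len(cycles)) {
        cs_seed <- .derive_seed(seed, ri, s, y)
        cs <- sample_candidates(config, rho[ri], cs_seed)
        act <- portfolio_totals(cs, apply_rule(cs, rules[["active"]], config, year = y))
        cf <- portfolio_totals(cs, apply_rule(cs, rules[["counterfactual"]], config))
        if (overhead)
          act <- apply_hta_overhead(act, config$hta_unit_cost,
                                    .n_reviewed(cs, rules[["active"]], config, y))
        if (!is.null(cycle_rows)) {
          cmp_y <- compare_outcomes(act, cf, config$threshold)
          cycle_rows[[length(cycle_rows) + 1L]] <- data.frame(
            rho = rho[ri], sim = s, year = y,
            cf_cost = cf$total_cost, cf_benefit = cf$total_benefit,
            act_cost = act$total_cost, act_benefit = act$total_benefit,
            delta_cost = cmp_y$delta_cost, delta_benefit = cmp_y$delta_benefit,
            nhb = cmp_y$nhb)
        }
        act_cost <- act_cost + act$total_cost
        act_ben <- act_ben + act$total_benefit
        act_n <- act_n + act$funded_count
        cf_cost <- cf_cost + cf$total_cost
        cf_ben <- cf_ben + cf$total_benefit
        cf_n <- cf_n + cf$funded_count
      }
      d_cost <- act_cost - cf_cost
      d_ben <- act_ben - cf_ben
      k <- k + 1L
      rows[[k]] <- data.frame(
        rho = rho[ri], sim = s,
        cf_cost = cf_cost, cf_benefit = cf_ben, cf_count = cf_n,
        cf_cer = if (cf_ben > 0) cf_cost / cf_ben else NA_real_,
        act_cost = act_cost, act_benefit = act_ben, act_count = act_n,
        act_cer = if (act_ben > 0) act_cost / act_ben else NA_real_,
        delta_cost = d_cost, delta_benefit = d_ben,
        nhb = d_ben - d_cost * 1000 / config$threshold,
        icer = if (d_ben != 0) d_cost / d_ben else NA_real_,
        quadrant = if (d_cost >= 0) {
          if (d_ben < 0) "cost_up_benefit_down" else "cost_up_benefit_up"
        } else {
          if (d_ben < 0) "cost_down_benefit_down" else "cost_down_benefit_up"
        })
    }
  }
  out <- list(records = do.call(rbind, rows), config = config, case = case,
              rules = rules, n_sims = n_sims, rho = rho,
              seed = as.integer(seed), call = match.call())
  if (!is.null(cycle_rows)) out$cycle_records <- do.call(rbind, cycle_rows)
  class(out) <- "psi_sim"
  out
}

#' @export
as.data.frame.psi_sim <- function(x, ...) x$records

#' @export
print.psi_sim <- function(x, ...) {
  cat(sprintf("Priority-setting simulation, case (%s): %s vs %s\n",
              x$case, x$rules[["active"]], x$rules[["counterfactual"]]))
  cat(sprintf("  setting '%s', %d simulated cycles at rho = {%s}, seed %d\n",
              x$config$name, x$n_sims, paste(x$rho, collapse = ", "), x$seed))
  nhb <- tapply(x$records$nhb, x$records$rho, mean)
  cat(sprintf("  mean NHB (thousand %ss/cycle): %s\n", x$config$benefit_unit,
              paste(sprintf("%g at rho=%s", round(nhb, 1), names(nhb)),
                    collapse = ", ")))
  invisible(x)
}

#' Summarise a priority-setting simulation
#'
#' Aggregates the per-simulation records into the headline comparison: for
#' each correlation level, the mean total cost (currency millions), mean
#' total benefit (thousands), mean funded count and expected
#' cost-effectiveness ratio against doing nothing (mean over simulations of
#' the per-simulation ratio, in thousands of currency per benefit unit) of
#' each scenario, and the expected net health benefit
#' `mean(dBenefit) - mean(dCost)/t` (identical, by linearity, to the mean
#' of per-simulation NHB). A quadrant classification table (see
#' [quadrant_table()]) is attached per correlation level.
#'
#' @param object a `"psi_sim"` object.
#' @param ... unused.
#' @return An object of class `"summary.psi_sim"` with components `table`
#'   (one row per correlation level) and `quadrants` (named list of 2 x 2
#'   percentage matrices).
#' @export
summary.psi_sim <- function(object, ...) {
  rec <- object$records
  per_rho <- lapply(split(rec, rec$rho), function(r) {
    data.frame(
      rho = r$rho[1],
      cf_cost = mean(r$cf_cost), act_cost = mean(r$act_cost),
      cf_benefit = mean(r$cf_benefit), act_benefit = mean(r$act_benefit),
      cf_count = mean(r$cf_count), act_count = mean(r$act_count),
      cf_icer = mean(r$cf_cer, na.rm = TRUE),
      act_icer = mean(r$act_cer, na.rm = TRUE),
      nhb = mean(r$delta_benefit) -
        mean(r$delta_cost) * 1000 / object$config$threshold)
  })
  tab <- do.call(rbind, per_rho)
  rownames(tab) <- NULL
  structure(
    list(table = tab,
         quadrants = lapply(split(rec, rec$rho), quadrant_table),
         case = object$case, rules = object$rules,
         config = object$config, n_sims = object$n_sims),
    class = "summary.psi_sim")
}

#' @export
print.summary.psi_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Case (%s) on setting '%s': %s (Active) vs %s (Absent), %d simulations\n\n",
              x$case, cfg$name, x$rules[["active"]], x$rules[["counterfactual"]],
              x$n_sims))
  tab <- x$table
  disp <- data.frame(
    rho = tab$rho,
    `cost absent` = round(tab$cf_cost), `cost active` = round(tab$act_cost),
    `benefit absent` = round(tab$cf_benefit),
    `benefit active` = round(tab$act_benefit),
    `n absent` = round(tab$cf_count, 2), `n active` = round(tab$act_count, 2),
    `ICER absent` = signif(tab$cf_icer, 4), `ICER active` = signif(tab$act_icer, 4),
    NHB = round(tab$nhb), check.names = FALSE)
  print(disp, row.names = FALSE)
  cat(sprintf("\ncosts in %s millions; benefits and NHB in thousand %ss;\nICER vs doing nothing, thousand %s per %s (mean of per-simulation ratios)\n",
              cfg$currency, cfg$benefit_unit, cfg$currency, cfg$benefit_unit))
  for (r in names(x$quadrants)) {
    cat(sprintf("\nQuadrant percentages at rho = %s (rows: cost increment; cols: benefit increment)\n", r))
    print(round(x$quadrants[[r]], 1))
  }
  invisible(x)
}

#' Plot a priority-setting simulation
#'
#' Scatter of the per-simulation benefit increment against the cost
#' increment (the cost-effectiveness plane of the paired comparison), one
#' colour per correlation level, with the axes through the origin
#' separating the four sign quadrants.
#'
#' @param x a `"psi_sim"` object.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.psi_sim <- function(x, ...) {
  rec <- x$records
  cfg <- x$config
  cols <- grDevices::hcl.colors(length(x$rho), "Dark 3")
  ci <- match(rec$rho, x$rho)
  graphics::plot(rec$delta_cost, rec$delta_benefit, col = cols[ci], pch = 16,
                 cex = 0.5,
                 xlab = sprintf("Cost increment (%s millions)", cfg$currency),
                 ylab = sprintf("Benefit increment (thousand %ss)", cfg$benefit_unit),
                 main = sprintf("Case (%s), setting '%s'", x$case, cfg$name), ...)
  graphics::abline(h = 0, v = 0, lty = 2, col = "grey40")
  graphics::legend("topright", legend = paste("rho =", x$rho), col = cols,
                   pch = 16, bty = "n")
  invisible(x)
}

#' Sensitivity sweep over one decision parameter
#'
#' Re-runs [psi_sim()] over a grid of values of one parameter --
#' `"threshold"`, `"budget"`, `"capacity_pct"`, `"phase_target_pct"` or
#' `"rho"` -- and stacks the per-correlation summary rows, for
#' response-surface style sensitivity analysis.
#'
#' @param config a `"country_config"`.
#' @param case comparison case passed to [psi_sim()].
#' @param param parameter to sweep.
#' @param values numeric grid of parameter values.
#' @param n_sims,rho,seed passed to [psi_sim()] (`rho` is ignored when
#'   `param = "rho"`).
#' @return A data frame: the [summary.psi_sim()] table with a leading
#'   `param`/`value` column pair, one block per grid value.
#' @export
psi_sweep <- function(config, case = "i",
                      param = c("threshold", "budget", "capacity_pct",
                                "phase_target_pct", "rho"),
                      values, n_sims = 200, rho = 0.5, seed = 1L) {
  param <- match.arg(param)
  stopifnot(is.numeric(values), length(values) >= 1)
  out <- lapply(values, function(v) {
    cfg <- config
    r <- rho
    if (param == "rho") r <- v else cfg[[param]] <- v
    .check_config(unclass(cfg))
    tab <- summary(psi_sim(cfg, case = case, n_sims = n_sims, rho = r,
                           seed = seed))$table
    cbind(param = param, value = v, tab)
  })
  do.call(rbind, out)
}
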