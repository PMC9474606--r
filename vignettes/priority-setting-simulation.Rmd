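---
title: "Simulating the value of explicit health priority setting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the value of explicit health priority setting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psisim)
```

## The question and the model

A priority setting institution (PSI) is an agency — NICE in England and
HITAP in Thailand are the canonical examples — that makes health funding
decisions explicitly, on the basis of health technology assessments (HTAs).
Running one diverts money from frontline care, so a fair question is whether
it pays for itself. `psisim` addresses the question with a paired Monte-Carlo
portfolio simulation.

Each simulated funding cycle generates a set of `N` candidate interventions
`I_i = (P_i, C_i, Q_i)`: the impacted population (thousands of cases), the
incremental cost per case (currency units) and the incremental health
benefit per case (QALYs gained or DALYs averted). Two funding scenarios are
then applied *to the identical candidate set*:

* **PSI-active**: interventions are funded when their cost-effectiveness
  ratio `C_i / Q_i` is at or below a threshold `t`, optionally subject to a
  budget `l`, to a limited analysis capacity (only the `p_a` percent of
  candidates with the largest budget impact `P_i C_i` are assessed), or to a
  phased run-in of that capacity over `Y` cycles.
* **PSI-absent** (the counterfactual): no cost-effectiveness information
  exists, so interventions are funded first-come-first-served (FCFS) in
  their random arrival order — either the first `n` of them, or as many as
  fit within the budget `l`.

The paired difference in total cost and total benefit between the two
portfolios, accumulated over many cycles, is the simulated value of the
institution.

## Sampling model

`P`, `C` and `Q` are log-normal. Published inputs are natural-scale means
and standard deviations, so `lognormal_from_moments()` converts them by
exact moment matching (`exp(mu + sigma^2/2) = mean`,
`mean^2 (exp(sigma^2) - 1) = sd^2`). We read the published moments as
natural-scale summaries rather than log-scale parameters because their
magnitudes (a mean cost of thousands of currency units per case, a mean
population of hundreds of thousands of cases) are only sensible on the
natural scale, and because this reading reproduces the published
counterfactual cycle totals to within one percent.

Costs and benefits of an intervention are correlated; the correlation
`rho` is specified on the *untransformed* scale. We induce it with a
Gaussian copula: `latent_correlation()` solves in closed form for the
latent normal correlation `rho_z` such that the bivariate log-normal pair
has Pearson correlation exactly `rho`,

```
cor(C, Q) = (exp(rho_z s_C s_Q) - 1) / sqrt((exp(s_C^2)-1)(exp(s_Q^2)-1)).
```

This is the standard normal-to-anything construction; it hits the target
correlation exactly in expectation, which the test suite confirms
empirically to ±0.01 at one million draws. Targets beyond the attainable
bound (at `rho_z = 1`) are clipped with a warning. The population size `P`
is drawn independently of `(C, Q)` — the correlation is defined between
costs and benefits only.

The default correlation sweep is `rho = c(0.2, 0.5, 0.8)` — largely
independent, moderately dependent and strongly dependent costs and
benefits — because dependence is the single input users find hardest to
elicit, and sweeping it shows its leverage on the results.

## Decision rules and their conventions

All six rules scan candidates in arrival order (the sampling order); no
rule re-sorts, so the FCFS framing is preserved even for the threshold
rules. Three conventions deserve explicit statement:

* **Population-scaled budgets.** Budget-limited rules track the cumulative
  *total* cost `P_i C_i` of **funded** interventions only. A budget of tens
  of billions against per-case costs of thousands would never bind, so the
  per-case reading is vacuous; the budget-impact product is also what the
  capacity-limited rule itself ranks on.
* **Skip-and-continue.** A candidate that does not fit the remaining budget
  is rejected, consumes nothing, and scanning continues: a later, cheaper
  candidate can still be funded. This makes the rules order-dependent and
  creates genuine *opportunity loss* — the active scenario can occasionally
  end up worse than the counterfactual because an earlier funding decision
  exhausted the budget before a highly cost-effective candidate arrived.
  One consequence worth noting: the number funded under a budget-limited
  FCFS rule is *not* monotone in the budget (a larger budget can admit one
  expensive early candidate that crowds out several cheap later ones).
* **Ties.** A candidate exactly at the threshold (`C/Q == t`) is funded; a
  candidate exactly at the capacity percentile cutoff counts as high budget
  impact and is assessed. The cutoff itself uses the nearest-rank
  convention — with distinct costs, exactly `ceiling(p_a N / 100)`
  candidates are at or above it — because it is exact for small `N` and
  needs no interpolation choice.

The four shipped comparisons pair the rules as: (i) pure threshold vs
count-based FCFS; (ii) threshold + budget vs budget-limited FCFS; (iii)
capacity-limited threshold vs budget-limited FCFS; (iv) phased run-in vs
budget-limited FCFS. In case (iv) the reviewed percentage grows linearly,
`r = p_Y * y / Y` in cycle `y`, each cycle draws a fresh candidate set, and
costs and benefits are summed over the `Y` cycles of one simulation before
comparison (per-cycle records are available with `phase_detail = TRUE`).
No funded intervention carries over between cycles; modelling legacy
funding commitments is out of scope.

## Metrics and units

Unit bookkeeping is centralised and worth keeping in mind: populations in
thousands of cases; per-case costs and the threshold in natural currency;
budgets in currency millions; summary costs in currency millions; summary
benefits in thousands of QALYs/DALYs. Per correlation level, the summary
reports the mean of each scenario's totals, the expected
cost-effectiveness ratio against doing nothing (the mean over simulations
of the per-simulation ratio — mean-of-ratios, not ratio-of-means, which is
the reading consistent with the published tables; in thousands of currency
per benefit unit), the expected net health benefit

```
NHB = dQ - dC / t
```

(the cost increment valued at the threshold, in thousands of benefit
units; by linearity the mean of per-simulation NHB equals the NHB of the
means, and the suite asserts both to 1e-9), and the between-scenario ICER
`dC / dQ`, undefined (NA) when `dQ = 0`. Each simulation is also
classified into the sign quadrant of `(dC, dQ)`, with `>= 0` counting as a
positive increment; `quadrant_table()` tabulates the four cells as
percentages. Optionally the running cost of the assessments themselves
(`hta_unit_cost` per HTA, applied to the number of interventions actually
reviewed) can be added to the active scenario; it is off by default since
the headline comparison excludes it, and at published per-HTA costs it
amounts to a few hundredths of a percent of cycle totals.

## Reproducibility

Every candidate set's seed is derived deterministically from the master
seed and the (correlation level, simulation, cycle) counters, so a single
record can be regenerated in isolation and identical calls are bitwise
identical. `export_run()` writes `summary.csv`, `records.csv`,
`quadrants.csv` and a `manifest.json` (package version, case, seed,
configuration and its hash) sufficient to reproduce every output file
exactly — the manifest round-trip is part of the test suite.

## Shipped parameterisations

Two indicative presets ship as YAML under `inst/extdata/` and load with
`psi_preset()`:

```{r presets}
psi_preset("uk")
psi_preset("malawi")
```

These describe an established universal-coverage setting (74 candidates,
t = 20,000 GBP/QALY, 75,000 M budget, 48 funded) and a fledgling one (40
candidates, t = 2 USD/DALY, 120 M budget, 14 funded). They are indicative
of the *type* of intervention portfolio in each setting, not a statement
about actual national decisions.

## A small run

```{r run}
fit <- psi_sim(psi_preset("uk"), case = "i", n_sims = 200,
               rho = c(0.2, 0.5, 0.8), seed = 1)
summary(fit)
```

The pattern that matters: the active scenario spends less, gains more
health, and its advantage (the NHB row) shrinks as the cost–benefit
correlation rises — with strongly correlated costs and benefits, random
funding is less often badly wrong. The full-scale analyses in the test
suite use 1000 simulations per correlation level, which completes in a few
seconds.

```{r plot, fig.width = 6, fig.height = 4.5}
plot(fit)
```

## What the generator does and does not emulate

The generator reproduces the moments, skew and cost–benefit dependence of
intervention portfolios, which is what the funding rules act on. It does
not emulate: non-log-normal shapes (bimodality, point masses at zero
benefit), dependence between population size and cost or benefit, serial
correlation of candidates across cycles, or strategic behaviour (price
negotiation in response to a public threshold). Passing tests therefore
show that the decision rules and metrics behave correctly under the
stated stochastic model — not that any particular health system will
realise the simulated savings.

## Known limitations

* With identical marginal moments and correlation, the fledgling-setting
  counterfactual cost total simulates roughly 20% above the corresponding
  published value while every benefit total matches; the published
  cost-side fitting procedure for that data-set is not fully determined by
  its description, and the discrepancy is confined to that one cell. The
  acceptance tolerances for that setting are correspondingly wider.
* The counterfactual is a deliberately information-free extreme; real
  PSI-absent systems often have partial cost-effectiveness signals, so the
  simulated value of the institution is an upper-bound style benchmark.
* Greedy sequential rules are intentional (they model arrival-order
  decisions); no optimal-knapsack selection is attempted.
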