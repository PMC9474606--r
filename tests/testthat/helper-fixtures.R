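# Fixtures built in code, plus naive single-purpose re-implementations of
# the funding-rule definitions used as independent oracles for small N.

## candidate data frame from explicit columns (P defaults to 1 so that the
## population-scaled cost equals C)
make_candidates <- function(C, Q, P = rep(1, length(C))) {
  structure(data.frame(P = P, C = C, Q = Q),
            class = c("candidate_set", "data.frame"))
}

## small non-degenerate config for fast property tests
toy_config <- function(n = 8, budget = 0.2, threshold = 15,
                       n_funded = 4, capacity_pct = 50) {
  country_config(
    name = "toy", currency = "CUR", benefit_unit = "QALY",
    q_mean = 1, q_sd = 2, c_mean = 10, c_sd = 20, p_mean = 2, p_sd = 3,
    n_candidates = n, threshold = threshold, budget = budget,
    n_funded = n_funded, capacity_pct = capacity_pct,
    phase_years = 4, phase_target_pct = 80)
}

## ---- oracle rules: recompute the cumulative funded spend from scratch at
## every candidate, directly from the rule definitions -------------------

oracle_budget_walk <- function(cs, eligible, l) {
  funded <- logical(nrow(cs))
  for (i in seq_len(nrow(cs))) {
    spent_before <- sum((cs$P * cs$C)[funded])
    funded[i] <- eligible[i] && (spent_before + cs$P[i] * cs$C[i] <= l)
  }
  funded
}

oracle_fcfs_budget <- function(cs, l)
  oracle_budget_walk(cs, rep(TRUE, nrow(cs)), l)

oracle_threshold <- function(cs, t) cs$C / cs$Q <= t

oracle_threshold_budget <- function(cs, t, l)
  oracle_budget_walk(cs, cs$C / cs$Q <= t, l)

oracle_threshold_partial <- function(cs, t, l, pa) {
  tc <- cs$P * cs$C
  k <- ceiling(pa * length(tc) / 100)
  cutoff <- if (k == 0) Inf else sort(tc, decreasing = TRUE)[k]
  eligible <- ifelse(tc >= cutoff, cs$C / cs$Q <= t, TRUE)
  oracle_budget_walk(cs, eligible, l)
}
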