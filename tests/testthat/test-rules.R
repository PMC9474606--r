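test_that("population-scaled intervention cost multiplies cases by cost per case", {
  # 540.22 thousand cases at 9,140 currency units/case = 4,937,610.8
  # thousand currency units, i.e. 4,937.6 millions
  expect_equal(intervention_cost(540.22, 9140) / 1000, 4937.6, tolerance = 1e-4)
  expect_identical(intervention_cost(2, 3), 6)
})

test_that("count-based FCFS funds exactly the first min(n, N) arrivals", {
  cs <- make_candidates(C = runif(74, 1, 10), Q = runif(74, 1, 10))
  p <- rule_fcfs_count(cs, 48)
  expect_identical(which(p$funded), 1:48)
  expect_equal(p$spent, sum((cs$P * cs$C)[1:48]))
  expect_identical(sum(rule_fcfs_count(cs, 0)$funded), 0L)
  expect_identical(sum(rule_fcfs_count(cs, 79)$funded), 74L)
})

test_that("budget-based FCFS skips unaffordable arrivals and continues", {
  cs <- make_candidates(C = c(40, 80, 50), Q = c(1, 1, 1))
  p <- rule_fcfs_budget(cs, 100)
  expect_identical(which(p$funded), c(1L, 3L))
  expect_equal(p$spent, 90)
  expect_identical(sum(rule_fcfs_budget(cs, 0)$funded), 0L)
  expect_identical(sum(rule_fcfs_budget(cs, 170)$funded), 3L)
})

test_that("threshold rule funds iff per-case CER is at or below t", {
  cs <- make_candidates(C = c(10, 30, 20), Q = c(1, 1, 1))
  p <- rule_threshold(cs, 20)
  expect_identical(p$funded, c(TRUE, FALSE, TRUE))  # tie at t is funded
  expect_true(all(rule_threshold(cs, Inf)$funded))
})

test_that("threshold + budget rule exhibits skip-and-continue opportunity loss", {
  # (CER, total cost): (5, 60), (50, 10), (8, 50); t = 20, l = 100.
  # #2 fails the threshold; #3 passes it but exceeds the 40 remaining.
  cs <- make_candidates(C = c(60, 10, 50), Q = c(60 / 5, 10 / 50, 50 / 8))
  p <- rule_threshold_budget(cs, t = 20, budget = 100)
  expect_identical(which(p$funded), 1L)
  expect_equal(p$spent, 60)
})

test_that("high-value cutoff follows the nearest-rank-above convention", {
  v <- c(10, 20, 30, 40, 50)
  expect_identical(high_value_cutoff(v, 20), 50)
  expect_identical(sum(v >= high_value_cutoff(v, 20)), 1L)
  expect_identical(high_value_cutoff(v, 100), 10)
  expect_identical(high_value_cutoff(v, 0), Inf)
  expect_identical(high_value_cutoff(v, 50), 30)  # ceil(2.5) = 3 at/above
})

test_that("partial rule reviews only high budget-impact candidates", {
  # candidate 1 is high-impact and fails the threshold; candidate 2 is
  # low-impact and cheap: only the low-impact one is funded
  cs <- make_candidates(C = c(100, 1), Q = c(1, 1))
  p <- rule_threshold_partial(cs, t = 20, budget = 200, capacity_pct = 50)
  expect_identical(p$funded, c(FALSE, TRUE))
})

test_that("rule reduction identities hold on random candidate sets", {
  cfg <- toy_config()
  for (s in 1:100) {
    cs <- sample_candidates(cfg, rho = 0.5, seed = s)
    t <- exp(runif(1, -1, 3)); l <- exp(runif(1, 1, 6))
    # no budget pressure: threshold_budget == threshold
    expect_identical(rule_threshold_budget(cs, t, Inf)$funded,
                     rule_threshold(cs, t)$funded)
    # no threshold pressure: threshold_budget == fcfs_budget
    expect_identical(rule_threshold_budget(cs, Inf, l)$funded,
                     rule_fcfs_budget(cs, l)$funded)
    # full / zero analysis capacity
    expect_identical(rule_threshold_partial(cs, t, l, 100)$funded,
                     rule_threshold_budget(cs, t, l)$funded)
    expect_identical(rule_threshold_partial(cs, t, l, 0)$funded,
                     rule_fcfs_budget(cs, l)$funded)
    # mature phase == full review; zero target == FCFS in every year
    expect_identical(rule_threshold_phased(cs, t, l, 100, 5, 5)$funded,
                     rule_threshold_budget(cs, t, l)$funded)
    expect_identical(rule_threshold_phased(cs, t, l, 0, 3, 5)$funded,
                     rule_fcfs_budget(cs, l)$funded)
  }
})

test_that("budget feasibility and monotonicity hold on random candidate sets", {
  cfg <- toy_config()
  for (s in 1:60) {
    cs <- sample_candidates(cfg, rho = 0.2, seed = 1000 + s)
    l <- exp(runif(1, 1, 6))
    for (p in list(rule_fcfs_budget(cs, l),
                   rule_threshold_budget(cs, 15, l),
                   rule_threshold_partial(cs, 15, l, 50),
                   rule_threshold_phased(cs, 15, l, 80, 2, 4))) {
      expect_lte(p$spent, l)
      expect_equal(p$spent, sum((cs$P * cs$C)[p$funded]))
    }
    # raising t never drops a funded intervention (no budget limit)
    lo <- rule_threshold(cs, 5)$funded
    hi <- rule_threshold(cs, 50)$funded
    expect_true(all(hi[lo]))
    # a budget covering every candidate funds every candidate (tiny
    # headroom guards the floating-point accumulation order)
    expect_true(all(rule_fcfs_budget(cs, sum(cs$P * cs$C) * (1 + 1e-12))$funded))
  }
})

test_that("scan implementations agree with the brute-force rule walk for small N", {
  cfg <- toy_config(n = 8)
  for (s in 1:60) {
    cs <- sample_candidates(cfg, rho = 0.5, seed = 2000 + s)
    t <- exp(runif(1, -1, 3)); l <- exp(runif(1, 0, 6))
    pa <- sample(0:100, 1)
    expect_identical(rule_fcfs_budget(cs, l)$funded, oracle_fcfs_budget(cs, l))
    expect_identical(rule_threshold(cs, t)$funded, oracle_threshold(cs, t))
    expect_identical(rule_threshold_budget(cs, t, l)$funded,
                     oracle_threshold_budget(cs, t, l))
    expect_identical(rule_threshold_partial(cs, t, l, pa)$funded,
                     oracle_threshold_partial(cs, t, l, pa))
  }
})

test_that("apply_rule dispatches on string identifiers with config parameters", {
  cfg <- toy_config()
  cs <- sample_candidates(cfg, rho = 0.5, seed = 77)
  budget <- cfg$budget * 1000
  expect_identical(apply_rule(cs, "fcfs_count", cfg)$funded,
                   rule_fcfs_count(cs, cfg$n_funded)$funded)
  expect_identical(apply_rule(cs, "threshold_budget", cfg)$funded,
                   rule_threshold_budget(cs, cfg$threshold, budget)$funded)
  expect_identical(apply_rule(cs, "threshold_phased", cfg, year = 2)$funded,
                   rule_threshold_phased(cs, cfg$threshold, budget,
                                         cfg$phase_target_pct, 2,
                                         cfg$phase_years)$funded)
  expect_error(apply_rule(cs, "knapsack", cfg))
})
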