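test_that("stable-state exit allocation follows the stated arithmetic", {
  expect_equal(unname(build_transition_row(0.5, 0.2, 0)), c(0.5, 0.3, 0, 0.2))
  expect_equal(unname(build_transition_row(0, 0, 0)), c(1, 0, 0, 0))
  # background mortality floors the death probability
  expect_equal(unname(build_transition_row(0.1, 0.02, 0.3)), c(0.7, 0, 0, 0.3))
  # same-cycle death is never double-counted into progression
  expect_equal(unname(build_transition_row(0.1, 0.4, 0)), c(0.6, 0, 0, 0.4))
  expect_error(build_transition_row(1.2, 0, 0), "probabilities")
})

test_that("cohort trace conserves occupancy with absorbing, monotone death", {
  inp <- build_cea_inputs(run_config("primary"))
  for (st in inp$strategies) {
    tr <- run_cohort(st, inp$settings, inp$life_table, inp$utilities, inp$profile)$trace
    occ <- as.matrix(tr[, c("stable", "prog1", "prog2", "death")])
    expect_true(all(abs(rowSums(occ) - 1) < 1e-9))
    expect_true(all(occ >= 0 & occ <= 1 + 1e-12))
    expect_true(all(diff(tr$death) >= 0))
    expect_true(all(diff(tr$stable) <= 1e-12))
  }
})

test_that("an event-free cohort at unit utility accrues one QALY per year undiscounted", {
  st <- null_strategy()
  set <- model_settings(horizon_years = 1, discount_annual = 0)
  res <- run_cohort(st, set, flat_life_table(), unit_utilities)
  expect_equal(res$total_qalys, n_cycles(set) * 21 / 365.25, tolerance = 1e-9)
  expect_equal(res$total_cost, 0)
})

test_that("discounting and horizon shrink totals monotonically", {
  inp <- build_cea_inputs(run_config("primary"))
  r0 <- run_cohort(inp$strategies$CPC,
                   model_settings(discount_annual = 0), inp$life_table,
                   inp$utilities, inp$profile)
  r5 <- run_cohort(inp$strategies$CPC, inp$settings, inp$life_table,
                   inp$utilities, inp$profile)
  expect_gt(r0$total_qalys, r5$total_qalys)
  expect_gt(r0$total_cost, r5$total_cost)

  short <- run_cohort(inp$strategies$CPC,
                      model_settings(horizon_years = 10), inp$life_table,
                      inp$utilities, inp$profile)
  expect_lte(short$total_qalys, r5$total_qalys)
  expect_lte(short$total_cost, r5$total_cost)
})

test_that("unit hazard ratios make the indirect arm trace the reference arm", {
  cfg <- set_param(set_param(run_config("secondary"), "hr_os_ppp", 1),
                   "hr_pfs_ppp", 1)
  inp <- build_cea_inputs(cfg)
  tr_cpc <- run_cohort(inp$strategies$CPC, inp$settings, inp$life_table,
                       inp$utilities, inp$profile)$trace
  tr_ppp <- run_cohort(inp$strategies$PPP, inp$settings, inp$life_table,
                       inp$utilities, inp$profile)$trace
  for (col in c("stable", "prog1", "prog2", "death"))
    expect_equal(tr_ppp[[col]], tr_cpc[[col]], tolerance = 1e-12)
})

test_that("cohort totals match the individual-level simulation oracle", {
  inp <- build_cea_inputs(run_config("primary"))
  for (st in inp$strategies) {
    co <- run_cohort(st, inp$settings, inp$life_table, inp$utilities, inp$profile)
    ms <- run_microsim(st, inp$settings, inp$life_table, inp$utilities,
                       inp$profile, n_subjects = 10000, seed = 4)
    expect_lt(abs(ms$total_cost - co$total_cost) / co$total_cost, 0.01)
    expect_lt(abs(ms$total_qalys - co$total_qalys) / co$total_qalys, 0.01)
  }
})

test_that("incremental comparison reproduces published-table arithmetic", {
  mk <- function(name, cost, q) list(strategy = name, total_cost = cost, total_qalys = q)
  ce <- compare_strategies(list(mk("PC", 8082, 1.16), mk("CPC", 11519, 1.57)),
                           wtp = 11146)
  expect_equal(ce$icer[2], (11519 - 8082) / (1.57 - 1.16))
  expect_equal(ce$icer[2], 8382.9, tolerance = 1e-4)
  expect_true(ce$cost_effective[2])

  same <- compare_strategies(list(mk("A", 100, 1), mk("B", 100, 1)))
  expect_true(is.na(same$icer[2]))
  expect_equal(same$d_cost[2], 0)

  simple <- compare_strategies(list(mk("A", 0, 1), mk("B", 100, 1.5)))
  expect_equal(simple$icer[2], 200)

  dom <- compare_strategies(list(mk("A", 100, 1), mk("B", 50, 1.5)))
  expect_equal(dom$dominance[2], "dominant")
})
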