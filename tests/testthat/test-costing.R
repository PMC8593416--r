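test_that("dose arithmetic follows the dosing rule", {
  prof <- patient_profile(weight = 65, bsa = 1.72)
  expect_equal(dose_amount("per_kg", 4.5, prof), 292.5)
  expect_equal(dose_amount("per_bsa", 500, prof), 860)
  expect_equal(dose_amount("flat_per_cycle", 200, prof), 200)
  expect_error(dose_amount("per_dose", 1, prof), "rule")
})

test_that("paid-cycle caps and duration caps zero out drug cost", {
  inp <- build_cea_inputs(run_config("secondary"))
  ppp <- inp$strategies$PPP
  pem_cost <- 79.31
  # pembrolizumab is paid for cycles 1-4 only
  expect_equal(cycle_drug_cost(ppp, "first", 1:4, inp$profile),
               rep(2597.79 + pem_cost, 4))
  expect_equal(cycle_drug_cost(ppp, "first", 5, inp$profile), pem_cost)
  # beyond the line's duration cap everything is 0
  expect_equal(cycle_drug_cost(ppp, "first", ppp$first_line_cap + 1, inp$profile), 0)
  # total paid pembrolizumab spend is 4 cycles regardless of cap (>= 4)
  pem_only <- vapply(1:60, function(cy)
    cycle_drug_cost(ppp, "first", cy, inp$profile) - c(pem_cost, 0)[1 + (cy > ppp$first_line_cap)],
    numeric(1))
  expect_equal(sum(pem_only), 4 * 2597.79)
})

test_that("per-kg and per-BSA drugs rescale with the patient profile", {
  niv <- drug_cost("nivolumab", 60.35, "per_kg", dose = 4.5)
  st <- strategy_spec("x", first_line = list(niv), first_line_cap = 10,
                      models = NULL)
  heavy <- patient_profile(weight = 78)
  expect_equal(cycle_drug_cost(st, "first", 1, heavy), 60.35 * 78 / 65)
})

test_that("state cost and utility composition match the stated rules", {
  inp <- build_cea_inputs(run_config("primary"))
  cpc <- inp$strategies$CPC
  u <- inp$utilities
  # stable on first-line treatment: utility minus AE disutility
  expect_equal(state_cycle_utility(cpc, "stable", TRUE, u), 0.856 - 0.079)
  expect_equal(state_cycle_utility(cpc, "stable", FALSE, u), 0.856)
  expect_equal(state_cycle_utility(cpc, "death", TRUE, u), 0)
  # second progression with no active third-line therapy: BSC + follow-up
  cpc0 <- cpc; cpc0$frac_3l <- 0
  expect_equal(state_cycle_cost(cpc0, "prog2", 1), 337.50 + 55.60)
  # death costs nothing per cycle (end-of-life is charged on entry)
  expect_equal(state_cycle_cost(cpc, "death", 1), 0)
  expect_error(state_cycle_cost(cpc, "cured", 1))
})

test_that("zeroing every cost parameter yields zero total cost", {
  cfg <- run_config("primary")
  for (nm in cfg$params$name[startsWith(cfg$params$name, "cost_")])
    cfg$params[cfg$params$name == nm, c("base", "low", "high")] <- 0
  ce <- run_base_case(cfg)
  expect_equal(ce$cost, c(0, 0))
  expect_gt(ce$qalys[2], 0)
})

test_that("utilities stay within [0, 1] even for extreme disutilities", {
  st <- strategy_spec("x", first_line = list(), first_line_cap = 5,
                      ae_disutility = 0.99)
  expect_gte(state_cycle_utility(st, "stable", TRUE, list(stable = 0.5)), 0)
})
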