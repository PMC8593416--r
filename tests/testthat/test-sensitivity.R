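test_that("moment-matched samplers recover the base value and range", {
  fx <- build_distribution("d", 0.05, dist = "fixed")
  expect_equal(fx$sample(5), rep(0.05, 5))

  set.seed(1)
  g <- build_distribution("cost", 424.51, 212.25, 636.76, "gamma")
  expect_equal(unname(g$hyper["shape"] / g$hyper["rate"]), 424.51)
  expect_lt(abs(mean(g$sample(1e5)) - 424.51) / 424.51, 0.01)

  b <- build_distribution("u", 0.856, 0.718, 0.994, "beta")
  m <- unname(b$hyper["shape1"] / sum(b$hyper))
  expect_equal(m, 0.856, tolerance = 1e-12)
  sdd <- sqrt(prod(b$hyper) / (sum(b$hyper)^2 * (sum(b$hyper) + 1)))
  expect_equal(sdd, (0.994 - 0.718) / 3.92, tolerance = 1e-10)
  expect_lt(abs(mean(b$sample(1e5)) - 0.856) / 0.856, 0.01)

  ln <- build_distribution("hr", 0.71, 0.57, 0.85, "lognormal")
  qs <- quantile(ln$sample(2e5), c(0.025, 0.5, 0.975))
  expect_equal(unname(qs[2]), 0.71, tolerance = 0.02)
  expect_equal(unname(qs[1]), 0.57, tolerance = 0.03)
  expect_equal(unname(qs[3]), 0.85, tolerance = 0.03)

  expect_warning(build_distribution("u", 0.5, -3, 4, "beta"), "infeasible")
})

test_that("one-way DSA spreads are zero for parameters outside the comparison", {
  cfg <- run_config("primary")
  out <- one_way_dsa(cfg, params = c("cost_pembrolizumab", "du_ppp", "cost_ae_cpc"))
  expect_equal(out$spread[out$param == "cost_pembrolizumab"], 0)
  expect_equal(out$spread[out$param == "du_ppp"], 0)
  expect_gt(out$spread[out$param == "cost_ae_cpc"], 0)
  # base ICER column is the unperturbed ICER for every row
  expect_equal(unique(out$icer_base), base_icer(cfg))
})

test_that("threshold search returns the fixed point when WTP equals the base ICER", {
  cfg <- run_config("primary")
  icer0 <- base_icer(cfg)
  thr <- threshold_search(cfg, "cost_camrelizumab", wtp = icer0,
                          bracket = c(212.25, 1000))
  expect_equal(thr, 424.51, tolerance = 1e-3)
  # post-condition: the ICER at the returned value matches the target WTP
  expect_lt(abs(base_icer(set_param(cfg, "cost_camrelizumab", thr)) - icer0) / icer0,
            1e-3)
})

test_that("threshold search reports absence of a crossing", {
  cfg <- run_config("primary")
  expect_message(
    res <- threshold_search(cfg, "cost_followup", bracket = c(27.80, 83.40)),
    "no ICER")
  expect_true(is.na(res))
})

test_that("degenerate distributions reproduce the base case in every PSA iteration", {
  cfg <- run_config("primary")
  cfg$params$dist <- "fixed"
  base <- run_base_case(cfg)
  psa <- run_psa(cfg, n = 4, seed = 1)
  for (i in 1:4) {
    it <- psa$draws[psa$draws$iteration == i, ]
    expect_equal(it$cost, base$cost, tolerance = 1e-12)
    expect_equal(it$qalys, base$qalys, tolerance = 1e-12)
  }
})

test_that("PSA is reproducible given the seed", {
  cfg <- run_config("primary")
  a <- run_psa(cfg, n = 5, seed = 42)
  b <- run_psa(cfg, n = 5, seed = 42)
  expect_identical(a$draws, b$draws)
})

test_that("CEAC probabilities are bounded, complementary, and pick min cost at WTP 0", {
  cfg <- run_config("primary")
  psa <- run_psa(cfg, n = 40, seed = 2)
  cc <- ceac(psa, wtp_grid = c(0, 11146, 40000))
  expect_true(all(cc$prob >= 0 & cc$prob <= 1))
  sums <- tapply(cc$prob, cc$wtp, sum)
  expect_true(all(abs(sums - 1) < 1e-12))

  fixed <- cfg; fixed$params$dist <- "fixed"
  p0 <- ceac(run_psa(fixed, n = 3, seed = 1), wtp_grid = 0)
  expect_equal(p0$prob[p0$strategy == "PC"], 1)  # cheaper strategy certain at WTP 0
})
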