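test_that("survival is 1 at t = 0 and non-increasing for every model-table law", {
  for (m in table1_models()) {
    expect_equal(surv_prob(m, 0), 1)
    s <- surv_prob(m, seq(0, 520, by = 0.5))
    expect_true(all(diff(s) <= 0))
    expect_true(all(s > 0 & s <= 1))
  }
  expect_equal(surv_prob(loglogistic_model(0.03905, 1.36768, variant = "exp_theta"), 0), 1)
})

test_that("log-logistic survival matches closed-form values", {
  # exp(0) = 1: S(1) = 1/(1 + 1) under the exp_theta reading
  expect_equal(loglogistic_survival(0, 1, 1, variant = "exp_theta"), 0.5)
  # direct evaluation, raw-theta reading
  expect_equal(loglogistic_survival(0.01503, 1.46627, 10), 0.6945537, tolerance = 1e-6)
  # model-object route agrees with the flat function
  expect_equal(surv_prob(loglogistic_model(0.01503, 1.46627), 10),
               loglogistic_survival(0.01503, 1.46627, 10))
})

test_that("per-cycle probability satisfies P(t) = 1 - S(t)/S(t-1) to machine precision", {
  tt <- 1:520
  for (m in c(table1_models(),
              list(hr_adjust(loglogistic_model(0.01503, 1.46627), 0.92),
                   hr_adjust(weibull_model(0.07471, 1.15519), 0.76)))) {
    expect_equal(cycle_prob(m, tt),
                 1 - surv_prob(m, tt) / surv_prob(m, tt - 1),
                 tolerance = 1e-12)
    expect_true(all(cycle_prob(m, tt) >= 0 & cycle_prob(m, tt) < 1))
  }
  expect_equal(loglogistic_cycle_prob(0, 1, 1, variant = "exp_theta"), 0.5)
  # independent brute-force check of one interior value
  s4 <- 1 / (1 + 0.03905 * 4^1.36768)
  s5 <- 1 / (1 + 0.03905 * 5^1.36768)
  expect_equal(loglogistic_cycle_prob(0.03905, 1.36768, 5), 1 - s5 / s4)
  expect_equal(loglogistic_cycle_prob(0.03905, 1.36768, 5), 0.06859953, tolerance = 1e-6)
})

test_that("hazard-ratio adjustment is a power on survival and the identity at HR = 1", {
  m <- loglogistic_model(0.01503, 1.46627)
  expect_identical(hr_adjusted_survival(0.01503, 1.46627, 1, 7),
                   loglogistic_survival(0.01503, 1.46627, 7))
  expect_equal(hr_adjusted_survival(0, 1, 2, 1, variant = "exp_theta"), 0.25)
  expect_equal(hr_adjusted_cycle_prob(0, 1, 2, 1, variant = "exp_theta"), 0.75)
  expect_equal(hr_adjusted_survival(0.01503, 1.46627, 0.92, 10),
               0.7151043, tolerance = 1e-6)
  expect_equal(hr_adjusted_cycle_prob(0.01503, 1.46627, 0.74, 3),
               0.02330795, tolerance = 1e-6)
  expect_equal(cycle_prob(hr_adjust(m, 1), 1:100), cycle_prob(m, 1:100))
})

test_that("Weibull survival matches closed-form values in both parameterisations", {
  expect_equal(weibull_survival(0.07471, 1.15519, 0), 1)
  expect_equal(weibull_survival(log(2), 1, 1), 0.5)
  expect_equal(weibull_survival(0.25070, 1.14230, 4), 0.2947926, tolerance = 1e-6)
  # aft form: S(t) = exp(-(t/scale)^shape)
  expect_equal(weibull_survival(2, 3, 1, form = "aft"), exp(-(1 / 2)^3))
})

test_that("median survival solves S(median) = 0.5", {
  for (m in c(table1_models(), list(hr_adjust(loglogistic_model(0.003326, 1.54225), 0.71)))) {
    expect_equal(surv_prob(m, median_survival(m)), 0.5, tolerance = 1e-10)
  }
})

test_that("invalid inputs are rejected", {
  expect_error(loglogistic_model(-0.1, 1), "theta")
  expect_error(loglogistic_model(0.1, -1), "kappa")
  expect_error(weibull_model(0, 1), "scale")
  expect_error(surv_prob(loglogistic_model(0.1, 1), -1), "t")
  expect_error(cycle_prob(loglogistic_model(0.1, 1), 0), "cycle")
  expect_error(hr_adjust(loglogistic_model(0.1, 1), 0), "hr")
})
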