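test_that("simulated IPD honours the censoring design", {
  m <- loglogistic_model(0.01503, 1.46627)
  ipd <- simulate_ipd(m, 50, seed = 1)
  expect_true(all(ipd$event == 1))
  expect_true(all(ipd$time >= 0))

  adm <- simulate_ipd(m, 20, censoring = "administrative", cens_max = 0, seed = 1)
  expect_true(all(adm$event == 0))
  expect_true(all(adm$time == 0))

  unif <- simulate_ipd(m, 500, censoring = "uniform", cens_max = 30, seed = 2)
  expect_true(any(unif$event == 0) && any(unif$event == 1))
  expect_true(all(unif$time <= 30))
})

test_that("same seed gives identical samples, different seeds differ", {
  m <- weibull_model(0.1, 1.2)
  expect_identical(simulate_ipd(m, 100, seed = 7), simulate_ipd(m, 100, seed = 7))
  expect_false(identical(simulate_ipd(m, 100, seed = 7),
                         simulate_ipd(m, 100, seed = 8)))
})

test_that("empirical median matches the closed-form log-logistic quantile", {
  th <- 0.01503; ka <- 1.46627
  ipd <- simulate_ipd(loglogistic_model(th, ka), 2000, seed = 11)
  analytic <- (1 / th)^(1 / ka)
  expect_lt(abs(median(ipd$time) - analytic) / analytic, 0.05)
})

test_that("KM construction gives the product-limit estimate with a valid risk table", {
  one <- km_with_risk_table(data.frame(time = 5, event = 1), interval = 3)
  expect_equal(one$surv[one$times < 5], 1)
  expect_equal(one$surv[one$times == 5], 0)

  ipd <- data.frame(time = 1:10, event = 1)
  km <- km_with_risk_table(ipd, interval = 2)
  expect_equal(diff(km$surv[km$times %in% 1:10]), rep(-0.1, 9))
  expect_true(all(diff(km$risk_table$n_risk) <= 0))
  expect_equal(km$risk_table$n_risk[1], 10)

  # DKW-style closeness to the analytic curve at deciles
  m <- loglogistic_model(0.01503, 1.46627)
  big <- km_with_risk_table(simulate_ipd(m, 500, seed = 3), interval = 3)
  dec <- quantile(big$times[-1], probs = seq(0.1, 0.9, 0.1))
  km_at <- stats::approx(big$times, big$surv, xout = dec, method = "constant")$y
  expect_lt(max(abs(km_at - surv_prob(m, dec))), 0.03)
})

test_that("synthetic life table is Gompertz-shaped, capped, and converts to cycles", {
  flat <- synthetic_life_table(0.005, 60, 0)
  expect_true(all(flat$annual_prob == 0.005))

  lt <- synthetic_life_table(0.005, 60, log(1.09))
  expect_equal(lt$annual_prob[lt$age == 70], 0.01183682, tolerance = 1e-6)
  expect_true(all(diff(lt$annual_prob) >= 0))
  expect_true(all(lt$annual_prob < 1))

  expect_equal(annual_to_cycle_prob(0.2), 1 - 0.8^(21 / 365.25))
  bg <- background_mortality(lt, 60, 100)
  expect_length(bg, 100)
  expect_true(all(diff(bg) >= 0))
})
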