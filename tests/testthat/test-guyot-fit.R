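test_that("censoring-free KM curves invert exactly", {
  ipd <- data.frame(time = c(2, 4, 5, 7, 8, 10, 12, 13, 15, 18), event = 1)
  km <- km_with_risk_table(ipd, interval = 5)
  rec <- km_to_pseudo_ipd(km)
  expect_equal(nrow(rec), 10)
  expect_true(all(rec$event == 1))
  expect_equal(sort(rec$time), sort(ipd$time))
})

test_that("a flat curve reconstructs to all-censored records", {
  curve <- structure(
    list(times = c(0, 3, 6, 9), surv = c(1, 1, 1, 1),
         risk_table = data.frame(time = c(0, 3, 6), n_risk = c(12, 8, 3))),
    class = "km_curve")
  rec <- km_to_pseudo_ipd(curve)
  expect_equal(nrow(rec), 12)
  expect_true(all(rec$event == 0))
})

test_that("reconstruction round-trips a censored KM curve within tolerance", {
  m <- loglogistic_model(0.01503, 1.46627)
  ipd <- simulate_ipd(m, 200, censoring = "uniform", cens_max = 60, seed = 21)
  km <- km_with_risk_table(ipd, interval = 6)
  rec <- km_to_pseudo_ipd(km)
  expect_equal(nrow(rec), 200)
  km2 <- km_with_risk_table(rec, interval = 6)
  # KM of the reconstruction reproduces the input curve at its time points
  at <- function(k, t) stats::approx(k$times, k$surv, xout = t,
                                     method = "constant", rule = 2)$y
  expect_lt(max(abs(at(km2, km$times) - km$surv)), 0.02)
})

test_that("simulate -> KM -> reconstruct -> refit recovers the generating parameters", {
  th <- 0.01503; ka <- 1.46627
  ipd <- simulate_ipd(loglogistic_model(th, ka), 500,
                      censoring = "uniform", cens_max = 80, seed = 5)
  km <- km_with_risk_table(ipd, interval = 6)
  fit <- fit_parametric(km_to_pseudo_ipd(km), "loglogistic")
  expect_lt(abs(fit$pars[["theta"]] - th) / th, 0.15)
  expect_lt(abs(fit$pars[["kappa"]] - ka) / ka, 0.15)
})

test_that("maximum-likelihood fits agree with an independent implementation", {
  skip_if_not_installed("flexsurv")
  ipd <- simulate_ipd(weibull_model(0.1, 1.2), 400,
                      censoring = "uniform", cens_max = 40, seed = 9)

  fw <- fit_parametric(ipd, "weibull")
  ow <- flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = ipd,
                              dist = "weibull")
  # flexsurv: S(t) = exp(-(t/scale)^shape)  =>  rate = scale^(-shape)
  sh <- unname(ow$res["shape", "est"]); sc <- unname(ow$res["scale", "est"])
  expect_equal(fw$pars[["shape"]], sh, tolerance = 1e-3)
  expect_equal(fw$pars[["scale"]], sc^(-sh), tolerance = 1e-3)
  expect_equal(fw$loglik, as.numeric(stats::logLik(ow)), tolerance = 1e-6)

  fl <- fit_parametric(ipd, "loglogistic")
  ol <- flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = ipd,
                              dist = "llogis")
  # flexsurv llogis: S(t) = 1/(1 + (t/scale)^shape)
  sh <- unname(ol$res["shape", "est"]); sc <- unname(ol$res["scale", "est"])
  expect_equal(fl$pars[["kappa"]], sh, tolerance = 1e-3)
  expect_equal(fl$pars[["theta"]], sc^(-sh), tolerance = 1e-3)
  expect_equal(fl$loglik, as.numeric(stats::logLik(ol)), tolerance = 1e-6)
})

test_that("exponential data recover a Weibull shape near 1", {
  ipd <- simulate_ipd(weibull_model(0.2, 1), 1000, seed = 13)
  fit <- fit_parametric(ipd, "weibull")
  expect_gt(fit$pars[["shape"]], 0.9)
  expect_lt(fit$pars[["shape"]], 1.1)
})

test_that("AIC selects the generating family in most seeded replicates", {
  wins <- vapply(1:20, function(s) {
    ipd <- simulate_ipd(weibull_model(0.1, 1.2), 500, seed = 100 + s)
    sel <- select_parametric(ipd)
    sel$family[1] == "weibull"
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})

test_that("degenerate fitting inputs behave as contracted", {
  expect_error(fit_parametric(data.frame(time = 1:20, event = 0), "weibull"),
               "all-censored")
  minimal <- data.frame(time = c(2, rep(c(1, 3), 5)), event = c(1, rep(0, 10)))
  fit <- fit_parametric(minimal, "loglogistic")
  expect_true(all(is.finite(fit$pars)))
  expect_true(is.finite(fit$aic))
})
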