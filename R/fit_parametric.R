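#' Maximum-likelihood fit of a parametric survival model to pseudo-IPD
#'
#' Fits a log-logistic (`S(t) = 1/(1 + theta t^kappa)`) or Weibull
#' (`S(t) = exp(-scale t^shape)`) law to right-censored data by maximising
#' the log-likelihood on the log-parameter scale (which keeps both
#' parameters positive). Three starting points are used to guard against
#' local optima; convergence uses a relative tolerance of 1e-8. The AIC
#' (`2k - 2 logL`, `k = 2`) supports model selection across families.
#'
#' @param ipd `data.frame` with `time` and `event` (1 = event, 0 = censored).
#' @param family `"loglogistic"` or `"weibull"`.
#' @return A list of class `parsurv_fit`: `family`, `pars` (named numeric,
#'   `theta`/`kappa` or `scale`/`shape`), `loglik`, `aic`, `n`, `n_event`,
#'   and `model` (the fitted [surv_model]).
#' @examples
#' ipd <- simulate_ipd(weibull_model(0.1, 1.2), n = 200, seed = 42)
#' fit_parametric(ipd, "weibull")
#' @export
fit_parametric <- function(ipd, family = c("loglogistic", "weibull")) {
  family <- match.arg(family)
  validate_ipd(ipd)
  if (sum(ipd$event) < 1)
    stop("cannot fit a parametric model to all-censored data")
  t <- ipd$time
  ev <- ipd$event == 1
  # zero times carry no likelihood information under these laws; nudge them
  eps <- if (any(t > 0)) min(t[t > 0]) / 2 else 1e-6
  t[t <= 0] <- eps

  negll <- if (family == "loglogistic") {
    function(lp) {
      th <- exp(lp[1]); ka <- exp(lp[2])
      z <- th * t^ka
      ll <- sum(ifelse(ev,
                       log(th) + log(ka) + (ka - 1) * log(t) - 2 * log1p(z),
                       -log1p(z)))
      if (!is.finite(ll)) 1e10 else -ll
    }
  } else {
    function(lp) {
      sc <- exp(lp[1]); sh <- exp(lp[2])
      z <- sc * t^sh
      ll <- sum(ifelse(ev, log(sc) + log(sh) + (sh - 1) * log(t) - z, -z))
      if (!is.finite(ll)) 1e10 else -ll
    }
  }

  med <- stats::median(t)
  rate0 <- if (family == "loglogistic") 1 / med else log(2) / med
  starts <- list(c(log(rate0), 0),
                 c(log(rate0) - 1, log(0.5)),
                 c(log(rate0) + 1, log(2)))
  fits <- lapply(starts, function(s)
    stats::optim(s, negll, method = "Nelder-Mead",
                 control = list(reltol = 1e-8, maxit = 2000)))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]

  pars <- exp(best$par)
  names(pars) <- if (family == "loglogistic") c("theta", "kappa") else c("scale", "shape")
  model <- if (family == "loglogistic")
    loglogistic_model(pars[["theta"]], pars[["kappa"]])
  else
    weibull_model(pars[["scale"]], pars[["shape"]])
  structure(
    list(family = family, pars = pars, loglik = -best$value,
         aic = 2 * 2 + 2 * best$value, n = nrow(ipd), n_event = sum(ipd$event),
         convergence = best$convergence, model = model),
    class = "parsurv_fit"
  )
}

#' @export
print.parsurv_fit <- function(x, ...) {
  cat(sprintf("<parsurv_fit> %s: %s\n  logLik = %.3f, AIC = %.3f (n = %d, events = %d)\n",
              x$family,
              paste(names(x$pars), signif(x$pars, 6), sep = " = ", collapse = ", "),
              x$loglik, x$aic, x$n, x$n_event))
  invisible(x)
}

#' Fit both supported families and rank them by AIC
#'
#' @inheritParams fit_parametric
#' @return `data.frame` with one row per family (`family`, parameter
#'   columns, `loglik`, `aic`), sorted by AIC.
#' @export
select_parametric <- function(ipd) {
  fits <- lapply(c("loglogistic", "weibull"), function(f) fit_parametric(ipd, f))
  out <- data.frame(
    family = vapply(fits, `[[`, character(1), "family"),
    par1 = vapply(fits, function(f) unname(f$pars[1]), numeric(1)),
    par2 = vapply(fits, function(f) unname(f$pars[2]), numeric(1)),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    aic = vapply(fits, `[[`, numeric(1), "aic")
  )
  out[order(out$aic), ]
}
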