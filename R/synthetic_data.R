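#' Simulate censored individual patient data from a parametric model
#'
#' Inverse-CDF sampling from a log-logistic or Weibull law (hazard-ratio
#' powers are honoured by sampling `U^(1/hr)`-adjusted survival levels),
#' optionally censored. Stands in for trial-level time-to-event data so the
#' reconstruction and refitting stages can be exercised end to end.
#'
#' @param model A [surv_model] object.
#' @param n Number of subjects (>= 1).
#' @param censoring `"none"`, `"uniform"` (independent censoring times drawn
#'   uniformly on `(0, cens_max)`), or `"administrative"` (all subjects
#'   censored at `cens_max` if still event-free).
#' @param cens_max Upper bound of the censoring law (required unless
#'   `censoring = "none"`).
#' @param seed Optional integer seed for reproducibility.
#' @return A `data.frame` with columns `time` and `event` (1 = event,
#'   0 = censored) — the pseudo-IPD layout used throughout the package.
#' @examples
#' ipd <- simulate_ipd(loglogistic_model(0.01503, 1.46627), n = 100, seed = 1)
#' @export
simulate_ipd <- function(model, n, censoring = c("none", "uniform", "administrative"),
                         cens_max = NULL, seed = NULL) {
  stopifnot(inherits(model, "surv_model"))
  censoring <- match.arg(censoring)
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1")
  n <- as.integer(n)
  if (censoring != "none") {
    if (is.null(cens_max) || !is.numeric(cens_max) || cens_max < 0)
      stop("`cens_max` must be a non-negative number for censored designs")
  }
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n)
  # invert S(t)^hr = u  <=>  S(t) = u^(1/hr)
  s <- u^(1 / model$hr)
  if (inherits(model, "loglogistic_model")) {
    lam <- if (model$variant == "exp_theta") exp(model$pars$theta) else model$pars$theta
    t_event <- ((1 - s) / (s * lam))^(1 / model$pars$kappa)
  } else {
    lam <- if (model$form == "aft") model$pars$scale^(-model$pars$shape) else model$pars$scale
    t_event <- (-log(s) / lam)^(1 / model$pars$shape)
  }
  if (censoring == "none") {
    out <- data.frame(time = t_event, event = 1L)
  } else {
    t_cens <- if (censoring == "uniform") stats::runif(n, 0, cens_max) else rep(cens_max, n)
    out <- data.frame(time = pmin(t_event, t_cens),
                      event = as.integer(t_event <= t_cens))
  }
  out
}

#' Kaplan-Meier curve with an interval risk table
#'
#' Product-limit estimate (via [survival::survfit]) of a pseudo-IPD sample,
#' packaged as the digitised-curve format the reconstruction stage reads:
#' step coordinates plus numbers at risk at regular interval boundaries.
#'
#' @param ipd `data.frame` with `time` and `event` columns.
#' @param interval Width of the risk-table reporting interval (same time
#'   unit as `ipd$time`).
#' @return A list of class `km_curve` with elements `times`, `surv`
#'   (step-function coordinates, starting at `(0, 1)`) and `risk_table`
#'   (`data.frame` with `time`, `n_risk`).
#' @export
km_with_risk_table <- function(ipd, interval = 3) {
  validate_ipd(ipd)
  if (!is.numeric(interval) || interval <= 0) stop("`interval` must be > 0")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  times <- c(0, fit$time)
  surv <- c(1, fit$surv)
  breaks <- seq(0, max(ipd$time) + interval, by = interval)
  n_risk <- vapply(breaks, function(b) sum(ipd$time >= b), integer(1))
  keep <- n_risk > 0 | breaks == 0
  structure(
    list(times = times, surv = surv,
         risk_table = data.frame(time = breaks[keep], n_risk = n_risk[keep])),
    class = "km_curve"
  )
}

validate_ipd <- function(ipd) {
  if (!is.data.frame(ipd) || !all(c("time", "event") %in% names(ipd)))
    stop("pseudo-IPD must be a data.frame with `time` and `event` columns")
  if (nrow(ipd) < 1) stop("pseudo-IPD must contain at least one record")
  if (any(ipd$time < 0)) stop("pseudo-IPD times must be >= 0")
  if (!all(ipd$event %in% c(0, 1))) stop("`event` must be 0/1")
  invisible(ipd)
}

validate_km_curve <- function(curve) {
  if (!inherits(curve, "km_curve")) {
    if (is.list(curve) && all(c("times", "surv", "risk_table") %in% names(curve)))
      class(curve) <- "km_curve"
    else stop("`curve` must be a km_curve (times, surv, risk_table)")
  }
  if (length(curve$times) != length(curve$surv))
    stop("`times` and `surv` must have equal length")
  if (is.unsorted(curve$times)) stop("KM `times` must be non-decreasing")
  if (abs(curve$surv[1] - 1) > 1e-12 || curve$times[1] != 0)
    stop("KM curve must start at (0, 1)")
  if (any(diff(curve$surv) > 1e-12)) stop("KM survival must be non-increasing")
  if (any(curve$surv < 0 | curve$surv > 1)) stop("KM survival must lie in [0, 1]")
  rt <- curve$risk_table
  if (!is.data.frame(rt) || nrow(rt) < 1 || !all(c("time", "n_risk") %in% names(rt)))
    stop("risk table must be a data.frame with `time` and `n_risk`")
  if (any(diff(rt$n_risk) > 0)) stop("risk-table counts must be non-increasing")
  invisible(curve)
}

#' Synthetic background-mortality life table
#'
#' Gompertz-shaped annual death probabilities,
#' `q(age) = q0 * exp(slope * (age - base_age))`, capped below 1. A synthetic
#' stand-in for a national life table (the default slope and anchor
#' approximate adult mortality in China); replaceable by any table with
#' `age` and `annual_prob` columns.
#'
#' @param base_prob Annual death probability at `base_age`, in (0, 1).
#' @param base_age Anchor age in years.
#' @param slope Log-linear increase per year of age (Gompertz slope).
#' @param ages Ages at which to tabulate (default `0:110`; below `base_age`
#'   the curve is extrapolated backwards with the same slope).
#' @return `data.frame` with columns `age`, `annual_prob`.
#' @examples
#' lt <- synthetic_life_table(0.005, 60, log(1.09))
#' lt$annual_prob[lt$age == 70]  # ~0.0118
#' @export
synthetic_life_table <- function(base_prob = 0.009, base_age = 60,
                                 slope = log(1.09), ages = 0:110) {
  if (!is.numeric(base_prob) || base_prob <= 0 || base_prob >= 1)
    stop("`base_prob` must be in (0, 1)")
  q <- pmin(base_prob * exp(slope * (ages - base_age)), 0.999)
  data.frame(age = ages, annual_prob = q)
}

#' Convert an annual death probability to a per-cycle probability
#'
#' Constant hazard within the year: `1 - (1 - q)^(cycle_days/365.25)`.
#'
#' @param annual_prob Annual probability in `[0, 1)`.
#' @param cycle_days Cycle length in days (default 21).
#' @return Per-cycle probability.
#' @export
annual_to_cycle_prob <- function(annual_prob, cycle_days = 21) {
  if (any(annual_prob < 0 | annual_prob >= 1)) stop("annual probability must be in [0, 1)")
  1 - (1 - annual_prob)^(cycle_days / 365.25)
}

#' Per-cycle background mortality along the model time grid
#'
#' Looks up the life-table annual probability at the attained (integer) age
#' in each cycle and converts it to the cycle length.
#'
#' @param life_table `data.frame` with `age`, `annual_prob`.
#' @param start_age Age in years at model entry.
#' @param n_cycles Number of cycles.
#' @param cycle_days Cycle length in days.
#' @return Numeric vector of length `n_cycles`.
#' @export
background_mortality <- function(life_table, start_age, n_cycles, cycle_days = 21) {
  stopifnot(is.data.frame(life_table), all(c("age", "annual_prob") %in% names(life_table)))
  age_at <- floor(start_age + (seq_len(n_cycles) - 1) * cycle_days / 365.25)
  idx <- match(pmin(age_at, max(life_table$age)), life_table$age)
  if (anyNA(idx)) stop("life table does not cover the required age span")
  annual_to_cycle_prob(life_table$annual_prob[idx], cycle_days)
}
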