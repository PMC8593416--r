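#' Parametric survival models for cycle-wise extrapolation
#'
#' The cohort engine consumes parametric survival laws evaluated on the
#' model's 3-week cycle grid. Two families are supported:
#'
#' * **log-logistic**, `S(t) = 1 / (1 + lambda * t^kappa)` where by default
#'   `lambda = theta` (`variant = "raw_theta"`). The published formula reads
#'   `exp(theta)`, which is retained behind `variant = "exp_theta"`, but with
#'   the fitted theta values only the raw reading yields extrapolated medians
#'   compatible with the source trials (see the methods vignette).
#' * **Weibull**, `S(t) = exp(-scale * t^shape)` (rate form, default) or the
#'   accelerated-failure-time form `S(t) = exp(-(t/scale)^shape)`
#'   (`form = "aft"`).
#'
#' A positive hazard ratio may be attached to any model; it acts as a power
#' on the survival function, `S(t)^hr`, the proportional-hazards adjustment
#' used for the indirect comparison arms.
#'
#' @param theta Rate-like parameter of the log-logistic law (> 0, or >= 0
#'   under `exp_theta` where the exponential guarantees positivity).
#' @param kappa Shape parameter of the log-logistic law (> 0).
#' @param scale,shape Weibull parameters (> 0).
#' @param variant Reading of the log-logistic rate: `"raw_theta"` (default)
#'   uses `theta` directly, `"exp_theta"` uses `exp(theta)`.
#' @param form Weibull parameterisation, `"rate"` (default) or `"aft"`.
#' @param hr Hazard ratio applied as a power on survival (> 0, default 1).
#' @param time_unit Unit of the time axis; informational. One of
#'   `"cycle_3wk"` (default), `"month"`, `"week"`.
#'
#' @return An object of class `surv_model` (and family subclass) with
#'   `surv_prob()` and `cycle_prob()` methods.
#' @examples
#' m <- loglogistic_model(theta = 0.01503, kappa = 1.46627)
#' surv_prob(m, 10)          # ~0.695
#' cycle_prob(m, 5)          # conditional event probability in cycle 5
#' @name surv_model
NULL

new_surv_model <- function(family, pars, variant = NULL, form = NULL,
                           hr = 1, time_unit = "cycle_3wk") {
  stopifnot(is.numeric(hr), length(hr) == 1L)
  if (!is.finite(hr) || hr <= 0) stop("`hr` must be a positive number")
  time_unit <- match.arg(time_unit, c("cycle_3wk", "month", "week"))
  structure(
    list(family = family, pars = pars, variant = variant, form = form,
         hr = hr, time_unit = time_unit),
    class = c(paste0(family, "_model"), "surv_model")
  )
}

#' @rdname surv_model
#' @export
loglogistic_model <- function(theta, kappa, variant = c("raw_theta", "exp_theta"),
                              hr = 1, time_unit = "cycle_3wk") {
  variant <- match.arg(variant)
  stopifnot(is.numeric(theta), is.numeric(kappa))
  if (kappa <= 0) stop("`kappa` must be > 0")
  if (variant == "raw_theta" && theta <= 0)
    stop("`theta` must be > 0 under the raw_theta variant")
  new_surv_model("loglogistic", list(theta = theta, kappa = kappa),
                 variant = variant, hr = hr, time_unit = time_unit)
}

#' @rdname surv_model
#' @export
weibull_model <- function(scale, shape, form = c("rate", "aft"),
                          hr = 1, time_unit = "cycle_3wk") {
  form <- match.arg(form)
  stopifnot(is.numeric(scale), is.numeric(shape))
  if (scale <= 0 || shape <= 0) stop("Weibull `scale` and `shape` must be > 0")
  new_surv_model("weibull", list(scale = scale, shape = shape),
                 form = form, hr = hr, time_unit = time_unit)
}

#' Attach a hazard ratio to a survival model
#'
#' Returns the model with `S(t)` replaced by `S(t)^hr` (multiplicative on the
#' existing hazard ratio, so adjustments compose).
#'
#' @param model A `surv_model`.
#' @param hr Positive hazard ratio.
#' @return The adjusted `surv_model`.
#' @export
hr_adjust <- function(model, hr) {
  stopifnot(inherits(model, "surv_model"))
  if (!is.numeric(hr) || length(hr) != 1L || !is.finite(hr) || hr <= 0)
    stop("`hr` must be a positive number")
  model$hr <- model$hr * hr
  model
}

#' Survival probability of a parametric model
#'
#' @param model A `surv_model`.
#' @param t Non-negative time(s) in the model's time unit.
#' @return `S(t)^hr`, in `(0, 1]`, vectorised over `t`.
#' @export
surv_prob <- function(model, t) UseMethod("surv_prob")

base_surv <- function(model, t) {
  if (any(!is.finite(t)) || any(t < 0)) stop("`t` must be finite and >= 0")
  if (inherits(model, "loglogistic_model")) {
    lam <- if (model$variant == "exp_theta") exp(model$pars$theta) else model$pars$theta
    1 / (1 + lam * t^model$pars$kappa)
  } else if (inherits(model, "weibull_model")) {
    if (model$form == "aft") {
      exp(-(t / model$pars$scale)^model$pars$shape)
    } else {
      exp(-model$pars$scale * t^model$pars$shape)
    }
  } else {
    stop("unknown survival family")
  }
}

#' @export
surv_prob.surv_model <- function(model, t) {
  base_surv(model, t)^model$hr
}

#' Per-cycle event probability of a parametric model
#'
#' The conditional probability that the event occurs in cycle `t` given
#' event-free survival to the start of the cycle:
#' `P(t) = 1 - S(t)/S(t-1)` (with the hazard-ratio power applied to the
#' survival ratio, matching the proportional-hazards transition formula).
#'
#' @param model A `surv_model`.
#' @param t Cycle index (integer-valued, >= 1), vectorised.
#' @return Probabilities in `[0, 1)`.
#' @export
cycle_prob <- function(model, t) UseMethod("cycle_prob")

#' @export
cycle_prob.surv_model <- function(model, t) {
  if (any(!is.finite(t)) || any(t < 1)) stop("cycle index `t` must be >= 1")
  1 - (base_surv(model, t) / base_surv(model, t - 1))^model$hr
}

#' @export
print.surv_model <- function(x, ...) {
  pars <- paste(names(x$pars), signif(unlist(x$pars), 6), sep = " = ",
                collapse = ", ")
  cat(sprintf("<surv_model> %s (%s)%s, time unit: %s\n", x$family, pars,
              if (x$hr != 1) sprintf(", HR = %g", x$hr) else "", x$time_unit))
  invisible(x)
}

# ---- flat functional interface -------------------------------------------

#' Log-logistic survival and cycle transition probability
#'
#' Direct functional forms used for stable-state transitions:
#' `S(t) = 1/(1 + lambda t^kappa)` and `P(t) = 1 - S(t)/S(t-1)`, with
#' `lambda = theta` (default) or `exp(theta)`. The hazard-ratio variants
#' raise the survival function (or the survival ratio) to the power `hr`.
#'
#' @inheritParams surv_model
#' @param t Time (>= 0) for survival; cycle index (>= 1) for cycle
#'   probabilities.
#' @param hr Positive hazard ratio.
#' @return Probabilities, vectorised over `t`.
#' @export
loglogistic_survival <- function(theta, kappa, t, variant = c("raw_theta", "exp_theta")) {
  surv_prob(loglogistic_model(theta, kappa, variant = match.arg(variant)), t)
}

#' @rdname loglogistic_survival
#' @export
loglogistic_cycle_prob <- function(theta, kappa, t, variant = c("raw_theta", "exp_theta")) {
  cycle_prob(loglogistic_model(theta, kappa, variant = match.arg(variant)), t)
}

#' @rdname loglogistic_survival
#' @export
hr_adjusted_survival <- function(theta, kappa, hr, t,
                                 variant = c("raw_theta", "exp_theta")) {
  surv_prob(loglogistic_model(theta, kappa, variant = match.arg(variant), hr = hr), t)
}

#' @rdname loglogistic_survival
#' @export
hr_adjusted_cycle_prob <- function(theta, kappa, hr, t,
                                   variant = c("raw_theta", "exp_theta")) {
  cycle_prob(loglogistic_model(theta, kappa, variant = match.arg(variant), hr = hr), t)
}

#' Weibull survival and cycle transition probability
#'
#' `S(t) = exp(-scale t^shape)` (rate form) and `P(t) = 1 - S(t)/S(t-1)`,
#' used for the second-line (post-progression) models.
#'
#' @inheritParams surv_model
#' @param t Time (>= 0) for survival; cycle index (>= 1) for cycle
#'   probabilities.
#' @return Probabilities, vectorised over `t`.
#' @export
weibull_survival <- function(scale, shape, t, form = c("rate", "aft")) {
  surv_prob(weibull_model(scale, shape, form = match.arg(form)), t)
}

#' @rdname weibull_survival
#' @export
weibull_cycle_prob <- function(scale, shape, t, form = c("rate", "aft")) {
  cycle_prob(weibull_model(scale, shape, form = match.arg(form)), t)
}

#' Median survival time of a parametric model
#'
#' Closed-form median (time at which `S(t)^hr = 0.5`), used for
#' plausibility checks against trial-reported medians.
#'
#' @param model A `surv_model`.
#' @return Median time in the model's time unit.
#' @export
median_survival <- function(model) {
  stopifnot(inherits(model, "surv_model"))
  target <- 0.5^(1 / model$hr)
  if (inherits(model, "loglogistic_model")) {
    lam <- if (model$variant == "exp_theta") exp(model$pars$theta) else model$pars$theta
    ((1 - target) / (target * lam))^(1 / model$pars$kappa)
  } else {
    lam <- if (model$form == "aft") model$pars$scale^(-model$pars$shape) else model$pars$scale
    (-log(target) / lam)^(1 / model$pars$shape)
  }
}
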