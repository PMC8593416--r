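#' Build a PSA sampler for one parameter
#'
#' Hyperparameters are derived by moment matching: the base value is the
#' mean and `(high - low)/3.92` the standard deviation (the range is read
#' as a 95% interval). Hazard ratios use a normal on the log scale with
#' moments from the CI. If the implied moments are infeasible (beta SD too
#' large for the mean), the sampler falls back to a range-matched uniform
#' with a warning.
#'
#' @param name Parameter label (for messages).
#' @param base,low,high Base value and range.
#' @param dist `"beta"`, `"gamma"`, `"normal"`, `"lognormal"`, or
#'   `"fixed"`.
#' @return A list of class `param_dist` with elements `name`, `dist`,
#'   `hyper` (named numeric) and `sample(n)`.
#' @export
build_distribution <- function(name, base, low = NA, high = NA,
                               dist = c("beta", "gamma", "normal",
                                        "lognormal", "fixed")) {
  dist <- match.arg(dist)
  if (dist != "fixed" && (is.na(low) || is.na(high)))
    stop("`", name, "`: a range is required for sampled parameters")
  sd <- if (dist == "fixed") 0 else (high - low) / 3.92
  out <- switch(dist,
    fixed = list(hyper = c(value = base),
                 sample = function(n) rep(base, n)),
    normal = list(hyper = c(mean = base, sd = sd),
                  sample = function(n) stats::rnorm(n, base, sd)),
    lognormal = {
      sdlog <- (log(high) - log(low)) / 3.92
      list(hyper = c(meanlog = log(base), sdlog = sdlog),
           sample = function(n) stats::rlnorm(n, log(base), sdlog))
    },
    gamma = {
      shape <- (base / sd)^2
      rate <- base / sd^2
      list(hyper = c(shape = shape, rate = rate),
           sample = function(n) stats::rgamma(n, shape, rate))
    },
    beta = {
      if (sd^2 >= base * (1 - base)) {
        warning("`", name, "`: beta moments infeasible; using uniform(",
                low, ", ", high, ")")
        list(hyper = c(min = low, max = high),
             sample = function(n) stats::runif(n, low, high))
      } else {
        nu <- base * (1 - base) / sd^2 - 1
        list(hyper = c(shape1 = base * nu, shape2 = (1 - base) * nu),
             sample = function(n) stats::rbeta(n, base * nu, (1 - base) * nu))
      }
    })
  structure(c(list(name = name, dist = dist, base = base), out),
            class = "param_dist")
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs the configured analysis once at the lower and once at the upper
#' bound of every parameter that has a range, all other parameters at base,
#' and reports the resulting ICERs ranked by spread.
#'
#' @param config A [run_config()].
#' @param params Optional character vector restricting the parameters
#'   varied (default: all with a range).
#' @return `data.frame`: `param`, `low`, `high`, `icer_base`, `icer_low`,
#'   `icer_high`, `spread`, sorted by decreasing spread.
#' @export
one_way_dsa <- function(config, params = NULL) {
  tab <- config$params[!is.na(config$params$low), ]
  if (!is.null(params)) {
    bad <- setdiff(params, tab$name)
    if (length(bad)) stop("no DSA range for: ", paste(bad, collapse = ", "))
    tab <- tab[tab$name %in% params, ]
  }
  icer0 <- base_icer(config)
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    lo <- base_icer(set_param(config, tab$name[i], tab$low[i]))
    hi <- base_icer(set_param(config, tab$name[i], tab$high[i]))
    data.frame(param = tab$name[i], low = tab$low[i], high = tab$high[i],
               icer_base = icer0, icer_low = lo, icer_high = hi,
               spread = abs(hi - lo))
  })
  out <- do.call(rbind, rows)
  out[order(-out$spread), ]
}

#' Threshold search: parameter value at which the ICER equals WTP
#'
#' Bisection on a single parameter, all others at base. The root function
#' is the incremental net monetary benefit, `INMB = WTP * dQALY - dCost`,
#' which equals zero exactly where the ICER equals WTP (for a QALY-gaining
#' comparator) and, unlike the raw ICER, stays monotone and well-defined
#' through dominance sign flips. Monotonicity over the bracket is checked
#' empirically at the endpoints and midpoint; absence of a sign change
#' returns `NA` with a message.
#'
#' @param config A [run_config()].
#' @param param Parameter name.
#' @param wtp Willingness-to-pay threshold; defaults to the configured one.
#' @param bracket Length-2 numeric search interval.
#' @param tol Relative tolerance on the parameter (default 1e-4).
#' @return The threshold value, or `NA_real_` if the INMB does not cross
#'   zero inside the bracket.
#' @export
threshold_search <- function(config, param, wtp = NULL, bracket, tol = 1e-4) {
  if (is.null(wtp)) wtp <- config$settings$wtp
  if (length(bracket) != 2 || bracket[1] >= bracket[2])
    stop("`bracket` must be an increasing length-2 interval")
  f <- function(x) {
    ce <- run_base_case(set_param(config, param, x))
    wtp * ce$d_qalys[2] - ce$d_cost[2]
  }
  f_lo <- f(bracket[1]); f_hi <- f(bracket[2])
  f_mid <- f(mean(bracket))
  if (!(min(f_lo, f_hi) <= f_mid && f_mid <= max(f_lo, f_hi)))
    warning("INMB does not look monotone in `", param, "` over the bracket")
  if (sign(f_lo) == sign(f_hi)) {
    message("no ICER = WTP crossing for `", param, "` in [",
            bracket[1], ", ", bracket[2], "]")
    return(NA_real_)
  }
  lo <- bracket[1]; hi <- bracket[2]
  while ((hi - lo) > tol * max(abs(hi), abs(lo), 1)) {
    mid <- (lo + hi) / 2
    if (sign(f(mid)) == sign(f_lo)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Probabilistic sensitivity analysis
#'
#' Samples every non-fixed parameter from its [build_distribution()] law,
#' re-runs the configured analysis per iteration, and records per-strategy
#' discounted cost and QALYs. Reproducible given `seed`; non-finite
#' iterations are dropped with a message.
#'
#' @param config A [run_config()].
#' @param n Number of Monte Carlo iterations (1,000 in the reported
#'   analysis).
#' @param seed Integer seed.
#' @return A list of class `psa_result`: `draws` (`data.frame` with
#'   `iteration`, `strategy`, `cost`, `qalys`), `strategies`, `n`, `seed`,
#'   `wtp`.
#' @export
run_psa <- function(config, n = 1000, seed = 1) {
  stopifnot(inherits(config, "run_config"))
  set.seed(seed)
  tab <- config$params
  sampled <- which(tab$dist != "fixed")
  draws_mat <- matrix(numeric(0), nrow = n, ncol = 0)
  for (i in sampled)
    draws_mat <- cbind(draws_mat,
                       build_distribution(tab$name[i], tab$base[i], tab$low[i],
                                          tab$high[i], tab$dist[i])$sample(n))
  colnames(draws_mat) <- tab$name[sampled]
  # guard: resample any non-positive normal draws for strictly positive inputs
  for (j in seq_len(ncol(draws_mat))) {
    bad <- draws_mat[, j] <= 0
    if (any(bad)) draws_mat[bad, j] <- tab$base[sampled[j]]
  }

  rows <- vector("list", n)
  dropped <- 0L
  for (it in seq_len(n)) {
    cfg <- config
    if (length(sampled)) cfg$params$base[sampled] <- draws_mat[it, ]
    ce <- tryCatch(run_base_case(cfg), error = function(e) NULL)
    if (is.null(ce) || any(!is.finite(ce$cost)) || any(!is.finite(ce$qalys))) {
      dropped <- dropped + 1L
      next
    }
    rows[[it]] <- data.frame(iteration = it, strategy = ce$strategy,
                             cost = ce$cost, qalys = ce$qalys)
  }
  if (dropped > 0) message(dropped, " PSA iteration(s) dropped (non-finite results)")
  draws <- do.call(rbind, rows)
  structure(list(draws = draws,
                 strategies = unique(draws$strategy),
                 n = n - dropped, seed = seed, wtp = config$settings$wtp),
            class = "psa_result")
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability (across PSA
#' iterations) that each strategy has the highest net monetary benefit.
#'
#' @param psa A [run_psa()] result.
#' @param wtp_grid Numeric vector of WTP values.
#' @return `data.frame`: `wtp`, `strategy`, `prob`; probabilities across
#'   strategies sum to 1 at each WTP.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 50000, by = 2500)) {
  stopifnot(inherits(psa, "psa_result"))
  d <- psa$draws
  wide_cost <- stats::reshape(d[c("iteration", "strategy", "cost")],
                              idvar = "iteration", timevar = "strategy",
                              direction = "wide")
  wide_q <- stats::reshape(d[c("iteration", "strategy", "qalys")],
                           idvar = "iteration", timevar = "strategy",
                           direction = "wide")
  strat <- psa$strategies
  cost <- as.matrix(wide_cost[paste0("cost.", strat)])
  qal <- as.matrix(wide_q[paste0("qalys.", strat)])
  out <- lapply(wtp_grid, function(w) {
    nmb <- w * qal - cost
    best <- max.col(nmb, ties.method = "first")
    data.frame(wtp = w, strategy = strat,
               prob = vapply(seq_along(strat),
                             function(j) mean(best == j), numeric(1)))
  })
  do.call(rbind, out)
}

#' Probability that the comparator strategy is cost-effective
#'
#' Fraction of PSA iterations in which the second (non-reference) strategy
#' has positive incremental net monetary benefit against the reference at
#' the given WTP.
#'
#' @param psa A [run_psa()] result (two-strategy analysis).
#' @param wtp Willingness-to-pay threshold; defaults to the one stored in
#'   the PSA.
#' @return Probability in `[0, 1]`.
#' @export
prob_cost_effective <- function(psa, wtp = NULL) {
  stopifnot(inherits(psa, "psa_result"))
  if (is.null(wtp)) wtp <- psa$wtp
  cc <- ceac(psa, wtp)
  cc$prob[cc$strategy == psa$strategies[2]]
}
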