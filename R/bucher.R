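#' Trial-level hazard ratio with confidence interval
#'
#' @param point Point estimate (> 0).
#' @param ci_low,ci_high 95% confidence limits (0 < low <= point <= high).
#' @param comparison Label, e.g. `"A vs C"`.
#' @param anchor Common-comparator label used to match trials in the
#'   anchored comparison.
#' @return A list of class `trial_hr`.
#' @export
trial_hr <- function(point, ci_low, ci_high, comparison = "", anchor = "") {
  if (any(c(point, ci_low, ci_high) <= 0)) stop("hazard ratios must be > 0")
  if (!(ci_low <= point && point <= ci_high))
    stop("need ci_low <= point <= ci_high")
  structure(list(point = point, ci_low = ci_low, ci_high = ci_high,
                 comparison = comparison, anchor = anchor),
            class = "trial_hr")
}

#' Anchored indirect comparison of hazard ratios (Bucher method)
#'
#' Fixed-effect anchored comparison through a common comparator C:
#' `log HR(A vs B) = log HR(A vs C) - log HR(B vs C)`, with standard errors
#' combined in quadrature (`SE = (log hi - log lo)/3.92` from each 95% CI)
#' and the 95% CI re-exponentiated. This is the implementable analogue of a
#' network meta-analysis for a single loop of two trials.
#'
#' @param hr_ac,hr_bc [trial_hr()] objects sharing the anchor C.
#' @return A `trial_hr` for A vs B.
#' @examples
#' a <- trial_hr(0.5, 0.4, 0.625, "A vs C", anchor = "C")
#' b <- trial_hr(0.8, 0.64, 1.0, "B vs C", anchor = "C")
#' bucher_indirect(a, b)$point  # 0.625
#' @export
bucher_indirect <- function(hr_ac, hr_bc) {
  stopifnot(inherits(hr_ac, "trial_hr"), inherits(hr_bc, "trial_hr"))
  if (!identical(hr_ac$anchor, hr_bc$anchor))
    stop("anchored comparison requires a shared anchor (got `",
         hr_ac$anchor, "` vs `", hr_bc$anchor, "`)")
  se_ac <- (log(hr_ac$ci_high) - log(hr_ac$ci_low)) / 3.92
  se_bc <- (log(hr_bc$ci_high) - log(hr_bc$ci_low)) / 3.92
  log_ab <- log(hr_ac$point) - log(hr_bc$point)
  se_ab <- sqrt(se_ac^2 + se_bc^2)
  trial_hr(exp(log_ab),
           exp(log_ab - 1.96 * se_ab),
           exp(log_ab + 1.96 * se_ab),
           comparison = paste(hr_ac$comparison, "vs", hr_bc$comparison),
           anchor = hr_ac$anchor)
}

#' @export
print.trial_hr <- function(x, ...) {
  cat(sprintf("<trial_hr> %s: %.3f (95%% CI %.3f-%.3f)\n",
              if (nzchar(x$comparison)) x$comparison else "HR",
              x$point, x$ci_low, x$ci_high))
  invisible(x)
}
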