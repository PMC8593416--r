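#' Reconstruct pseudo-individual patient data from a Kaplan-Meier curve
#'
#' Implements the iterative reconstruction algorithm of Guyot and colleagues:
#' given digitised step-function coordinates of a published KM curve and the
#' numbers-at-risk table printed beneath it, the algorithm recovers a set of
#' individual event/censoring times whose KM estimate reproduces the
#' published curve.
#'
#' Within each risk-table interval the number of censored observations is
#' estimated iteratively so that the implied number at risk at the start of
#' the next interval matches the printed count; censoring times are spread
#' uniformly across the interval, and at tied times events are placed before
#' censorings. After the final risk-table row, any subjects still at risk
#' beyond the last coordinate are censored there.
#'
#' @param curve A `km_curve` (see [km_with_risk_table()]): list with `times`
#'   and `surv` step coordinates (starting at `(0, 1)`) and a `risk_table`
#'   `data.frame` (`time`, `n_risk`) whose first row gives the initial
#'   sample size.
#' @return A pseudo-IPD `data.frame` with columns `time` and `event`
#'   (1 = event, 0 = censored); the number of rows equals the initial number
#'   at risk.
#' @references Guyot P, Ades AE, Ouwens MJNM, Welton NJ. Enhanced secondary
#'   analysis of survival data: reconstructing the data from published
#'   Kaplan-Meier survival curves. BMC Med Res Methodol. 2012;12:9.
#' @export
km_to_pseudo_ipd <- function(curve) {
  curve <- validate_km_curve(curve)
  tk <- curve$times
  sk <- curve$surv
  rt <- curve$risk_table
  if (rt$n_risk[1] < 1) stop("risk table must give a positive initial count")

  # drop the (0, 1) anchor; clicks are the observed coordinates
  keep <- tk > 0
  tk <- tk[keep]
  sk <- sk[keep]
  if (length(tk) == 0) stop("KM curve has no coordinates beyond t = 0")

  lower_t <- rt$time
  upper_t <- c(rt$time[-1], max(tk) + 1e-9)
  n_int <- length(lower_t)
  int_of <- pmax(1L, findInterval(tk, lower_t))

  # walk the clicks of one interval for a given censor pattern
  walk <- function(n_enter, km_enter, idx, ct, lo, hi) {
    n <- n_enter
    km <- km_enter
    d_i <- numeric(length(idx))
    prev <- lo
    for (j in seq_along(idx)) {
      k <- idx[j]
      n <- n - sum(ct >= prev & ct < tk[k])   # censored strictly before click
      d <- if (n > 0 && km > 0) round(n * (1 - sk[k] / km)) else 0
      d <- max(0, min(d, n))
      if (d > 0) km <- km * (1 - d / n)
      n <- n - d
      d_i[j] <- d
      prev <- tk[k]
    }
    n <- n - sum(ct >= prev & ct <= hi)
    list(n_end = n, km_end = km, d_i = d_i)
  }

  d <- numeric(length(tk))
  cens_times <- numeric(0)
  n_hat <- rt$n_risk[1]
  km_hat <- 1

  for (i in seq_len(n_int)) {
    idx <- which(int_of == i)
    target <- if (i < n_int) rt$n_risk[i + 1] else NA_real_
    c_i <- 0L
    res <- NULL
    for (iter in 1:100) {
      ct <- if (c_i > 0)
        lower_t[i] + (seq_len(c_i) - 0.5) / c_i * (upper_t[i] - lower_t[i])
      else numeric(0)
      res <- walk(n_hat, km_hat, idx, ct, lower_t[i], upper_t[i])
      if (is.na(target)) break
      gap <- res$n_end - target
      c_new <- max(0L, c_i + as.integer(gap))
      if (c_new == c_i) break
      c_i <- c_new
    }
    if (length(idx)) d[idx] <- res$d_i
    if (c_i > 0)
      cens_times <- c(cens_times,
                      lower_t[i] + (seq_len(c_i) - 0.5) / c_i * (upper_t[i] - lower_t[i]))
    n_hat <- res$n_end
    km_hat <- res$km_end
  }

  if (n_hat > 0) cens_times <- c(cens_times, rep(max(tk), n_hat))

  out <- rbind(
    if (sum(d) > 0)
      data.frame(time = rep(tk, times = d), event = 1L),
    if (length(cens_times))
      data.frame(time = cens_times, event = 0L)
  )
  out <- out[order(out$time, -out$event), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) != rt$n_risk[1])
    stop("reconstruction failed to account for all subjects (",
         nrow(out), " vs ", rt$n_risk[1], ")")
  out
}
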