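#' Read and write the package's plain-text data dialects
#'
#' Pseudo-IPD travels as CSV (`time`, `event`); digitised KM curves as a
#' two-column coordinate file (`time`, `surv`) plus a risk-table file
#' (`time`, `n_risk`); fitted survival models as YAML (family, parameters,
#' time unit).
#'
#' @param ipd Pseudo-IPD `data.frame`.
#' @param path,coords_path,risk_path File paths.
#' @return Readers return the object; writers return the path invisibly.
#' @name cea_io
NULL

#' @rdname cea_io
#' @export
write_pseudo_ipd <- function(ipd, path) {
  validate_ipd(ipd)
  utils::write.csv(ipd[c("time", "event")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname cea_io
#' @export
read_pseudo_ipd <- function(path) {
  ipd <- utils::read.csv(path)
  validate_ipd(ipd)
  ipd
}

#' @rdname cea_io
#' @param curve A `km_curve`.
#' @export
write_km_files <- function(curve, coords_path, risk_path) {
  curve <- validate_km_curve(curve)
  utils::write.csv(data.frame(time = curve$times, surv = curve$surv),
                   coords_path, row.names = FALSE)
  utils::write.csv(curve$risk_table, risk_path, row.names = FALSE)
  invisible(coords_path)
}

#' @rdname cea_io
#' @export
read_km_files <- function(coords_path, risk_path) {
  co <- utils::read.csv(coords_path)
  rt <- utils::read.csv(risk_path)
  validate_km_curve(structure(list(times = co$time, surv = co$surv,
                                   risk_table = rt),
                              class = "km_curve"))
}

#' @rdname cea_io
#' @param model A [surv_model] (or [parsurv_fit] whose model is taken).
#' @export
write_surv_model <- function(model, path) {
  if (inherits(model, "parsurv_fit")) model <- model$model
  stopifnot(inherits(model, "surv_model"))
  yaml::write_yaml(list(family = model$family, pars = as.list(model$pars),
                        variant = model$variant, form = model$form,
                        hr = model$hr, time_unit = model$time_unit),
                   path)
  invisible(path)
}

#' @rdname cea_io
#' @export
read_surv_model <- function(path) {
  y <- yaml::read_yaml(path)
  if (y$family == "loglogistic")
    loglogistic_model(y$pars$theta, y$pars$kappa, variant = y$variant,
                      hr = y$hr, time_unit = y$time_unit)
  else
    weibull_model(y$pars$scale, y$pars$shape, form = y$form,
                  hr = y$hr, time_unit = y$time_unit)
}
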