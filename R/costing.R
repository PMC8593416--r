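#' Patient profile used for dose-based cost scaling
#'
#' @param weight Body weight in kg (> 0).
#' @param bsa Body surface area in m^2 (> 0).
#' @param start_age Age in years at model entry (used for background
#'   mortality).
#' @return A list of class `patient_profile`.
#' @export
patient_profile <- function(weight = 65, bsa = 1.72, start_age = 60) {
  if (!is.numeric(weight) || weight <= 0) stop("`weight` must be > 0")
  if (!is.numeric(bsa) || bsa <= 0) stop("`bsa` must be > 0")
  structure(list(weight = weight, bsa = bsa, start_age = start_age),
            class = "patient_profile")
}

#' Dose per administration under a dosing rule
#'
#' @param rule `"flat_per_cycle"`, `"per_kg"`, or `"per_bsa"`.
#' @param dose Dose in mg (flat), mg/kg, or mg/m^2.
#' @param profile A [patient_profile()].
#' @return Dose in mg.
#' @examples
#' dose_amount("per_kg", 4.5, patient_profile(weight = 65))   # 292.5 mg
#' dose_amount("per_bsa", 500, patient_profile(bsa = 1.72))   # 860 mg
#' @export
dose_amount <- function(rule, dose, profile) {
  stopifnot(inherits(profile, "patient_profile"))
  switch(rule,
    flat_per_cycle = dose,
    per_kg  = dose * profile$weight,
    per_bsa = dose * profile$bsa,
    stop("unknown dosing rule: ", rule)
  )
}

#' A drug-cost component of a treatment line
#'
#' `per_cycle_cost` is the (already reimbursement-adjusted) cost per 3-week
#' cycle at the reference patient (65 kg, 1.72 m^2). For weight- or
#' BSA-dosed drugs the cost is rescaled linearly to the modelled profile,
#' so sampling weight/BSA in sensitivity analyses propagates to costs.
#' `paid_cycles_cap` encodes patient-assistance rules (e.g. pembrolizumab
#' is paid for four cycles, after which the assistance program covers it).
#'
#' @param name Drug label.
#' @param per_cycle_cost Cost per cycle in USD at the reference profile; if
#'   omitted, derived as `full_price_per_cycle * (1 - reimbursement_fraction)`.
#' @param dosing_rule `"flat_per_cycle"`, `"per_kg"`, or `"per_bsa"`.
#' @param dose Dose per administration (mg, mg/kg, or mg/m^2); informational
#'   unless cost is being re-derived.
#' @param paid_cycles_cap Number of cycles the payer is charged (default
#'   unlimited).
#' @param full_price_per_cycle,reimbursement_fraction Optional re-derivation
#'   of the per-cycle cost from an unadjusted price.
#' @return A list of class `drug_cost`.
#' @export
drug_cost <- function(name, per_cycle_cost = NULL,
                      dosing_rule = c("flat_per_cycle", "per_kg", "per_bsa"),
                      dose = NA_real_, paid_cycles_cap = Inf,
                      full_price_per_cycle = NULL, reimbursement_fraction = 0) {
  dosing_rule <- match.arg(dosing_rule)
  if (reimbursement_fraction < 0 || reimbursement_fraction > 1)
    stop("`reimbursement_fraction` must be in [0, 1]")
  if (is.null(per_cycle_cost)) {
    if (is.null(full_price_per_cycle))
      stop("give `per_cycle_cost` or `full_price_per_cycle`")
    per_cycle_cost <- full_price_per_cycle * (1 - reimbursement_fraction)
  }
  if (per_cycle_cost < 0) stop("costs must be >= 0")
  structure(list(name = name, per_cycle_cost = per_cycle_cost,
                 dosing_rule = dosing_rule, dose = dose,
                 paid_cycles_cap = paid_cycles_cap,
                 reimbursement_fraction = reimbursement_fraction),
            class = "drug_cost")
}

scaled_drug_cost <- function(drug, profile) {
  scale <- switch(drug$dosing_rule,
                  flat_per_cycle = 1,
                  per_kg = profile$weight / 65,
                  per_bsa = profile$bsa / 1.72)
  drug$per_cycle_cost * scale
}

#' A treatment strategy: drugs, caps, downstream-care mix, AE burden
#'
#' Encodes one arm of the analysis. Treatment-duration caps translate the
#' trial-reported median treatment cycles into the model (treatment cost
#' stops beyond the cap even if the patient remains progression-free);
#' `frac_2l`/`frac_3l` are the fractions of progressing patients who receive
#' active second-/third-line therapy rather than best supportive care.
#'
#' @param name Strategy label.
#' @param first_line List of [drug_cost()] components of first-line therapy.
#' @param first_line_cap Maximum number of first-line treatment cycles.
#' @param second_line List of [drug_cost()] components of second-line
#'   therapy.
#' @param second_line_cap Maximum number of second-line treatment cycles.
#' @param frac_2l,frac_3l Fractions in `[0, 1]` receiving active second- and
#'   third-line therapy.
#' @param ae_cost One-off adverse-event management cost (USD), charged at
#'   model entry.
#' @param ae_disutility Utility decrement applied in the stable state while
#'   on first-line treatment.
#' @param third_line_cost,bsc_cost,followup_cost Per-cycle costs (USD).
#' @param eol_cost End-of-life care cost (USD), charged once on the
#'   transition into death.
#' @param models Named list of [surv_model]s: `os1`, `pfs1` (first line,
#'   from the stable state) and `os2`, `pfs2` (second line, from the
#'   progression states).
#' @return A list of class `strategy_spec`.
#' @export
strategy_spec <- function(name, first_line, first_line_cap,
                          second_line = list(), second_line_cap = Inf,
                          frac_2l = 0.5, frac_3l = 0.5,
                          ae_cost = 0, ae_disutility = 0,
                          third_line_cost = 0, bsc_cost = 0,
                          followup_cost = 0, eol_cost = 0,
                          models = NULL) {
  if (inherits(first_line, "drug_cost")) first_line <- list(first_line)
  if (inherits(second_line, "drug_cost")) second_line <- list(second_line)
  costs <- c(ae_cost, third_line_cost, bsc_cost, followup_cost, eol_cost)
  if (any(costs < 0)) stop("all costs must be >= 0")
  for (f in c(frac_2l, frac_3l))
    if (f < 0 || f > 1) stop("therapy fractions must be in [0, 1]")
  if (ae_disutility < 0) stop("`ae_disutility` must be >= 0")
  if (!is.null(models)) {
    need <- c("os1", "pfs1", "os2", "pfs2")
    if (!all(need %in% names(models)))
      stop("`models` must contain: ", paste(need, collapse = ", "))
  }
  structure(list(name = name, first_line = first_line,
                 first_line_cap = first_line_cap,
                 second_line = second_line, second_line_cap = second_line_cap,
                 frac_2l = frac_2l, frac_3l = frac_3l,
                 ae_cost = ae_cost, ae_disutility = ae_disutility,
                 third_line_cost = third_line_cost, bsc_cost = bsc_cost,
                 followup_cost = followup_cost, eol_cost = eol_cost,
                 models = models),
            class = "strategy_spec")
}

#' Drug cost of one cycle within a treatment line
#'
#' Sums the strategy's drug components for the given line. A component
#' contributes 0 beyond its `paid_cycles_cap` or beyond the line's duration
#' cap.
#'
#' @param strategy A [strategy_spec()].
#' @param line `"first"` or `"second"`.
#' @param cycle_within_line Cycle index within the line (>= 1).
#' @param profile A [patient_profile()] for dose-based scaling.
#' @return Cost in USD.
#' @export
cycle_drug_cost <- function(strategy, line = c("first", "second"),
                            cycle_within_line, profile = patient_profile()) {
  line <- match.arg(line)
  if (any(cycle_within_line < 1)) stop("`cycle_within_line` must be >= 1")
  drugs <- if (line == "first") strategy$first_line else strategy$second_line
  cap <- if (line == "first") strategy$first_line_cap else strategy$second_line_cap
  vapply(cycle_within_line, function(cy) {
    if (cy > cap) return(0)
    sum(vapply(drugs, function(d) {
      if (cy > d$paid_cycles_cap) 0 else scaled_drug_cost(d, profile)
    }, numeric(1)))
  }, numeric(1))
}

model_states <- c("stable", "prog1", "prog2", "death")

#' Per-cycle cost and utility of a health state
#'
#' Composition rules: the stable state pays first-line drugs (within caps)
#' plus routine follow-up; first progression pays second-line drugs (within
#' caps) for the treated fraction and best supportive care for the rest;
#' second progression pays third-line therapy for the treated fraction and
#' BSC for the rest; all alive states pay follow-up. End-of-life cost is
#' charged by the engine on the transition into death, not here. Utility is
#' the state utility, reduced by the strategy's adverse-event disutility in
#' the stable state while on first-line treatment; death has utility 0.
#'
#' @param strategy A [strategy_spec()].
#' @param state One of `"stable"`, `"prog1"`, `"prog2"`, `"death"`.
#' @param cycle Model cycle (>= 1); the stable state's line counter.
#' @param line_cycle Cycle within the second treatment line (for `prog1`).
#' @param profile A [patient_profile()].
#' @return Cost in USD for the cycle.
#' @export
state_cycle_cost <- function(strategy, state, cycle, line_cycle = 1,
                             profile = patient_profile()) {
  state <- match.arg(state, model_states)
  switch(state,
    stable = strategy$followup_cost +
      cycle_drug_cost(strategy, "first", cycle, profile),
    prog1 = strategy$followup_cost +
      strategy$frac_2l * cycle_drug_cost(strategy, "second", line_cycle, profile) +
      (1 - strategy$frac_2l) * strategy$bsc_cost,
    prog2 = strategy$followup_cost +
      strategy$frac_3l * strategy$third_line_cost +
      (1 - strategy$frac_3l) * strategy$bsc_cost,
    death = 0
  )
}

#' @rdname state_cycle_cost
#' @param on_first_line Logical; is the cohort still within the first-line
#'   treatment duration?
#' @param utilities Named list/vector with `stable`, `prog1`, `prog2`.
#' @return Utility in `[0, 1]`.
#' @export
state_cycle_utility <- function(strategy, state, on_first_line, utilities) {
  state <- match.arg(state, model_states)
  u <- switch(state,
    stable = utilities[["stable"]] - strategy$ae_disutility * as.numeric(on_first_line),
    prog1 = utilities[["prog1"]],
    prog2 = utilities[["prog2"]],
    death = 0
  )
  max(0, u)
}
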