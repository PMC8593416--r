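# shared fixtures, built in code

table1_models <- function() {
  list(
    os_cpc = loglogistic_model(0.003326, 1.542250),
    os_pc = loglogistic_model(0.004501, 1.618052),
    pfs_cpc = loglogistic_model(0.01503, 1.46627),
    pfs_pc = loglogistic_model(0.03905, 1.36768),
    os2 = weibull_model(0.07471, 1.15519),
    pfs2 = weibull_model(0.25070, 1.14230)
  )
}

# a strategy with flat hazards and unit utility, for engine arithmetic tests
null_strategy <- function(theta = 1e-12, models = NULL) {
  if (is.null(models)) {
    m <- loglogistic_model(theta, 1)
    models <- list(os1 = m, pfs1 = m, os2 = m, pfs2 = m)
  }
  strategy_spec("null", first_line = list(), first_line_cap = 0,
                models = models)
}

flat_life_table <- function(q = 1e-12) {
  data.frame(age = 0:120, annual_prob = q)
}

unit_utilities <- list(stable = 1, prog1 = 1, prog2 = 1)
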