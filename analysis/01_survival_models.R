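#!/usr/bin/env Rscript
# Survival extrapolation stage: the parametric models that drive the Markov
# transitions, and a demonstration of the digitised-curve reconstruction
# pipeline (simulate a trial-sized cohort from the first-line PFS model,
# build its KM curve and risk table, reconstruct pseudo-IPD, and refit).

suppressPackageStartupMessages(library(nsclcCEA))
dir.create("results", showWarnings = FALSE)

models <- list(
  os_cpc = loglogistic_model(0.003326, 1.542250),
  os_pc = loglogistic_model(0.004501, 1.618052),
  pfs_cpc = loglogistic_model(0.01503, 1.46627),
  pfs_pc = loglogistic_model(0.03905, 1.36768),
  os_2l_docetaxel = weibull_model(0.07471, 1.15519),
  pfs_2l_docetaxel = weibull_model(0.25070, 1.14230)
)

med <- data.frame(
  model = names(models),
  median_cycles = round(vapply(models, median_survival, numeric(1)), 2)
)
med$median_months <- round(med$median_cycles * 21 / 30.4375, 1)
write.csv(med, "results/model_medians.csv", row.names = FALSE)
cat("Extrapolated medians (3-week cycles / months):\n")
print(med, row.names = FALSE)
cat("\nThe first-line medians sit close to the trial-reported ones",
    "(CPC OS 27.9 mo by calibration, PC OS ~20 mo, PFS 11.3 / 8.3 mo),",
    "supporting the cycle time scale.\n\n")

# reconstruction demonstration on a CameL-sized cohort (n = 412 per arm ~ 205)
ipd <- simulate_ipd(models$pfs_cpc, 205, censoring = "uniform",
                    cens_max = 80, seed = 2021)
km <- km_with_risk_table(ipd, interval = 6)
write_km_files(km, "results/km_coords_sim.csv", "results/km_risk_sim.csv")
rec <- km_to_pseudo_ipd(km)
write_pseudo_ipd(rec, "results/pseudo_ipd_sim.csv")

fits <- select_parametric(rec)
write.csv(fits, "results/survival_fits.csv", row.names = FALSE)
cat("Refit of reconstructed pseudo-IPD (generating: log-logistic",
    "theta 0.01503, kappa 1.46627):\n")
print(fits, row.names = FALSE)
cat(sprintf("\nLog-logistic preferred by AIC: %s; parameter recovery errors: %.1f%% / %.1f%%\n",
            fits$family[1] == "loglogistic",
            100 * abs(fits$par1[fits$family == "loglogistic"] / 0.01503 - 1),
            100 * abs(fits$par2[fits$family == "loglogistic"] / 1.46627 - 1)))
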