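#!/usr/bin/env Rscript
# Threshold analyses: parameter values at which the cost-effectiveness
# verdict flips at WTP = $11,146/QALY.

suppressPackageStartupMessages(library(nsclcCEA))
dir.create("results", showWarnings = FALSE)

pri <- run_config("primary")
sec <- run_config("secondary")

thr <- data.frame(
  analysis = c("primary", "secondary"),
  param = c("cost_camrelizumab", "hr_pfs_ppp"),
  base = c(424.51, 0.92),
  threshold = c(
    threshold_search(pri, "cost_camrelizumab", bracket = c(212.25, 1000)),
    threshold_search(sec, "hr_pfs_ppp", bracket = c(0.5, 1.1))
  )
)
write.csv(thr, "results/thresholds.csv", row.names = FALSE)
print(thr, row.names = FALSE)
cat(sprintf("\nCPC stays cost-effective vs PC up to a camrelizumab price of $%.2f per cycle;\n",
            thr$threshold[1]))
cat(sprintf("PPP becomes cost-effective vs CPC once its PFS hazard ratio falls below %.3f.\n",
            thr$threshold[2]))
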