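---
title: "Model structure, inputs and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, inputs and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsclcCEA)
```

This vignette is the package's account of its science: the cohort model and
its assumptions, where every input comes from, the choices made where the
published record under-determines the model, and what the tests do and do
not establish.

## The decision problem

First-line camrelizumab + pemetrexed + carboplatin (CPC) improved
progression-free and overall survival over pemetrexed + carboplatin (PC) in
the CameL trial, at a much lower drug price than the imported PD-1 inhibitor
pembrolizumab (PPP regimen, KEYNOTE-189). From the Chinese healthcare-system
perspective the question is whether CPC's extra cost per QALY gained stays
under a willingness-to-pay (WTP) of $11,146/QALY (1× 2020 per-capita GDP),
and whether PPP could justify its price against CPC.

## Cohort model

Four states — stable disease, first progression, second progression,
death — with 3-week cycles over 30 years (521 cycles) and 5%/year
discounting of costs and QALYs, applied as $(1+r)^{-t\,\Delta}$ with
$\Delta$ the cycle length in years. Accrual uses start-of-cycle occupancy;
a half-cycle correction is available (`model_settings()`) but off by
default, matching the common practice of cycle-boundary accounting in
decision-tree software.

Stable-state exits are driven by two parametric curves per arm:

* overall survival (OS), log-logistic $S(t) = 1/(1+\theta t^\kappa)$, giving
  the per-cycle death probability $P(t) = 1 - S(t)/S(t-1)$;
* progression-free survival (PFS), same family, giving the per-cycle
  probability of *any* first event (progression or death).

The death probability is floored by age-specific background mortality (a
`max`, not an additive hazard — the OS curve already contains deaths from
all causes observed in the trial), and progression is the excess of the PFS
event probability over same-cycle death, floored at zero
(`build_transition_row()`). Post-progression transitions use the
second-line Weibull models ($S(t)=e^{-\lambda t^\gamma}$, rate form; the
alternative $(t/\lambda)^\gamma$ parameterisation is available) for
docetaxel, raised to the nivolumab hazard ratios in the PC arm, indexed by
*model* time. Indexing second-line curves by time since model entry rather
than time since progression is the standard cohort simplification when no
per-state clock exists; it makes post-progression survival slightly
pessimistic for late progressors (the Weibull hazards increase with time)
and is listed under limitations. Death from the second-progression state
uses the same second-line OS per-cycle probability — the source analysis is
silent on this transition, and this choice keeps the post-progression death
hazard continuous across the two progression states.

The first-progression state is internally expanded into time-in-state
tunnel compartments (one per second-line treatment cycle up to the duration
cap) so second-line drug cost stops after exactly the capped number of
treatment cycles for each entry cohort; the reported trace aggregates the
tunnels back to four states.

The indirect (PPP) arm re-uses the CPC curves exponentiated by the
network-meta-analysis hazard ratios, $S(t)^{HR}$, equivalently
$P(t) = 1 - [S(t)/S(t-1)]^{HR}$ — the proportional-hazards reading. At
$HR = 1$ this is exactly the identity, which the test suite checks.

## Inputs and their provenance

`default_parameters()` carries one row per input: base value,
deterministic-sensitivity range, PSA family, and a provenance tag. The
bundled YAML configurations (`inst/extdata/config_primary.yaml`,
`config_secondary.yaml`) are the same table in file form. Three provenance
classes matter:

**`table`** — survival parameters, hazard ratios (OS 0.71 [0.57–0.85], PFS
0.92 [0.74–1.10] for PPP vs CPC; 0.76/0.87 for nivolumab vs docetaxel),
per-cycle costs in USD (camrelizumab 424.51, pembrolizumab 2,597.79,
pemetrexed 79.31, nivolumab 60.35, docetaxel 5.61, follow-up 55.60,
third-line 854.05, BSC 337.50, end-of-life 2,627.80, AE lump costs per
strategy), utilities (stable 0.856, first progression 0.768, second
progression 0.703) and AE disutilities (0.079/0.045/0.063), patient weight
65 kg and body surface area 1.72 m², taken as printed from the published
input table. Prices are already reimbursement-adjusted; carboplatin, folic
acid and vitamin B12 are fully reimbursed and carry zero cost. Per-kg and
per-m² drugs are rescaled by weight/65 and BSA/1.72 so that sampling weight
and BSA in sensitivity analyses propagates into costs.

**`calibrated`** — the CPC OS shape parameter. The printed CPC OS row
(θ = 0.003326, κ = 2.439689) is internally inconsistent: on the 3-week
cycle scale it implies a median OS of about 10 cycles (≈7 months) — far
below the trial's reported 27.9-month median — and it places the CPC OS
curve *below* the PC curve (θ = 0.004501, κ = 1.618052, median ≈28 cycles
≈ 19.5 months, consistent with the trial) for essentially all times, which
would contradict the trial's survival advantage and the published
cost-effectiveness results alike. We therefore keep the printed θ and
recalibrate κ so the extrapolated median equals the trial's 27.9 months
(40.44 cycles): κ = ln(1/θ)/ln(40.44) = 1.54225. This repair, rather than
recalibrating θ at the printed steep shape, is preferred because the steep
shape would make the OS hazard overtake the PFS hazard around cycle 40 and
truncate the stable state in a way that is inconsistent with the published
one-way sensitivity results for the stable-disease utility. All four PFS
parameter sets reproduce their trial medians on the cycle scale as printed
(see `analysis/01_survival_models.R`), which also fixes the time unit.

**`assumed`** — inputs that exist only in an unavailable supplement:
subsequent-therapy fractions (0.5 per line: half of progressing patients
receive active second-/third-line therapy, half best supportive care) and
median-treatment-cycle caps. Treatment duration in the source analysis is
capped at the trial-reported median treatment cycles, which the supplement
alone records; we reconstruct them from the published analysis's own
arithmetic: the printed camrelizumab price threshold ($553.92) together
with the printed incremental cost and QALYs implies roughly 8.8 discounted
paid camrelizumab cycles, which a 10-cycle cap reproduces; PC pemetrexed
(largely maintenance) is capped at its median PFS, 12 cycles; pembrolizumab
treatment at 11 cycles (≈7.4 months, its reported median exposure) with
only 4 cycles paid under the patient-assistance program; second-line
docetaxel/nivolumab at 4 cycles (≈2.8 months, the CheckMate 078 median
PFS). These are inputs, not fitted constants: they are exposed to the DSA
with ±25% ranges and can be overridden in the configuration. The
background-mortality table is likewise a documented synthetic stand-in — a
Gompertz curve anchored at an annual death probability of 0.009 at age 60
with slope ln(1.09)/year, approximating Chinese adult mortality — and is
replaceable by any `age`/`annual_prob` table.

Other structural choices where the record is silent: the adverse-event
cost is a one-off lump charged at model entry (the source gives a single
per-strategy AE cost with no timing); the AE disutility applies in the
stable state only while on first-line treatment (within the duration cap);
end-of-life care is charged once on the flow into death; routine follow-up
applies to all alive states in all cycles; the model cohort enters at age
60 (typical of the trial populations), which only affects background
mortality.

## Sensitivity analyses

*One-way DSA* re-runs the full model at each parameter's bounds (costs
±50%, utilities and HRs at their 95% CIs, discount rate 0–8%) and ranks
parameters by ICER spread. *Threshold search* bisects a parameter until the
ICER equals WTP; the root function is the incremental net monetary benefit
$\mathrm{INMB} = \mathrm{WTP}\cdot\Delta Q - \Delta C$, which has the same
root but stays monotone and finite through dominance flips; relative
tolerance 1e-4, with an empirical monotonicity check over the bracket.
*PSA* samples utilities from beta, costs from gamma, weight/BSA from
normal, and hazard ratios from log-normal distributions (normal on the log
scale preserves positivity; a literal-normal reading of the published
distribution table is available through `build_distribution()`), with
hyperparameters moment-matched to the base value as mean and
$(\mathrm{high}-\mathrm{low})/3.92$ as SD; infeasible beta moments fall
back to a range-matched uniform with a warning. Survival curve parameters,
the discount rate, treatment caps and therapy fractions are held fixed in
PSA. Parameters are sampled independently (the published record reports no
correlation structure). 1,000 iterations are used, summarised as CEACs and
the probability of cost-effectiveness at WTP.

## Numerical and testing choices

* **MLE refitting** maximises the censored-data log-likelihood on the
  log-parameter scale (Nelder-Mead, relative tolerance 1e-8, three starting
  points) — `flexsurv` serves as an independent oracle in the tests, never
  as the implementation.
* **KM reconstruction** follows the iterative numbers-at-risk algorithm:
  censoring within each risk-table interval is spread uniformly, events are
  placed before censorings at tied times, and subjects remaining after the
  last coordinate are censored there; the reconstruction must reproduce the
  input curve within 0.02 absolute and account for every subject.
* **The cohort engine's correctness oracle** is an individual-level
  simulation that draws state sojourns by inverse-CDF sampling from the
  same per-cycle probabilities (an algorithmically independent route).
  Because per-subject QALYs are heavy-tailed, the oracle uses stratified
  (Latin-hypercube) uniforms per draw dimension — unbiased, with Monte
  Carlo error comfortably below the 1% agreement level at 10,000 subjects
  used in the tests.
* **Problem sizes** in the shipped analyses: 521 cycles, 1,000 PSA
  iterations, 10,000-subject oracle runs, 200–500-subject reconstruction
  experiments — the scale of the original analysis, and small enough that
  the whole suite runs in minutes on one CPU.
* Degenerate inputs are contracts, not crashes: all-censored data refuse to
  fit; a flat KM curve reconstructs to all-censored records; zero-cost
  configurations yield exactly zero total cost; occupancy conservation is
  asserted every cycle at 1e-9.

## The synthetic-data generator

`simulate_ipd()` draws censored samples from the model's own laws by
inverse CDF (uniform or administrative censoring), `km_with_risk_table()`
turns them into the digitised-curve format, and `synthetic_life_table()`
produces the Gompertz background-mortality stand-in. The generator emulates
the *shape* of trial data — censoring patterns, risk-table granularity,
sample sizes — but not digitisation error of real published figures,
informative censoring, or covariate structure. Passing the round-trip and
recovery tests therefore shows the pipeline is self-consistent at trial
scale, not that reconstruction from any particular published figure would
recover that trial's parameters.

## What reproduces, what does not, and why

With all placeholder defaults fixed as above, the primary comparison lands
close to the published results: costs within 3% (PC $7,847 vs $8,082) and
1% (CPC $11,605 vs $11,519), incremental QALYs 0.387 vs 0.41, ICER $9,702
vs $8,378/QALY (within the ±20% band the reproduction targets), the
camrelizumab price threshold $489 vs $554, and the PFS-HR threshold 0.773
vs 0.81. The PPP total cost matches to 0.1% ($18,218 vs $18,230).

Two published quantities resist reproduction, for reasons the model makes
visible:

* **The secondary increment.** The published PPP-vs-CPC gain (0.10 QALYs,
  ICER $65,563) sits very close to the zero-crossing of a steep response
  in the PFS hazard ratio: at the threshold HR of 0.773 the incremental
  QALYs must equal ΔC/WTP ≈ 0.59 (from `results/thresholds.csv` and the
  base-case ΔC), against 0.21 at HR = 0.92 — about −0.25 QALYs per 0.1 of
  HR. A shift of ~0.04 in the effective HR anchor — well inside the
  uncertainty created by the unavailable survival supplement — therefore
  doubles or halves the increment, and the published one-way DSA shows the
  same steepness (its low-HR bound flips the verdict outright). Our run
  gives 0.21 QALYs and $31,152/QALY. The *threshold* (where the verdict
  flips), which is the decision-relevant quantity on such a slope, does
  reproduce (0.773 vs 0.81), as does the conclusion: PPP is far from
  cost-effective at its current price.
* **The PSA acceptability (36%).** Our PSA gives ~68% probability that CPC
  is cost-effective at $11,146/QALY. A 36% figure implies the *median* PSA
  ICER exceeded WTP even though the deterministic ICER ($8,378) and every
  published one-way bound except the camrelizumab price ceiling fall below
  it; we could not construct a distributional convention consistent with
  both published facts, and report the number our stated conventions
  produce. The qualitative CEAC behaviour reproduces: acceptability rises
  steeply with WTP, and PPP is rarely cost-effective against CPC (12% of
  secondary-PSA iterations at WTP; the published analysis reported none).

## Limitations

Second-line curves are indexed by model time (no per-state clock for
hazards); the prog2 death hazard borrows the second-line OS model;
supplement-only inputs are reconstructed, not observed; PSA samples
parameters independently; costs are payer-perspective USD with no
inflation indexing; and the indirect comparison module implements a
fixed-effect anchored contrast, not the Bayesian network meta-analysis
whose point estimates the model takes as inputs.
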