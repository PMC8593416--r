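analysis: primary
settings:
  cycle_days: 21.0
  horizon_years: 30.0
  discount_annual: 0.05
  wtp: 11146.0
  start_age: 60.0
  half_cycle_correction: no
parameters:
  os_cpc_theta:
    base: 0.003326
    dist: fixed
  os_cpc_kappa:
    base: 1.54225
    dist: fixed
    provenance: calibrated
  os_pc_theta:
    base: 0.004501
    dist: fixed
  os_pc_kappa:
    base: 1.618052
    dist: fixed
  pfs_cpc_theta:
    base: 0.01503
    dist: fixed
  pfs_cpc_kappa:
    base: 1.46627
    dist: fixed
  pfs_pc_theta:
    base: 0.03905
    dist: fixed
  pfs_pc_kappa:
    base: 1.36768
    dist: fixed
  os2_scale:
    base: 0.07471
    dist: fixed
  os2_shape:
    base: 1.15519
    dist: fixed
  pfs2_scale:
    base: 0.2507
    dist: fixed
  pfs2_shape:
    base: 1.1423
    dist: fixed
  hr_os_ppp:
    base: 0.71
    low: 0.57
    high: 0.85
    dist: lognormal
  hr_pfs_ppp:
    base: 0.92
    low: 0.74
    high: 1.1
    dist: lognormal
  hr_os_niv:
    base: 0.76
    low: 0.56
    high: 1.04
    dist: lognormal
  hr_pfs_niv:
    base: 0.87
    low: 0.46
    high: 1.19
    dist: lognormal
  cost_camrelizumab:
    base: 424.51
    low: 212.25
    high: 636.76
    dist: gamma
  cost_pembrolizumab:
    base: 2597.79
    low: 1298.89
    high: 3896.69
    dist: gamma
  cost_pemetrexed:
    base: 79.31
    low: 39.65
    high: 118.96
    dist: gamma
  cost_nivolumab:
    base: 60.35
    low: 30.17
    high: 90.52
    dist: gamma
  cost_docetaxel:
    base: 5.61
    low: 2.81
    high: 8.41
    dist: gamma
  cost_followup:
    base: 55.6
    low: 27.8
    high: 83.4
    dist: gamma
  cost_third_line:
    base: 854.05
    low: 427.02
    high: 1281.08
    dist: gamma
  cost_bsc:
    base: 337.5
    low: 168.75
    high: 506.25
    dist: gamma
  cost_eol:
    base: 2627.8
    low: 1313.9
    high: 3941.7
    dist: gamma
  cost_ae_cpc:
    base: 1407.53
    low: 703.77
    high: 2111.3
    dist: gamma
  cost_ae_ppp:
    base: 1141.48
    low: 570.74
    high: 1712.22
    dist: gamma
  cost_ae_pc:
    base: 883.9
    low: 441.95
    high: 1325.85
    dist: gamma
  u_stable:
    base: 0.856
    low: 0.718
    high: 0.994
    dist: beta
  u_prog1:
    base: 0.768
    low: 0.595
    high: 0.941
    dist: beta
  u_prog2:
    base: 0.703
    low: 0.545
    high: 0.861
    dist: beta
  du_cpc:
    base: 0.079
    low: 0.061
    high: 0.096
    dist: beta
  du_ppp:
    base: 0.045
    low: 0.035
    high: 0.056
    dist: beta
  du_pc:
    base: 0.063
    low: 0.049
    high: 0.077
    dist: beta
  discount_rate:
    base: 0.05
    low: 0.0
    high: 0.08
    dist: fixed
  weight:
    base: 65.0
    low: 52.0
    high: 78.0
    dist: normal
  bsa:
    base: 1.72
    low: 1.38
    high: 2.07
    dist: normal
  start_age:
    base: 60.0
    low: 55.0
    high: 65.0
    dist: fixed
    provenance: assumed
  cap_1l_cpc:
    base: 10.0
    low: 8.0
    high: 12.0
    dist: fixed
    provenance: assumed
  cap_1l_pc:
    base: 12.0
    low: 9.0
    high: 15.0
    dist: fixed
    provenance: assumed
  cap_1l_ppp:
    base: 11.0
    low: 8.0
    high: 14.0
    dist: fixed
    provenance: assumed
  cap_2l:
    base: 4.0
    low: 3.0
    high: 5.0
    dist: fixed
    provenance: assumed
  pembro_paid_cycles:
    base: 4.0
    dist: fixed
  frac_2l:
    base: 0.5
    low: 0.25
    high: 0.75
    dist: fixed
    provenance: assumed
  frac_3l:
    base: 0.5
    low: 0.25
    high: 0.75
    dist: fixed
    provenance: assumed
  lt_base_prob:
    base: 0.009
    dist: fixed
    provenance: assumed
  lt_slope:
    base: 0.0861777
    dist: fixed
    provenance: assumed
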