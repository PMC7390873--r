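horizon_cycles: 120
cycle_length_months: 1
start_age: 64.0
discount_rate_annual: 0.035
initial_nyha:
  NYHA_I: 0.045
  NYHA_II: 0.716
  NYHA_III: 0.231
  NYHA_IV: 0.008
wtp_thresholds:
  gdp_per_capita: 10276.0
  gdp_x3: 30828.0
psa_draws: 10000
seed: 723
options:
  weibull_mode: raw
  hosp_anchor: 0.00868
  calibration_window: 120
  hr_scale: rate
  disutility_mode: per_event
  readmission_mode: unconditional
  drug_copay_is_reimbursed: yes
  inpatient_copay_is_patient_share: yes
hazards:
  hospitalization:
    family: weibull
    lam: -0.00097
    shape: 1.02685
    low: 0.00868
    up: 0.0145
  cv_death:
    family: exponential
    lam: -0.00577
    low: 0.00412
    up: 0.00844
params:
  readmission: 0.0147
  nyha_progress_enalapril: 0.0088
  nyha_progress_sacval: 0.0068
  hr_hosp_sacval: 0.79
  hr_cvdeath_sacval: 0.8
  hr_hosp_nyha3: 1.71
  hr_hosp_nyha4: 3.4
  rr_cvdeath_nyha3: 1.372
  rr_cvdeath_nyha4: 1.64
  utility_nyha12: 0.78
  utility_nyha3: 0.715
  utility_nyha4: 0.66
  disutility_hosp: 0.1
  disutility_readmit: 0.1
  cost_sacval_monthly: 17.120000000000001
  cost_enalapril_monthly: 10.65
  cost_outpatient_monthly: 41.560000000000002
  copay_inpatient: 0.3
  cost_hosp_event: 1920.490000000000009
  cost_readmit_event: 1340.049999999999955
drugs:
  sacval:
    dose: 200 mg twice daily
    unit_price: 1.42
    copay_ratio: 0.8
    monthly_price: 85.609999999999999
    monthly_cost: 17.120000000000001
  enalapril:
    dose: 10 mg twice daily
    unit_price: 0.18
    copay_ratio: 0.0
    monthly_price: 10.65
    monthly_cost: 10.65
mortality:
  age:
  - 1.0
  - 5.0
  - 10.0
  - 15.0
  - 20.0
  - 25.0
  - 30.0
  - 35.0
  - 40.0
  - 45.0
  - 50.0
  - 55.0
  - 60.0
  - 65.0
  - 70.0
  - 75.0
  - 80.0
  - 85.0
  - 100.0
  annual_prob:
  - 0.002949
  - 0.000284
  - 0.00015
  - 0.000169
  - 0.000177
  - 0.000154
  - 0.000298
  - 0.000458
  - 0.000472
  - 0.00071
  - 0.0011998
  - 0.0029394
  - 0.0028332
  - 0.0066972
  - 0.0097194
  - 0.0121676
  - 0.016739
  - 0.0331037
  - 1.0
nyha_matrix:
- - 0.0
  - 0.831
  - 0.169
  - 0.0
- - 0.422
  - 0.0
  - 0.531
  - 0.047
- - 0.0
  - 0.847
  - 0.0
  - 0.153
- - 0.0
  - 0.0
  - 1.0
  - 0.0
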