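# hipscreen default configuration.
# Every value here is the package default; user configs may override any
# subset of keys (unknown keys are rejected).

random_seed: 1

cohort:
  n_pairs: 50                   # fracture/control pairs (cohort = 2 * n_pairs)
  mean_strength: 3265           # population mean femoral strength, N
  auc_mss: 0.82                 # target discrimination AUC of FE-predicted strength
  auc_abmd: 0.75                # target discrimination AUC of aBMD
  see_fraction: 0.155           # FE prediction error, fraction of mean strength (%SEE/100)
  ser_fraction: 0.22            # strength-on-aBMD regression error, fraction (%SER/100)
  tscore_reference_mean: 0.942  # young-adult femoral-neck aBMD reference mean, g/cm^2
  tscore_reference_sd: 0.122    # young-adult reference SD, g/cm^2
  abmd_slope: 0.00025           # expected aBMD per newton of strength (1 g/cm^2 per 4000 N)
  abmd_intercept: 0.2           # g/cm^2
  age_min: 55                   # years, uniform range
  age_max: 90
  weight_mean: 65               # kg (65 kg puts four body-weight forces at ~2551 N)
  weight_sd: 10
  height_mean: 160              # cm
  height_sd: 7
  min_strength: 200             # positivity floor for strength draws, N

thresholds:
  tscore_treat_cutoff: -2.5     # WHO osteoporosis intervention threshold (inclusive)
  tscore_safe_cutoff: -1.0      # discharge above this T-score (dual pathway)
  mss_cutoff: 2551              # treat at or below this FE-predicted strength, N
  mss_absolute: 3000            # alternative absolute strength threshold, N
  bw_multiple: 4                # body-weight-multiple strength threshold
  g: 9.81                       # m/s^2 for body-weight conversion

treatment:
  efficacy: 0.40                # fraction of fractures prevented among treated

costs:                          # GBP; UK NHS 2016/17 tariffs and published estimates
  dxa_exam: 62
  ct_exam: 78
  simulation: 250               # FE analysis service per case
  specialist_visit: 189
  radiographer_per_case: 8
  per_assessment_dxa: 251       # stated per-visit total, DXA pathway
  per_assessment_qct: 522       # stated per-visit total, strength pathway
  treatment_per_patient_horizon: 7200  # £60/month over the 10-year horizon
  fracture_direct: 16302        # direct cost per hip fracture
  fracture_indirect: 10364      # indirect cost per hip fracture
  horizon_years: 10
  assessment_interval_years: 2
  discount_rate: 0

qaly:
  qaly_no_fracture: 0.91        # women over 55, no fracture
  qaly_fracture: 0.63           # after hip fracture
  willingness_to_pay: 30000     # GBP per QALY (upper NICE benchmark)

pathways:
  scale_to: 1000                # project tallies per this many referred patients

trial:
  mean_strength: 3265
  sd_abmd: 3054                 # predictor SD, aBMD arm, N
  sd_qct: 2199                  # predictor SD, FE-strength arm, N
  n_per_group_abmd: 123         # reference group size, aBMD arm
  detect_fraction: 0.20         # difference to detect, fraction of mean strength
  alpha: 0.05
  power: 0.80
  fixed_per_patient: 5000       # GBP
  dxa_cost: 62
  ct_cost: 78
  simulation_cost: 250

radiation:
  baseline_fracture_death_risk: 0.028  # death related to hip fracture, women > 50
  accuracy_gain: 0.07                  # 7 pp identification gain
  treatment_efficacy: 0.40
  cancer_risk_per_ct: 0.000154         # at 3.8 mSv effective dose
  cancer_mortality: 0.52
  dose_dxa_msv: 0.001
  dose_ct_standard_msv: 6
  dose_ct_protocol_msv: [1.3, 4.8]     # whole-femur low-dose protocol range
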