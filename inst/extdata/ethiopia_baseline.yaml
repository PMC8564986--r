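# Baseline scenario: annual screening mammography, Ethiopian cohort.
# Stage distributions are stored as printed (each sums to 1.001); the loader
# renormalizes proportionally. Parameter provenance: see
# ethiopia_baseline_provenance.csv alongside this file.
schema_version: 1
cohort_size: 100000
horizon_cycles: 10
cycle_length_years: 1
wtp_threshold: 2808.5        # 3 x GDP per capita, USD per life-year
other_cause_mortality: 0.0   # structural state; no published rate
discounts:
  cost_rate: 0.05
  effect_rate: 0.03
policy:
  name: government
  private_share: 0.0
costs:
  mammography_gov: 4.5
  mammography_private: 42
  doctor_visit: 6
  fnac: 22
  treatment_by_stage:
    I: 160
    II: 458.48
    III: 850.45
    IV: 668.7
age_groups:
  40-49:
    annual_incidence: 0.000878
    sensitivity: 0.821
    specificity: 0.859
    remaining_life_years:
      40-44: 36.10367697
      45-49: 31.72113989
    lyg_per_death_averted: 31.3958
  50-59:
    annual_incidence: 0.00079
    sensitivity: 0.921
    specificity: 0.859
    lyg_per_death_averted: 23.9052
reference_incidence:
  30-39: 0.000853
  60-69: 0.000656
transitions:
  I_40-49:
    stage_group: I
    age_group: 40-49
    p_rem_local: 0.01
    p_rem_dist: 0.000016
    p_local_dist: 0.062
    p_local_death: 0.013
    p_dist_death: 0.555
  I_50-59:
    stage_group: I
    age_group: 50-59
    p_rem_local: 0.009
    p_rem_dist: 0.000025
    p_local_dist: 0.052
    p_local_death: 0.013
    p_dist_death: 0.137
  II_III_40-49:
    stage_group: II_III
    age_group: 40-49
    p_rem_local: 0.018
    p_rem_dist: 0.024
    p_local_dist: 0.165
    p_local_death: 0.0
    p_dist_death: 0.386
  II_III_50-59:
    stage_group: II_III
    age_group: 50-59
    p_rem_local: 0.016
    p_rem_dist: 0.105
    p_local_dist: 0.13
    p_local_death: 0.0
    p_dist_death: 0.423
  IV_40-49:
    stage_group: IV
    age_group: 40-49
    p_rem_local: 0.0
    p_rem_dist: 0.0
    p_local_dist: 0.0
    p_local_death: 0.0
    p_dist_death: 0.386
  IV_50-59:
    stage_group: IV
    age_group: 50-59
    p_rem_local: 0.0
    p_rem_dist: 0.0
    p_local_dist: 0.0
    p_local_death: 0.0
    p_dist_death: 0.423
stage_distributions:
  screened:
    I: 0.521
    II: 0.382
    III: 0.057
    IV: 0.041
  non_screened:
    I: 0.1
    II: 0.189
    III: 0.569
    IV: 0.143
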