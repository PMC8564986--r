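parameter,value,units,source
age_groups.40-49.annual_incidence,0.000878,probability per woman-year,"Kantelhardt et al. age distribution extrapolated to national incidence via WHO cancer data for Ethiopia"
age_groups.50-59.annual_incidence,0.00079,probability per woman-year,"Kantelhardt et al. age distribution extrapolated to national incidence via WHO cancer data for Ethiopia"
reference_incidence.30-39,0.000853,probability per woman-year,"Kantelhardt et al.; band excluded from the model (no validated screening protocol under 40)"
reference_incidence.60-69,0.000656,probability per woman-year,"Kantelhardt et al.; band excluded from the model (lower Ethiopian life expectancy)"
age_groups.40-49.sensitivity,0.821,probability,"Keen et al., age-specific screening mammography test characteristics"
age_groups.50-59.sensitivity,0.921,probability,"Keen et al., age-specific screening mammography test characteristics"
age_groups.40-49.specificity,0.859,probability,"Keen et al., age-specific screening mammography test characteristics"
age_groups.50-59.specificity,0.859,probability,"Keen et al., age-specific screening mammography test characteristics"
transitions.I_40-49.p_rem_local,0.01,per-cycle probability,"Gocgun et al. Markov model transition rates"
transitions.I_40-49.p_rem_dist,0.000016,per-cycle probability,"Gocgun et al. Markov model transition rates"
transitions.I_40-49.p_local_dist,0.062,per-cycle probability,"Gocgun et al. Markov model transition rates"
transitions.I_40-49.p_local_death,0.013,per-cycle probability,"Gocgun et al.; published once without an age split, applied to both age bands"
transitions.I_40-49.p_dist_death,0.555,per-cycle probability,"Gocgun et al. Markov model transition rates"
transitions.I_50-59.p_rem_local,0.009,per-cycle probability,"Gocgun et al. Markov model transition rates"
transitions.I_50-59.p_rem_dist,0.000025,per-cycle probability,"Gocgun et al. Markov model transition rates"
transitions.I_50-59.p_local_dist,0.052,per-cycle probability,"Gocgun et al. Markov model transition rates"
transitions.I_50-59.p_local_death,0.013,per-cycle probability,"Gocgun et al.; published once without an age split, applied to both age bands"
transitions.I_50-59.p_dist_death,0.137,per-cycle probability,"Gocgun et al. Markov model transition rates"
transitions.II_III_40-49.p_rem_local,0.018,per-cycle probability,"Gocgun et al.; stages II and III published as one rate set"
transitions.II_III_40-49.p_rem_dist,0.024,per-cycle probability,"Gocgun et al.; stages II and III published as one rate set"
transitions.II_III_40-49.p_local_dist,0.165,per-cycle probability,"Gocgun et al.; stages II and III published as one rate set"
transitions.II_III_40-49.p_local_death,0,per-cycle probability,"no published local-recurrence-to-death rate for stages II & III; default 0"
transitions.II_III_40-49.p_dist_death,0.386,per-cycle probability,"Gocgun et al.; stages II and III published as one rate set"
transitions.II_III_50-59.p_rem_local,0.016,per-cycle probability,"Gocgun et al.; stages II and III published as one rate set"
transitions.II_III_50-59.p_rem_dist,0.105,per-cycle probability,"Gocgun et al.; stages II and III published as one rate set"
transitions.II_III_50-59.p_local_dist,0.13,per-cycle probability,"Gocgun et al.; stages II and III published as one rate set"
transitions.II_III_50-59.p_local_death,0,per-cycle probability,"no published local-recurrence-to-death rate for stages II & III; default 0"
transitions.II_III_50-59.p_dist_death,0.423,per-cycle probability,"Gocgun et al.; stages II and III published as one rate set"
transitions.IV_40-49.p_dist_death,0.386,per-cycle probability,"Gocgun et al.; stage IV enters the chain in the distant-recurrence state"
transitions.IV_50-59.p_dist_death,0.423,per-cycle probability,"Gocgun et al.; stage IV enters the chain in the distant-recurrence state"
stage_distributions.screened,"0.521, 0.382, 0.057, 0.041 (I-IV, printed; renormalized from sum 1.001)",proportions,"Wong et al., Chinese screening programme stage distribution"
stage_distributions.non_screened,"0.1, 0.189, 0.569, 0.143 (I-IV, printed; renormalized from sum 1.001)",proportions,"Tesfaw et al., Ethiopian clinical stage-at-diagnosis distribution"
costs.mammography_gov,4.5,USD per exam,"mean reported government-institution price (institutional communication)"
costs.mammography_private,42,USD per exam,"mean reported private-institution price (institutional communication)"
costs.doctor_visit,6,USD per visit,"mean reported price (institutional communication)"
costs.fnac,22,USD per procedure,"mean reported price (institutional communication)"
costs.treatment_by_stage.I,160,USD per diagnosed case,"Hoang Lan et al., stage-specific direct medical treatment costs"
costs.treatment_by_stage.II,458.48,USD per diagnosed case,"Hoang Lan et al., stage-specific direct medical treatment costs"
costs.treatment_by_stage.III,850.45,USD per diagnosed case,"Hoang Lan et al., stage-specific direct medical treatment costs"
costs.treatment_by_stage.IV,668.7,USD per diagnosed case,"Hoang Lan et al., stage-specific direct medical treatment costs"
age_groups.40-49.remaining_life_years.40-44,36.10367697,years,"WHO life tables for Ethiopia"
age_groups.40-49.remaining_life_years.45-49,31.72113989,years,"WHO life tables for Ethiopia"
age_groups.40-49.lyg_per_death_averted,31.3958,years per death averted,"calibration constant: baseline life-years gained 2466.14 divided by baseline deaths averted 78.55"
age_groups.50-59.lyg_per_death_averted,23.9052,years per death averted,"calibration constant: baseline life-years gained 2566.93 divided by baseline deaths averted 107.38"
discounts.cost_rate,0.05,annual proportion,"analysis convention: 5% annual discounting of costs"
discounts.effect_rate,0.03,annual proportion,"analysis convention: 3% annual discounting of life-years"
wtp_threshold,2808.5,USD per life-year,"3 x Ethiopian GDP per capita (2020 World Bank report); threshold variants 2808.9 and 2808 also circulate; treated as a free parameter"
cohort_size,100000,women,"analysis convention: results per 100,000 women"
horizon_cycles,10,annual cycles,"analysis convention: 10 annual screening rounds"
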