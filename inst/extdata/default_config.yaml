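version: '1.0'
benefit_values:
  condition_severity:
    mild: 1.0
    moderate: 3.0
    severe: 5.0
  condition_prevalence:
    population_subset: 2.0
    general_population: 3.0
    rare_orphan: 5.0
  treatment_availability:
    many_4_plus: 1.0
    some_1_to_3: 3.0
    none_exist: 5.0
  durability:
    not_consistent: 1.0
    likely_semi_robust: 3.0
    consistent_substantial: 5.0
orphan_multiplier: 1.25
gbs_ceiling: 100.0
risk_severity_values:
  mild: 1.0
  moderate: 3.0
  severe: 5.0
risk_frequency_values:
  low: 1.0
  medium: 3.0
  high: 5.0
mitigation_values:
  routine_pharmacovigilance: 0.0
  label_warning_precaution: 1.0
  boxed_warning: 2.0
  monitored_administration: 3.0
  postmarketing_study_registry: 4.0
  rems: 5.0
residual_floor: 1.0
nbs_bands:
  thresholds:
  - 0.0
  - 25.0
  - 60.0
  labels:
  - negative
  - marginal_low
  - medium
  - high
brr_bands:
  thresholds:
  - 1.0
  - 3.0
  - 10.0
  labels:
  - negative
  - marginal_low
  - medium
  - high
brr_decimals: 2
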