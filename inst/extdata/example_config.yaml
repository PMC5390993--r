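# Example cohort configuration for cohort_config_from_yaml().
# Scalar fields map onto cohort_config() arguments; variable_specs maps
# variable names to variable_spec() fields, with class-conditional means
# written as named maps (fast/slow for decline-linked variables,
# high/low for survival-linked ones).
n_subjects: 50
fraction_fast: 0.21
missing_rate: 0.1
followup_censor_rate: 0.53
seed: 1
variable_specs:
  alsfrs_total:
    family: exponential
    A_mean: 39.4
    A_sd: 5.28
    k_mean: {fast: 0.004, slow: 0.0005}
    k_sd: {fast: 0.001, slow: 0.00015}
    noise_sd: 1.5
    link: decline
    A_range: [10, 48]
  weight:
    family: exponential
    A_mean: 75.6
    A_sd: 18.3
    k_mean: {fast: 0.0005, slow: 0.00015}
    k_sd: 0.00008
    noise_sd: 1.0
    link: decline
  pulse:
    family: exponential
    A_mean: 75
    A_sd: 9
    k_mean: {high: -0.0007, low: -0.0001}
    k_sd: 0.00012
    noise_sd: 3
    link: survival
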