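# Example end-to-end configuration for mrcea::run_pipeline().
# The generator block feeds cohort_params(); the intervention block mirrors
# the prostate-cancer SGLT2-inhibition scenario (OR 0.29, CI 0.13-0.65,
# annual drug cost GBP 470.40, GBP 20,000/QALY threshold).
seed: 20260920

generator:
  n_individuals: 4000
  n_variants: 8
  prevalence: 0.05
  beta_cost: 800
  beta_qaly: -0.05
  missing_rate: 0.3

analysis:
  scheme: beta
  outcomes: [annual_cost, annual_qaly]
  m_imputations: 5

intervention:
  or: 0.29
  or_ci: [0.13, 0.65]
  drug_cost_annual: 470.40
  wtp_threshold: 20000
  n_draws: 2000
  counts:
    n_cases: 6155
    n_total: 144032
    label: all
  effects:
    cost_effect: 134
    cost_ci: [-217, 485]
    qaly_effect: -2.68
    qaly_ci: [-7.48, 2.12]
    source: mendelian_randomization
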