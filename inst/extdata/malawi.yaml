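# Indicative parameterisation for a fledgling universal-health-coverage
# setting (Malawi-like). Moments are natural-scale mean/sd of log-normal
# margins. Units: costs and threshold in USD, population in thousands of
# cases, budget in USD millions.
name: Malawi
currency: USD
benefit_unit: DALY
q_mean: 7.05
q_sd: 16.93
c_mean: 20
c_sd: 30
p_mean: 1464.74
p_sd: 2910.67
n_candidates: 40
threshold: 2
budget: 120
n_funded: 14
capacity_pct: 20
phase_years: 5
phase_target_pct: 100
hta_unit_cost: 0
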