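# Indicative parameterisation for an established universal-health-coverage
# setting (UK-like). Moments are natural-scale mean/sd of log-normal margins.
# Units: costs and threshold in GBP (cost per case mean is 9.14 thousand GBP),
# population in thousands of cases, budget in GBP millions.
name: UK
currency: GBP
benefit_unit: QALY
q_mean: 0.62
q_sd: 1.18
c_mean: 9140
c_sd: 19050
p_mean: 540.22
p_sd: 595.41
n_candidates: 74
threshold: 20000
budget: 75000
n_funded: 48
capacity_pct: 20
phase_years: 5
phase_target_pct: 100
hta_unit_cost: 0
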