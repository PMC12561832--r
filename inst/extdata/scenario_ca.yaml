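# Simulation scenario: Concentration Addition truth.
# truth_a / truth_b: either {model, ec50_ugL, beta} or {model, alpha, beta,
# conc_scale, alpha_sign}. Ladder endpoints are the range-finding C_H / C_L.
truth_a:
  model: Logit
  ec50_ugL: 374.87
  beta: 3.2
truth_b:
  model: Logit
  ec50_ugL: 19988.75
  beta: 2.6
c_high_a: 10000
c_low_a: 10
c_high_b: 1300000
c_low_b: 300
n_points: 12
replicates: 3
sigma: 0.02          # OD-scale noise standard deviation
noise_scale: od      # or "effect"
control_od: 0.5
background_od: 0
interaction: CA_truth
kappa: 1
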