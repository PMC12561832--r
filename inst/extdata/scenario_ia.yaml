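# Simulation scenario: Independent Action truth.
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
sigma: 0.02
noise_scale: od
control_od: 0.5
background_od: 0
interaction: IA_truth
kappa: 1
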