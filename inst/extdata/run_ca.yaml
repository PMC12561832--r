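# Full pipeline run configuration: simulate a CA-truth study and assess all
# six mixture rays (five EquRay rays plus the fixed 1:10 environmental ratio).
scenario:
  truth_a: {model: Logit, ec50_ugL: 374.87, beta: 3.2}
  truth_b: {model: Logit, ec50_ugL: 19988.75, beta: 2.6}
  c_high_a: 10000
  c_low_a: 10
  c_high_b: 1300000
  c_low_b: 300
  n_points: 12
  replicates: 3
  sigma: 0.02
  control_od: 0.5
  interaction: CA_truth
rays:
  equray: {n_rays: 5}
  fixed_ratio: {ratio_a: 1, ratio_b: 10}
models: [Logit, Weibull]
level: 0.95
noec_method: dunnett
orientation: effect
band_edges_ugL: [1000, 20000]
out_dir: raymix-out
seed: 1
log_level: info
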