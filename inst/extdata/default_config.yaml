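# Default run configuration: reproduces the canonical experiment settings.
seed: 1
log_level: info
paths:
  params: null          # null = parameter file shipped with the package
  out_dir: cvsude_out
solver:
  method: ode45
  hmax: 0.01
  atol: 1.0e-7
  rtol: 1.0e-4
  dt: 0.01
training:
  window: 0.3
  noise: 0.05
  stage1_lr: 0.01
  stage1_iters: 1000
  stage2_lr: 1.0e-4
  stage2_iters: 100
  threshold: null       # null = canonical threshold by noise (1 / 8 / 50)
  ensemble_size: 10
  max_attempts: 50
  nsub: 4
sr:
  population: 400
  generations: 40
  tournament: 5
  p_crossover: 0.6
  p_subtree: 0.25
  p_point: 0.1
  max_complexity: 30
  p_exp: 0.1
  optimize_constants: true
  subsample: 2000
  horizon: 0.75
evaluation:
  t_end: 10.0
  horizon: 10.0
  table_window: 0.3
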