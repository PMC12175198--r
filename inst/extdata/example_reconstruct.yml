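# Joint reconstruction of the stack written by example_simulate.yml:
# recovers the high-resolution complex object together with defocus,
# pupil Zernike coefficients and per-LED intensity factors.
mode: reconstruct
log_level: info
paths:
  stack: fpm_example/stack
  out: fpm_example
optimizer:
  loss_kind: L1
  epochs: 200
  batch_size: 13
  seed: 0
  learning_rates:
    spectrum: 1.0e-2
    pupil: 1.0e-3
    z: 1.0e-1
    gamma: 3.0e-3
  lr_schedule: cosine
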