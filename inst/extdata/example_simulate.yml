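# Simulate a 13x13-LED green-channel capture stack of a synthetic tissue
# phantom under the package's reference acquisition geometry.
# Lengths in um except led_pitch and led_height (mm).
mode: simulate
log_level: info
paths:
  out: fpm_example
optical:
  wavelength: 0.523
  objective_na: 0.3
  magnification: 10
  camera_pixel: 6.5
  led_grid: [13, 13]
  led_pitch: 4
  led_height: 52
  hr_upsample: 4
  lr_shape: [32, 32]
phantom:
  kind: tissue
  size: 128
  mu_range: [0.0, 1.5]
  phi_range: [0.0, 1.5]
  feature_scale: 2.0
  seed: 2
simulate:
  z: 0.0
  gammas: 1.0
  seed: 0
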