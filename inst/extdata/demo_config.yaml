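seed: 42
n_subjects: 3
n_repeats: 3
grid:
  nx: 32
  ny: 32
  voxel_dims:
  - 0.4
  - 0.4
  - 2.0
noise_sigma: 0.02
b0_coef:
- 0.0
- 0.05
- -0.04
- 0.02
- 0.03
- -0.02
classes:
- name: contralateral
  ph: 7.0
  shape: ellipse
  center:
  - 0.3
  - 0.5
  radii:
  - 0.16
  - 0.28
- name: peritumoral
  ph: 7.05
  shape: annulus
  center:
  - 0.7
  - 0.45
  radii:
  - 0.145
  - 0.17
  inner_radii:
  - 0.1
  - 0.12
- name: tumor
  ph: 7.2
  shape: ellipse
  center:
  - 0.7
  - 0.45
  radii:
  - 0.1
  - 0.12
timepoints:
- time: 0.0
  ph: []
- time: 20.0
  ph:
    tumor: 6.89
    contralateral: 6.78
    peritumoral: 6.85
- time: 40.0
  ph: []
cest:
  start: 1.2
  stop: 6.6
  step: 0.1
  refs:
  - -1000.0
  - 1000.0
  b1: 1.5
  duration: 4.0
wassr:
  start: -0.6
  stop: 0.6
  step: 0.03
  refs:
  - -1000.0
  - 1000.0
  b1: 0.2
  duration: 0.1
smoothing: 0.4
wassr_smoothing: gcv
calibration:
  slope: -4.0
  intercept: 12.800000000000001
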