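name: ranitidine
title: Ranitidine HCl floating matrix (2 factors, 3 time points + f2)
config:
  factors:
  - name: x1
    label: Amount of gelucire 43/01
    unit: mg
    levels:
    - 504.0
    - 672.0
    - 840.0
    center: 672.0
    scale: 168.0
  - name: x2
    label: Amount of ethylcellulose
    unit: mg
    levels:
    - 84.0
    - 168.0
    - 252.0
    center: 168.0
    scale: 84.0
  responses:
  - label: y1
    kind: NTB
    lsl: 26.0
    usl: 39.0
    weights:
      mean: 1.0
      var: 1.0
      cv: 1.0
      cov: 1.0
    time: 1.0
    target: 32.5
  - label: y2
    kind: NTB
    lsl: 54.0
    usl: 81.0
    weights:
      mean: 1.0
      var: 1.0
      cv: 1.0
      cov: 1.0
    time: 5.0
    target: 67.5
  - label: y3
    kind: NTB
    lsl: 68.0
    usl: 102.0
    weights:
      mean: 1.0
      var: 1.0
      cv: 1.0
      cov: 1.0
    time: 10.0
    target: 85.0
  - label: f2
    kind: LTB
    lsl: 50.0
    usl: 100.0
    weights:
      mean: 1.0
      var: 1.0
      cv: 1.0
      cov: 1.0
surfaces:
- name: mean_y1
  role: mean
  label: y1
  terms:
  - '1'
  - x1
  - x2
  - x1^2
  - x2^2
  - x1:x2
  coefficients:
  - 37.191000000000003
  - -7.918
  - -3.955
  - 1.148
  - -1.432
  - -0.558
- name: var_y1
  role: variance
  label: y1
  terms:
  - '1'
  - x1
  - x2
  - x1^2
  - x2^2
  - x1:x2
  coefficients:
  - 1.957
  - 0.862
  - -0.693
  - -0.105
  - -0.04
  - -1.32
- name: cv_y1
  role: cv
  label: y1
  terms:
  - '1'
  - x1
  - x2
  - x1^2
  - x2^2
  - x1:x2
  coefficients:
  - 0.038
  - 0.015
  - -0.003
  - -0.002
  - -0.001
  - -0.012
- name: mean_y2
  role: mean
  label: y2
  terms:
  - '1'
  - x1
  - x2
  - x1^2
  - x2^2
  - x1:x2
  coefficients:
  - 75.290000000000006
  - -6.358
  - -8.795
  - 1.035
  - -1.345
  - 0.745
- name: var_y2
  role: variance
  label: y2
  terms:
  - '1'
  - x1
  - x2
  - x1^2
  - x2^2
  - x1:x2
  coefficients:
  - 5.129
  - 0.25
  - 0.915
  - -2.223
  - -0.583
  - -1.18
- name: cv_y2
  role: cv
  label: y2
  terms:
  - '1'
  - x1
  - x2
  - x1^2
  - x2^2
  - x1:x2
  coefficients:
  - 0.031
  - 0.003
  - 0.006
  - -0.009
  - -0.002
  - -0.005
- name: mean_y3
  role: mean
  label: y3
  terms:
  - '1'
  - x1
  - x2
  - x1^2
  - x2^2
  - x1:x2
  coefficients:
  - 89.215999999999994
  - -8.49
  - -7.528
  - 3.797
  - -1.728
  - -3.195
- name: var_y3
  role: variance
  label: y3
  terms:
  - '1'
  - x1
  - x2
  - x1^2
  - x2^2
  - x1:x2
  coefficients:
  - 3.026
  - -0.145
  - -1.292
  - 2.372
  - -1.968
  - 0.75
- name: cv_y3
  role: cv
  label: y3
  terms:
  - '1'
  - x1
  - x2
  - x1^2
  - x2^2
  - x1:x2
  coefficients:
  - 0.017
  - 0.002
  - -0.003
  - 0.007
  - -0.004
  - -0.003
- name: mean_f2
  role: scalar
  label: f2
  terms:
  - '1'
  - x1
  - x2
  - x1^2
  - x2^2
  - x1:x2
  coefficients:
  - 50.156999999999996
  - 7.52
  - 9.473000000000001
  - -5.26
  - -1.49
  - -0.66
printed_optimum:
- name: x1
  coded: -0.909
  uncoded: 657.728799999999978
  consistent: no
- name: x2
  coded: 1.0
  uncoded: 252.0
  consistent: yes
notes:
- 'the published x1 optimum is internally inconsistent: coded -0.909 decodes to 519.288
  mg under the stated coding (x1-672)/168, not the published 657.7288'
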