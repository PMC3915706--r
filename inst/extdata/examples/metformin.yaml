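name: metformin
title: Metformin gel beads (3 factors, 3 time points)
config:
  factors:
  - name: x1
    label: Concentration of sodium alginate
    unit: '%'
    levels:
    - 1.25
    - 1.75
    - 2.25
    center: 1.75
    scale: 0.5
  - name: x2
    label: Concentration of gellan gum
    unit: '%'
    levels:
    - 0.0
    - 0.25
    - 0.5
    center: 0.25
    scale: 0.25
  - name: x3
    label: Concentration of metformin
    unit: '%'
    levels:
    - 2.5
    - 3.75
    - 5.0
    center: 3.75
    scale: 1.25
  responses:
  - label: y1
    kind: NTB
    lsl: 21.0
    usl: 26.0
    weights:
      mean: 1.0
      var: 1.0
      cv: 1.0
      cov: 1.0
    time: 0.5
    target: 23.5
  - label: y2
    kind: NTB
    lsl: 62.0
    usl: 65.0
    weights:
      mean: 1.0
      var: 1.0
      cv: 1.0
      cov: 1.0
    time: 3.5
    target: 63.5
  - label: y3
    kind: NTB
    lsl: 91.0
    usl: 94.0
    weights:
      mean: 1.0
      var: 1.0
      cv: 1.0
      cov: 1.0
    time: 8.0
    target: 92.5
surfaces:
- name: mean_y1
  role: mean
  label: y1
  terms:
  - '1'
  - x1
  - x2
  - x3
  - x1^2
  - x2^2
  - x3^2
  - x1:x2
  - x1:x3
  - x2:x3
  coefficients:
  - 31.152999999999999
  - -3.546
  - -3.884
  - 3.243
  - 0.667
  - 1.874
  - -3.391
  - 2.897
  - -0.767
  - 1.175
- name: var_y1
  role: variance
  label: y1
  terms:
  - '1'
  - x1
  - x2
  - x3
  - x1^2
  - x2^2
  - x3^2
  - x1:x2
  - x1:x3
  - x2:x3
  coefficients:
  - 0.669
  - -0.456
  - -0.45
  - -0.839
  - 1.542
  - -1.429
  - 2.026
  - -1.309
  - -1.167
  - 0.649
- name: cv_y1
  role: cv
  label: y1
  terms:
  - '1'
  - x1
  - x2
  - x3
  - x1^2
  - x2^2
  - x3^2
  - x1:x2
  - x1:x3
  - x2:x3
  coefficients:
  - 0.028
  - 0.002
  - 0.0004
  - -0.016
  - 0.01
  - -0.01
  - 0.022
  - -0.016
  - -0.01
  - 0.002
- name: mean_y2
  role: mean
  label: y2
  terms:
  - '1'
  - x1
  - x2
  - x3
  - x1^2
  - x2^2
  - x3^2
  - x1:x2
  - x1:x3
  - x2:x3
  coefficients:
  - 64.474000000000004
  - -6.603
  - -4.648
  - 3.1
  - -0.977
  - 4.658
  - 1.287
  - -1.168
  - -0.65
  - -0.705
- name: var_y2
  role: variance
  label: y2
  terms:
  - '1'
  - x1
  - x2
  - x3
  - x1^2
  - x2^2
  - x3^2
  - x1:x2
  - x1:x3
  - x2:x3
  coefficients:
  - 0.841
  - -0.063
  - 0.215
  - 0.12
  - -0.173
  - 0.765
  - 0.048
  - -0.084
  - -0.56
  - -0.371
- name: cv_y2
  role: cv
  label: y2
  terms:
  - '1'
  - x1
  - x2
  - x3
  - x1^2
  - x2^2
  - x3^2
  - x1:x2
  - x1:x3
  - x2:x3
  coefficients:
  - 0.011
  - 0.001
  - 0.003
  - -0.001
  - -0.001
  - 0.007
  - -0.0003
  - -3.0e-05
  - -0.004
  - -0.002
- name: mean_y3
  role: mean
  label: y3
  terms:
  - '1'
  - x1
  - x2
  - x3
  - x1^2
  - x2^2
  - x3^2
  - x1:x2
  - x1:x3
  - x2:x3
  coefficients:
  - 92.465999999999994
  - -4.383
  - -2.878
  - 1.811
  - -1.242
  - 2.206
  - -0.987
  - -1.1
  - 0.168
  - 2.018
- name: var_y3
  role: variance
  label: y3
  terms:
  - '1'
  - x1
  - x2
  - x3
  - x1^2
  - x2^2
  - x3^2
  - x1:x2
  - x1:x3
  - x2:x3
  coefficients:
  - 0.895
  - -0.192
  - 0.213
  - -0.302
  - 0.029
  - -0.564
  - 0.786
  - -0.135
  - 0.088
  - -0.284
- name: cv_y3
  role: cv
  label: y3
  terms:
  - '1'
  - x1
  - x2
  - x3
  - x1^2
  - x2^2
  - x3^2
  - x1:x2
  - x1:x3
  - x2:x3
  coefficients:
  - 0.01
  - -0.001
  - 0.001
  - -0.001
  - 0.0001
  - -0.004
  - 0.004
  - -0.001
  - 0.001
  - -0.001
printed_optimum:
- name: x1
  coded: 1.0
  uncoded: 2.25
  consistent: yes
- name: x2
  coded: -0.9192
  uncoded: 0.0202
  consistent: yes
- name: x3
  coded: -1.0
  uncoded: 2.5
  consistent: yes
notes:
- the published coding of x1 ('x1-1.758/1.25') is inconsistent with its levels 1.25/1.75/2.25
  and with the published decode (coded 1 -> 2.25%); center 1.75, scale 0.5 reproduces
  the published table and is used here
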