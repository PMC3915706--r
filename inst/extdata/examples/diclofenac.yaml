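name: diclofenac
title: Diclofenac sodium controlled-release (3 factors, 3 time points)
config:
  factors:
  - name: x1
    label: Stirring speed
    unit: rpm
    levels:
    - 500.0
    - 1000.0
    - 1500.0
    center: 1000.0
    scale: 500.0
  - name: x2
    label: Concentration of calcium chloride
    unit: '%'
    levels:
    - 5.0
    - 10.0
    - 15.0
    center: 10.0
    scale: 5.0
  - name: x3
    label: Percentage of liquid paraffin
    unit: '%'
    levels:
    - 0.0
    - 25.0
    - 50.0
    center: 25.0
    scale: 25.0
  responses:
  - label: y1
    kind: NTB
    lsl: 20.0
    usl: 40.0
    weights:
      mean: 1.0
      var: 1.0
      cv: 1.0
      cov: 1.0
    time: 1.0
    target: 30.0
  - label: y2
    kind: NTB
    lsl: 50.0
    usl: 70.0
    weights:
      mean: 1.0
      var: 1.0
      cv: 1.0
      cov: 1.0
    time: 6.0
    target: 60.0
  - label: y3
    kind: NTB
    lsl: 65.0
    usl: 80.0
    weights:
      mean: 1.0
      var: 1.0
      cv: 1.0
      cov: 1.0
    time: 8.0
    target: 72.5
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
  - 39.929000000000002
  - 2.365
  - -2.206
  - -1.959
  - 0.202
  - 1.971
  - -0.912
  - -1.389
  - 0.797
  - 0.079
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
  - 73.367999999999995
  - 4.388
  - -5.031
  - -2.379
  - 0.399
  - 0.579
  - -0.127
  - -1.525
  - -0.062
  - -0.359
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
  - 83.203000000000003
  - 4.165
  - -4.562
  - -2.498
  - -0.624
  - -0.907
  - 1.176
  - -2.37
  - 0.151
  - -1.632
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
  - 7.31
  - -0.642
  - 0.032
  - 2.799
  - 1.698
  - 5.377
  - 4.895
  - 5.543
  - 1.893
  - -0.686
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
  - 5.74
  - -1.195
  - 1.609
  - -5.458
  - 7.112
  - 0.037
  - 9.608000000000001
  - 11.9
  - -4.042
  - 0.98
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
  - 11.548
  - -6.216
  - 3.632
  - -0.354
  - 2.053
  - 2.293
  - 2.581
  - -5.282
  - 2.575
  - -5.902
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
  - 0.063
  - -0.005
  - -0.001
  - 0.012
  - 0.007
  - 0.008
  - 0.014
  - 0.021
  - 0.008
  - -0.003
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
  - 0.04
  - -0.002
  - 0.007
  - -0.003
  - 0.006
  - -0.004
  - 0.009
  - 0.013
  - -0.008
  - 0.004
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
  - 0.039
  - -0.009
  - 0.008
  - 0.002
  - -0.0002
  - 0.004
  - 0.006
  - -0.007
  - 0.002
  - -0.006
- name: cov_y1_y2
  role: covariance
  label: y1_y2
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
  - 1.89
  - 2.507
  - -0.799
  - 0.299
  - 0.677
  - -2.227
  - -4.571
  - -2.594
  - -0.655
  - -2.289
  pair:
  - y1
  - y2
- name: cov_y1_y3
  role: covariance
  label: y1_y3
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
  - 1.091
  - 1.603
  - -1.572
  - 3.023
  - -3.872
  - -3.299
  - 3.353
  - -1.879
  - 0.966
  - 2.559
  pair:
  - y1
  - y3
  note: the published x1/x2 terms are typographically fused ('1.603x11.572x2'); stored
    as +1.603*x1 - 1.572*x2, the sign of the x2 term being unrecoverable
- name: cov_y2_y3
  role: covariance
  label: y2_y3
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
  - -2.945
  - -1.711
  - -1.729
  - -3.296
  - 2.541
  - 2.411
  - -2.738
  - -0.22
  - 3.237
  - 3.732
  pair:
  - y2
  - y3
printed_optimum:
- name: x1
  coded: -0.7576
  uncoded: 621.200000000000045
  consistent: yes
- name: x2
  coded: -0.3939
  uncoded: 8.0305
  consistent: yes
- name: x3
  coded: 1.0
  uncoded: 50.0
  consistent: yes
notes: []
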