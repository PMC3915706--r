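name: verapamil
title: Verapamil HCl coated pellets (3 factors, 5 time points)
config:
  factors:
  - name: x1
    label: Coating weight gain
    unit: '%'
    levels:
    - 8.0
    - 11.0
    - 14.0
    center: 11.0
    scale: 3.0
  - name: x2
    label: Duration of coating
    unit: h
    levels:
    - 24.0
    - 36.0
    - 48.0
    center: 36.0
    scale: 12.0
  - name: x3
    label: Amount of plasticizer
    unit: '%'
    levels:
    - 60.0
    - 90.0
    - 120.0
    center: 90.0
    scale: 30.0
  responses:
  - label: y1
    kind: NTB
    lsl: 13.359999999999999
    usl: 20.039999999999999
    weights:
      mean: 1.0
      var: 1.0
      cv: 1.0
      cov: 1.0
    time: 2.0
    target: 16.699999999999999
  - label: y2
    kind: NTB
    lsl: 26.640000000000001
    usl: 39.960000000000001
    weights:
      mean: 1.0
      var: 1.0
      cv: 1.0
      cov: 1.0
    time: 4.0
    target: 33.299999999999997
  - label: y3
    kind: NTB
    lsl: 40.0
    usl: 60.0
    weights:
      mean: 1.0
      var: 1.0
      cv: 1.0
      cov: 1.0
    time: 6.0
    target: 50.0
  - label: y4
    kind: NTB
    lsl: 50.0
    usl: 90.0
    weights:
      mean: 1.0
      var: 1.0
      cv: 1.0
      cov: 1.0
    time: 9.0
    target: 75.0
  - label: y5
    kind: NTB
    lsl: 80.0
    usl: 120.0
    weights:
      mean: 1.0
      var: 1.0
      cv: 1.0
      cov: 1.0
    time: 12.0
    target: 100.0
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
  - 12.986000000000001
  - -2.16
  - -1.0
  - 0.68
  - 0.121
  - -0.279
  - 0.221
  - 0.038
  - 0.038
  - 0.163
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
  - 1.274
  - 0.057
  - 0.33
  - -0.235
  - -0.064
  - 0.056
  - -0.298
  - -0.002
  - 0.426
  - 0.292
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
  - 0.082
  - 0.013
  - 0.017
  - -0.015
  - -0.006
  - 0.011
  - -0.016
  - 0.002
  - 0.014
  - 0.015
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
  - 25.120999999999999
  - -5.2
  - -2.0
  - 1.43
  - 0.47
  - -0.331
  - 0.619
  - 0.163
  - 0.063
  - 0.338
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
  - 1.747
  - 0.112
  - 0.004
  - -0.564
  - -1.017
  - 1.813
  - -0.732
  - -0.442
  - 0.185
  - -0.185
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
  - 0.046
  - 0.01
  - 0.002
  - -0.011
  - -0.013
  - 0.025
  - -0.009
  - -0.004
  - 0.0004
  - -0.004
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
  - 42.938000000000002
  - -7.27
  - -2.87
  - 2.31
  - -0.257
  - -0.257
  - -0.057
  - 0.913
  - 0.463
  - -0.688
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
  - 3.412
  - 0.072
  - 0.965
  - 0.052
  - 3.869
  - -1.106
  - -1.351
  - -1.126
  - 0.936
  - -0.049
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
  - 0.042
  - 0.009
  - 0.008
  - -0.002
  - -0.023
  - -0.005
  - -0.007
  - -0.006
  - 0.004
  - 0.001
- name: mean_y4
  role: mean
  label: y4
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
  - 67.278000000000006
  - -11.369999999999999
  - -3.02
  - 3.27
  - -2.541
  - 3.709
  - -3.841
  - 0.125
  - 0.825
  - 0.05
- name: var_y4
  role: variance
  label: y4
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
  - 3.563
  - 0.311
  - -0.064
  - 0.085
  - -0.895
  - 0.32
  - 0.425
  - 0.523
  - -0.208
  - -0.09
- name: cv_y4
  role: cv
  label: y4
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
  - 0.027
  - 0.007
  - 0.002
  - -0.002
  - -0.001
  - 0.001
  - 0.003
  - 0.003
  - -0.002
  - -0.001
- name: mean_y5
  role: mean
  label: y5
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
  - 82.394999999999996
  - -12.84
  - -5.25
  - 3.8
  - -0.567
  - -0.417
  - 0.333
  - -0.675
  - 0.625
  - 0.125
- name: var_y5
  role: variance
  label: y5
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
  - 3.944
  - -0.428
  - 0.038
  - -0.142
  - 1.018
  - -1.592
  - -0.662
  - 0.705
  - -0.065
  - 0.643
- name: cv_y5
  role: cv
  label: y5
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
  - 0.024
  - 0.002
  - 0.002
  - -0.002
  - 0.004
  - -0.006
  - -0.002
  - 0.003
  - -0.001
  - 0.003
printed_optimum:
- name: x1
  coded: -0.6566
  uncoded: 9.030200000000001
  consistent: yes
- name: x2
  coded: 0.5152
  uncoded: 29.817599999999999
  consistent: no
- name: x3
  coded: 1.0
  uncoded: 120.0
  consistent: yes
notes:
- 'the published x2 optimum is internally inconsistent: coded 0.5152 decodes to 42.1824
  h under the stated coding (x2-36)/12, not the published 29.8176'
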