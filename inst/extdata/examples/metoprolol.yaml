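name: metoprolol
title: Metoprolol hydrophilic matrix (2 factors, 3 time points + t50, MDT, f2)
config:
  factors:
  - name: x1
    label: Xanthan gum
    unit: '%'
    levels:
    - 20.0
    - 30.0
    - 40.0
    center: 30.0
    scale: 10.0
  - name: x2
    label: Methocel
    unit: '%'
    levels:
    - 10.0
    - 20.0
    - 30.0
    center: 20.0
    scale: 10.0
  responses:
  - label: y1
    kind: NTB
    lsl: 15.0
    usl: 20.0
    weights:
      mean: 1.0
      var: 1.0
      cv: 1.0
      cov: 1.0
    time: 1.0
    target: 17.5
  - label: y2
    kind: NTB
    lsl: 20.0
    usl: 40.0
    weights:
      mean: 1.0
      var: 1.0
      cv: 1.0
      cov: 1.0
    time: 4.0
    target: 30.0
  - label: y3
    kind: NTB
    lsl: 60.0
    usl: 70.0
    weights:
      mean: 1.0
      var: 1.0
      cv: 1.0
      cov: 1.0
    time: 12.0
    target: 65.0
  - label: t50
    kind: NTB
    lsl: 6.0
    usl: 8.0
    weights:
      mean: 1.0
      var: 1.0
      cv: 1.0
      cov: 1.0
    target: 7.0
  - label: MDT
    kind: NTB
    lsl: 8.0
    usl: 10.0
    weights:
      mean: 1.0
      var: 1.0
      cv: 1.0
      cov: 1.0
    target: 9.0
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
  - 20.777999999999999
  - -3.317
  - -4.017
  - 0.183
  - -0.917
  - -0.325
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
  - 38.677999999999997
  - -4.5
  - -5.7
  - 1.583
  - -1.467
  - -1.425
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
  - 68.822000000000003
  - -5.483
  - -5.5
  - 2.317
  - -1.333
  - 0.15
- name: mean_t50
  role: scalar
  label: t50
  terms:
  - '1'
  - x1
  - x2
  - x1^2
  - x2^2
  coefficients:
  - 6.222
  - 1.0
  - 1.167
  - -0.333
  - 0.167
  note: published without an x1:x2 term; stored as published
- name: mean_MDT
  role: scalar
  label: MDT
  terms:
  - '1'
  - x1
  - x2
  - x1^2
  - x2^2
  - x1:x2
  coefficients:
  - 8.222
  - 0.767
  - 0.933
  - -0.333
  - 0.267
  - -0.1
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
  - 68.555999999999997
  - 11.183
  - 11.449999999999999
  - -2.483
  - -3.583
  - -1.525
printed_optimum:
- name: x1
  coded: 0.0458
  uncoded: 30.457999999999998
  consistent: yes
- name: x2
  coded: 0.6726
  uncoded: 26.725999999999999
  consistent: yes
notes: []
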