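composition:
- 0.5
- 0.5
kf:
  epsilon: 1.0
  delta: 0.2
  cos_theta_max: 0.98
  sigma: 1.0
matrix:
- - 1
  - 0
  - 0
  - 0
  - 0
  - 0
  - 0
  - 0
- - 0
  - 1
  - 0
  - 0
  - 0
  - 0
  - 0
  - 0
- - 0
  - 0
  - 0
  - 0
  - 0
  - 0
  - 1
  - 0
- - 0
  - 0
  - 0
  - 0
  - 0
  - 0
  - 0
  - 1
- - 0
  - 0
  - 0
  - 0
  - 0
  - 1
  - 0
  - 0
- - 0
  - 0
  - 0
  - 0
  - 1
  - 0
  - 0
  - 0
- - 0
  - 0
  - 1
  - 0
  - 0
  - 0
  - 0
  - 0
- - 0
  - 0
  - 0
  - 1
  - 0
  - 0
  - 0
  - 0
species:
- patch_vectors:
  - - 0.577350269189626
    - 0.577350269189626
    - 0.577350269189626
  - - 0.577350269189626
    - -0.577350269189626
    - -0.577350269189626
  - - -0.577350269189626
    - 0.577350269189626
    - -0.577350269189626
  - - -0.577350269189626
    - -0.577350269189626
    - 0.577350269189626
  patch_colors:
  - 1
  - 2
  - 3
  - 4
- patch_vectors:
  - - 0.577350269189626
    - 0.577350269189626
    - 0.577350269189626
  - - 0.577350269189626
    - -0.577350269189626
    - -0.577350269189626
  - - -0.577350269189626
    - 0.577350269189626
    - -0.577350269189626
  - - -0.577350269189626
    - -0.577350269189626
    - 0.577350269189626
  patch_colors:
  - 5
  - 6
  - 7
  - 8
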