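tps:
  astragalus_plus_centrale: astragalus_plus_centrale.tps
  astragalus_only: astragalus_only.tps
trees:
  sim: tree.nwk
reference: o1
focal_clade:
- f1
- f2
- f3
- f4
medial_subset: medial
scale_mode: mm
divisor: n-1
scheme:
  n_landmarks: 9
  n_semilandmarks: 2
  semilandmark_neighbours:
    '10':
    - 2
    - 6
    '11':
    - 6
    - 9
  subsets:
    medial:
    - 2
    - 6
    - 9
    - 10
    - 11
simulation:
  scenario: loss_expansion
  sigma: 0.1
  delta: 0.5
  noise: 0.02
  seed: 42
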