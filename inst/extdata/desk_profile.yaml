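edge_scale: 5.0
n_cycles: 4.0
use_cpd: yes
reference_bodyweight: 75.0
geometry:
  proximal_cut_depth: 8.9
  distal_cut_level: 100.0
  max_overhang: 2.0
  edge_length:
  - 2.0
  - 2.5
contact:
  friction_coefficient: 0.5
  interference_fit: 500.0
  ramp_increments: 20
  penalty_normal: 5000.0
  slip_tolerance: 0.01
gap_threshold: 0.5
threshold: 112.0
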