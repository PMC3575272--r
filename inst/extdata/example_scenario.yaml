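# Example scenario: study-mean subject, 3x4 tactor display, 60 mm backward
# platform perturbation. Omitted keys take the package defaults.
subject:
  height_m: 1.78
  mass_kg: 86
display:
  preset: 3x4
biofeedback:
  tau_f: 0.3
  k_s:             # rows 1-3; columns [ankle, hip], N m
    - [4, 0]
    - [6, 2]
    - [8, 3]
  k_c:
    - [0, 0]
    - [0, 0]
    - [0, 0]
perturbation:
  direction_deg: 180
  displacement_m: 0.060
  onset_s: 0.5
simulation:
  dt: 0.001
  horizon: 4
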