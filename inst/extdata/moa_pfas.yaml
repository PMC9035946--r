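potency:
  PFOA: 1.0
  PFOS: 1.5
calibration:
  Imax: 0.8047
  targetEffect: -39.0
  EC50: 8.0
  hill: 1.0
  achievedEffect: -38.63
  masterSeed: 20220326
  nPerArm: 50
entries:
- target: CYTOKINE_SECRETION
  species: IL6
  Imax: 0.8047
  EC50: 8.0
  hill: 1.0
- target: CYTOKINE_SECRETION
  species: TNFA
  Imax: 0.8047
  EC50: 8.0
  hill: 1.0
- target: CYTOKINE_SECRETION
  species: IL4
  Imax: 0.8047
  EC50: 8.0
  hill: 1.0
- target: CYTOKINE_SECRETION
  species: IL8
  Imax: 0.8047
  EC50: 8.0
  hill: 1.0
- target: CYTOKINE_SECRETION
  species: IL18
  Imax: 0.8047
  EC50: 8.0
  hill: 1.0
- target: CYTOKINE_SECRETION
  species: IFNG
  Imax: 0.8047
  EC50: 8.0
  hill: 1.0
- target: CYTOKINE_SECRETION
  species: IL10
  Imax: 0.8047
  EC50: 8.0
  hill: 1.0
- target: B_POOL_MU
  species: ~
  Imax: 0.8047
  EC50: 8.0
  hill: 1.0
- target: THYMIC_OUTPUT
  species: ~
  Imax: 0.8047
  EC50: 8.0
  hill: 1.0
- target: MAST_GROWTH
  species: ~
  Imax: 0.8047
  EC50: 8.0
  hill: 1.0
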