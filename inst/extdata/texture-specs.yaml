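# Default per-class texture parameterisation for the synthetic fixture
# generator. Intensities are HU-like (air ~ -1000, water 0); structural
# contributions are centred to zero mean before use, so mean_intensity is the
# expected patch mean for every class.
normal:
  mean_intensity: -870
  speckle_sd: 35
  structure: none
  structure_scale: 0
  structure_amp: 0
ggo:
  mean_intensity: -570
  speckle_sd: 55
  structure: coarse_blobs
  structure_scale: 0.15
  structure_amp: 80
consolidation:
  mean_intensity: 30
  speckle_sd: 40
  structure: none
  structure_scale: 0
  structure_amp: 0
ro:
  mean_intensity: -720
  speckle_sd: 45
  structure: fine_lines
  structure_scale: 3
  structure_amp: 330
emphysema:
  mean_intensity: -810
  speckle_sd: 40
  structure: low_attenuation_holes
  structure_scale: 0.25
  structure_amp: 180
honeycombing:
  mean_intensity: -780
  speckle_sd: 45
  structure: rings
  structure_scale: 4
  structure_amp: 550
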