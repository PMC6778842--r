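# Default reference H&E template: stain matrix and maximum concentrations
# from the public reference Macenko implementation. Vectors are renormalized
# to unit length on load.
template:
  H: [0.5626, 0.7201, 0.4062]
  E: [0.2159, 0.8012, 0.5581]
  maxCh: 1.9705
  maxCe: 1.0308
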