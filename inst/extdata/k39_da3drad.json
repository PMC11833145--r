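{
  "nucleus": "K39",
  "sequence": "DA-3D-RAD-C",
  "tr_ms": 40,
  "te_ms": 0.4,
  "flip_deg": 90,
  "nominal_resolution_mm": [8, 8, 32],
  "n_projections": 2960,
  "readout_duration_ms": 5
}
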