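{
  "nucleus": "Na23",
  "sequence": "DA-3D-RAD-C",
  "tr_ms": 120,
  "te_ms": 0.3,
  "flip_deg": 90,
  "nominal_resolution_mm": [2.5, 2.5, 15],
  "n_projections": 5384,
  "readout_duration_ms": 10
}
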