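{
  "nucleus": "H1",
  "sequence": "MESE",
  "tr_ms": 3000,
  "esp_ms": 9.5,
  "etl": 32,
  "exc_flip_deg": 90,
  "ref_flip_deg": 180
}
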