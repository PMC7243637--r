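{
  "weight_kg": 12,
  "initial_hct_pct": 35,
  "events": [
    { "kind": "blood_loss", "volume_ml": 200 },
    { "kind": "crystalloid_in", "volume_ml": 400 }
  ]
}
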