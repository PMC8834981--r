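{
  "zone": "B",
  "seed": 102,
  "pattern": "grid",
  "spacing": 100,
  "extent": [400, 400]
}
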