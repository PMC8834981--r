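{
  "zone": "A",
  "seed": 101,
  "pattern": "suburban-loops",
  "spacing": 150,
  "extent": [400, 400]
}
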