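{
  "channels": [1],
  "dwell": 1e-05,
  "mode": "sted2d",
  "power": 30,
  "scan": {
    "pixel": {"x": 0.1, "y": 0.1, "z": 1}
  }
}
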