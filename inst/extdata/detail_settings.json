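{
  "channels": [2, 3],
  "dwell": 1e-05,
  "mode": "sted2d",
  "power": 30,
  "scan": {
    "pixel": {"x": 0.05, "y": 0.05, "z": 0.5}
  }
}
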