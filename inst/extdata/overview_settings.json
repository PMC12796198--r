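{
  "channels": [1, 2, 3],
  "dwell": 1e-05,
  "mode": "confocal",
  "power": 30,
  "scan": {
    "pixel": {"x": 0.2, "y": 0.2, "z": 1},
    "range": {"x": 50, "y": 50, "z": 6}
  }
}
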