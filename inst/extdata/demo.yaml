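# Two-level overview-detail demo pipeline: confocal overviews walk an
# outward spiral; colocalizing two-channel spot pairs and whole nuclei are
# detected after every overview and imaged as higher-priority STED details.
name: overview-detail-demo
backend:
  type: sim
  seed: 7
  generate:
    density: 1.5
    extent: [160, 160]
    pair_spots: 2
levels:
  - {name: detail, rank: 1}
  - {name: overview, rank: 2}
generators:
  - name: detail-coloc
    after: overview
    target: detail
    blocks:
      - {type: settings_file, path: detail_settings.json}
      - {type: stage_inherit}
      - {type: detect_coloc, channels: [2, 3], box_size: 2,
         peak_threshold: 8, min_fov: 2}
  - name: detail-nuclei
    after: overview
    target: detail
    blocks:
      - {type: settings_file, path: nucleus_settings.json}
      - {type: stage_inherit}
      - {type: detect_nuclei, intensity_threshold: 50, min_pixels: 30,
         min_fov: 2}
  - name: next-overview
    after: overview
    target: overview
    blocks:
      - {type: settings_file, path: overview_settings.json}
      - {type: positions, mode: spiral, pitch: 45, origin: [80, 80, 3]}
stops:
  - {kind: max_images, count: 10}
  - {kind: no_objects, count: 5, level: overview}
initial:
  - {level: overview, settings: overview_settings.json, position: [35, 35, 3]}
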