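{
  "shape": [96, 48, 48],
  "resolution_mm": 0.3,
  "roots": [
    {"type": "helix", "center": [16, 16], "radiusXY": 5, "pitch": 56,
     "turns": 1.25, "phase": 0, "z0": 8, "radius": 3, "intensity": 255},
    {"type": "straight", "from": [36.5, 36.5, 10], "to": [30.5, 40.5, 80],
     "radius": 3, "intensity": 255}
  ],
  "noise": {"salt_fraction": 0.05, "gaussian_sigma": 0},
  "seed": 17
}
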