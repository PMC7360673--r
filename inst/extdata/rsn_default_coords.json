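{
  "_comment": [
    "Default resting-state-network sphere centers (MNI mm, radius mm).",
    "These are generic literature-style coordinates shipped as editable",
    "defaults only; they are NOT taken from any specific study and every",
    "analysis should read its own coordinates from configuration."
  ],
  "rois": [
    {"name": "pDMN", "radius": 15,
     "centers": [[0, -52, 26], [-46, -66, 30], [50, -62, 28]]},
    {"name": "aDMN", "radius": 15,
     "centers": [[0, 52, -6], [0, 42, 4]]},
    {"name": "DAN", "radius": 15,
     "centers": [[-24, -8, 50], [26, -6, 50], [-26, -62, 52], [28, -58, 52]]},
    {"name": "VAN", "radius": 15,
     "centers": [[54, -46, 20], [48, 22, 10]]},
    {"name": "FPN", "radius": 15,
     "centers": [[-42, 34, 20], [44, 36, 20], [-48, -48, 48], [50, -46, 48]]},
    {"name": "SMN", "radius": 15,
     "centers": [[-38, -22, 54], [40, -20, 54], [0, -10, 54]]}
  ]
}
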