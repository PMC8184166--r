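{
  "rows": 64,
  "cols": 64,
  "n_slices": 40,
  "slice_spacing": 1.0,
  "pixel_spacing": 1.0,
  "background_hu": -1024,
  "noise_sigma": 0,
  "seed": 1,
  "dataset_id": "phantom-default",
  "shapes": [
    {"center": [20.5, 32.5, 32.5], "radii": [14.0, 20.5, 20.5], "hu": 40},
    {"center": [18.5, 32.5, 22.9], "radii": [7.2, 6.4, 6.4], "hu": 700},
    {"center": [23.7, 37.6, 42.1], "radii": [4.0, 5.1, 5.1], "hu": -950}
  ]
}
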