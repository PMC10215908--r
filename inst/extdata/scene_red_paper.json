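{
  "distance_cm": 50,
  "scale_model": "pinhole_inverse_square",
  "focal_constant": 300,
  "width": 640,
  "height": 480,
  "wall_color": [40, 40, 45],
  "noise": {"sigma": 0, "gradient": 0, "cast": [1, 1, 1]},
  "seed": 1,
  "shapes": [
    {"kind": "rectangle", "w_mm": 40, "h_mm": 40, "x_mm": 0, "y_mm": 0, "color": [230, 120, 110]}
  ]
}
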