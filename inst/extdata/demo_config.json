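{
  "optics": {},
  "calibration": {
    "half_width_deg": 4,
    "half_height_deg": 4,
    "frames_per_point": 160
  },
  "light_step": {
    "dark_s": 0.3,
    "step_frames": 30,
    "step_grey": 150,
    "post_s": 0.8
  },
  "targets": [
    {"x_deg": 0, "y_deg": 0, "frames": 120},
    {"x_deg": 3, "y_deg": 2, "frames": 120},
    {"x_deg": -3, "y_deg": 2, "frames": 120},
    {"x_deg": -3, "y_deg": -2, "frames": 120},
    {"x_deg": 3, "y_deg": -2, "frames": 120}
  ],
  "epoch_s": 0.2
}
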