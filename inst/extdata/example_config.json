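{
  "geometry": {
    "parent_width": 0.004,
    "parent_length": 0.024,
    "curvature": 50,
    "sac_neck_width": 0.004,
    "dome_radius": 0.003,
    "sac_shape": "circular_segment",
    "sac_center_arc": 0.012,
    "coil_fill_fraction": 0.85
  },
  "rheology": { "model": "casson", "gamma_min": 0.001 },
  "waveform": { "period": 0.8, "mean_velocity": 0.3 },
  "coil": { "porosity": [0.79, 0.89], "wire_diameter": 0.00025 },
  "hct": [0.35, 0.45],
  "solver": { "cycles_to_run": 2, "cycles_to_discard": 1 },
  "resolution": 0.0004,
  "grid_ladder": [0.0005, 0.00035, 0.00025],
  "osi_threshold": 0.2,
  "iso_velocity_level": 0.4
}
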