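{
  "schema_version": 1,
  "comment": "Default model configuration. Units: mm, s, kg (force = kg*mm/s^2). Body spring/damping magnitudes and Hill-curve parameters are a synthetic calibration reproducing the structure of the prior rod-and-spring body model; see the package vignette.",
  "ranges": {
    "bias": [
      -15.0,
      15.0
    ],
    "tau": [
      0.05,
      2.0
    ],
    "w_self": [
      -15.0,
      15.0
    ],
    "nmj": [
      0.0,
      15.0
    ],
    "chem": [
      -15.0,
      15.0
    ],
    "gap": [
      0.0,
      2.5
    ],
    "gain_F": [
      0.0,
      1.0
    ]
  },
  "simulation": {
    "dt_neural": 0.0005,
    "dt_body": 0.0001,
    "duration": 50.0,
    "transient": 10.0,
    "record_stride": 10
  },
  "fitness": {
    "amp_threshold": 0.5,
    "freq_target": 0.44,
    "vel_target": 0.22
  },
  "ga": {
    "pop_size": 96,
    "generations": 300,
    "mutation_sigma": 0.12,
    "recomb_prob": 0.5,
    "elitism": 1,
    "stage1_threshold": 0.99,
    "stage1_eval_duration": 24.0,
    "stage1_eval_transient": 8.0,
    "stage2_eval_duration": 12.0,
    "stage2_eval_transient": 4.0,
    "stage1_amp_margin": 1.1,
    "mutation_sigma_min": 0.01
  },
  "body": {
    "n_seg": 50,
    "length": 1.0,
    "half_width_max": 0.04,
    "width_shape": 1.04,
    "k_lateral": 20.0,
    "c_lateral": 0.02,
    "k_diagonal": 20.0,
    "c_diagonal": 0.02,
    "drag_par": 0.0032,
    "drag_perp": 0.128
  },
  "muscle": {
    "n_per_side": 24,
    "tau_m": 0.1,
    "f_max": 0.03,
    "fl_width": 0.5,
    "fv_vmax": 4.0,
    "fv_hill": 2.0,
    "fv_cap": 1.5,
    "span_segments": 4,
    "gamma0": 0.7
  }
}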