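{
  "latency_ms": 100,
  "burst_window_ms": [100, 300],
  "trace_end_ms": 500,
  "f0": 60,
  "burst_amp": 200,
  "phase_jitter_sd": 0.15,
  "burst_noise_rel": 0.5,
  "amp_noise_cv": 0.1,
  "background_sd": 10,
  "late_irregular_gain": 0.4,
  "artifact_amp": 2000,
  "fs_raw": 100000,
  "pre_stim_ms": 100,
  "provenance": {
    "target_apen": 0.49,
    "achieved_apen": 0.488188297359375,
    "n_reps": 160,
    "calibration_seed": 20100713
  }
}
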