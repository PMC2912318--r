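# Shared fixtures, all built in code at test time.

make_sine <- function(freq, fs = 2000, n = 200, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * (seq_len(n) - 1L) / fs + phase)
}

# a small, fast parameter set for structure/property tests (20 kHz keeps the
# 2 kHz decimation factor integral at 10)
fast_params <- function(...) {
  synth_params(fs_raw = 20000, ...)
}

fast_cohort_spec <- function(n_slices = 3L, base_seed = 11L) {
  pc <- lapply(CONDITIONS, function(cond) fast_params())
  names(pc) <- CONDITIONS
  cohort_spec(n_slices = n_slices, base_seed = base_seed,
              per_condition_params = pc)
}

# full pipeline ApEn of one generated trace
pipeline_apen_one <- function(params, seed, cfg = pipeline_config()) {
  rec <- generate_recording(params, "control", "fix", seed = seed)
  pp <- preprocess(rec, cfg)
  seg <- isolate_gamma_segment(pp$recording, cfg$gamma_window_ms)
  approximate_entropy(seg, apen_params(m = cfg$apen_m,
                                       r_coeff = cfg$apen_r_coeff))$apen
}

# gamma-band (30-120 Hz) RMS ratio of [0,100) vs [150,250) ms post-stimulus,
# on the artifact-blanked, decimated trace: the "latency" property
latency_rms_ratio <- function(rec, target_fs = 2000) {
  bl <- remove_stimulus_artifact(rec)
  g <- bandpass_filter(resample_signal(bl, target_fs), 30, 120)
  t_ms <- (seq_along(g$samples) - 1L) / g$fs * 1000 - g$stim_time_ms
  rms <- function(w) sqrt(mean(g$samples[t_ms >= w[1] & t_ms < w[2]]^2))
  rms(c(0, 100)) / rms(c(150, 250))
}

random_recording <- function(seed) {
  set.seed(seed)
  n <- sample(50:400, 1)
  fs <- sample(c(500, 1000, 2000), 1)
  recording(stats::rnorm(n), fs = fs,
            stim_time_ms = stats::runif(1, 0, n / fs * 500),
            condition = sample(CONDITIONS, 1),
            slice_id = sprintf("r%d", seed),
            meta = list(tag = "roundtrip"))
}
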