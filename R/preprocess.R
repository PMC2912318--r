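# Preprocessing chain: stimulus-artifact blanking -> anti-aliased decimation
# to 2 kHz -> piecewise linear detrend -> 30-300 Hz zero-phase band-pass.
#
# Filtering note: no IIR filter-design library ships with this environment,
# so zero-phase filtering is implemented directly in the frequency domain by
# multiplying the spectrum with the *squared* Butterworth magnitude response
# |H(f)|^2 — the exact amplitude response of forward-backward (filtfilt)
# application of the analog prototype, with identically zero phase. Reflection
# padding suppresses the circular-convolution edge transient.

# Odd-reflection pad, apply a real nonnegative gain curve in the frequency
# domain, unpad. `gain` is a function of frequency (Hz) returning the
# amplitude multiplier (already squared for filtfilt equivalence).
fft_zero_phase <- function(x, fs, gain) {
  fs <- as.numeric(fs)
  n <- length(x)
  pad <- min(n - 1L, as.integer(round(0.2 * fs)))  # 200 ms each side
  if (pad > 0L) {
    left <- 2 * x[1L] - x[seq(pad + 1L, 2L)]
    right <- 2 * x[n] - x[seq(n - 1L, n - pad)]
    xp <- c(left, x, right)
  } else {
    xp <- x
  }
  np <- length(xp)
  k <- c(0L, seq_len(np - 1L))
  k <- pmin(k, np - k)
  f <- as.numeric(k) * fs / np
  g <- gain(f)
  y <- Re(stats::fft(stats::fft(xp) * g, inverse = TRUE)) / np
  if (pad > 0L) y[(pad + 1L):(pad + n)] else y
}

# Squared magnitude (filtfilt amplitude) of an order-n analog Butterworth
# band-pass with corner frequencies (lo, hi) Hz.
butter_bandpass_gain <- function(lo, hi, order = 4L) {
  force(lo); force(hi); force(order)
  function(f) {
    W <- ifelse(f > 0, (f^2 - lo * hi) / ((hi - lo) * f), Inf)
    ifelse(is.finite(W), 1 / (1 + W^(2 * order)), 0)
  }
}

# Squared magnitude of an order-n analog Butterworth low-pass, cutoff fc Hz.
butter_lowpass_gain <- function(fc, order = 16L) {
  force(fc); force(order)
  function(f) 1 / (1 + (f / fc)^(2 * order))
}

#' Blank the stimulation artifact by linear interpolation
#'
#' Samples inside `[stim - pre, stim + post)` ms are replaced by the straight
#' line joining the boundary samples; everything else is untouched and the
#' time base is preserved (no samples are deleted).
#'
#' @param rec an `lfp_recording`.
#' @param blank_ms `c(pre, post)` extent of the blanked window, ms.
#' @return an `lfp_recording` of identical length.
#' @export
remove_stimulus_artifact <- function(rec, blank_ms = c(2, 10)) {
  stopifnot(inherits(rec, "lfp_recording"))
  pre <- blank_ms[1]; post <- blank_ms[2]
  if (pre < 0 || post <= 0) stop("blank_ms must be c(pre >= 0, post > 0)", call. = FALSE)
  n <- length(rec$samples)
  t0 <- rec$stim_time_ms - pre
  t1 <- rec$stim_time_ms + post
  i0 <- as.integer(floor(t0 / 1000 * rec$fs)) + 1L   # last sample before window
  i1 <- as.integer(ceiling(t1 / 1000 * rec$fs)) + 1L # first sample at/after end
  if (i0 < 1L || i1 > n) {
    stop(sprintf(
      "blanking window [%s, %s) ms extends past the trace (0 to %s ms)",
      fmt_num(t0), fmt_num(t1), fmt_num(duration_ms(rec))), call. = FALSE)
  }
  x <- rec$samples
  inside <- seq(i0 + 1L, i1 - 1L)
  if (length(inside) > 0L && i1 > i0 + 1L) {
    x[inside] <- x[i0] + (x[i1] - x[i0]) * (inside - i0) / (i1 - i0)
  }
  out <- rec
  out$samples <- x
  out
}

#' Decimate to a lower sampling rate with zero-phase anti-aliasing
#'
#' Applies a zero-phase low-pass at 0.8 x the target Nyquist frequency and
#' keeps every `fs/target_fs`-th sample (the factor must be an integer).
#' `stim_time_ms` is preserved; the retained sample times are a subset of the
#' original ones.
#'
#' @param rec an `lfp_recording`.
#' @param target_fs output sampling rate, Hz.
#' @return an `lfp_recording` at `target_fs`.
#' @export
resample_signal <- function(rec, target_fs) {
  stopifnot(inherits(rec, "lfp_recording"))
  factor <- rec$fs / target_fs
  if (abs(factor - round(factor)) > 1e-9 || factor < 1) {
    stop(sprintf(
      "fs (%s Hz) must be an integer multiple of target_fs (%s Hz); factor %s is not integral",
      fmt_num(rec$fs), fmt_num(target_fs), fmt_num(factor)), call. = FALSE)
  }
  factor <- as.integer(round(factor))
  out <- rec
  if (factor > 1L) {
    fc <- 0.8 * target_fs / 2
    y <- fft_zero_phase(rec$samples, rec$fs, butter_lowpass_gain(fc))
    out$samples <- y[seq(1L, length(y), by = factor)]
    out$fs <- as.numeric(target_fs)
  }
  out
}

#' Piecewise linear detrend
#'
#' The trace is split into contiguous pieces of `knot_spacing_ms` (a short
#' final remainder is merged into the preceding piece) and the least-squares
#' line of each piece is subtracted, leaving every piece with zero mean and
#' zero slope.
#'
#' @param rec an `lfp_recording`.
#' @param knot_spacing_ms piece length, ms.
#' @return an `lfp_recording`; `meta$detrend_knots_ms` records piece starts.
#' @export
piecewise_detrend <- function(rec, knot_spacing_ms = 100) {
  stopifnot(inherits(rec, "lfp_recording"))
  n <- length(rec$samples)
  piece_n <- as.integer(round(knot_spacing_ms / 1000 * rec$fs))
  if (piece_n < 2L) {
    stop("knot spacing must cover at least 2 samples", call. = FALSE)
  }
  starts <- seq(1L, n, by = piece_n)
  # fold a trailing fragment of < 2 samples into the previous piece
  if (length(starts) > 1L && n - starts[length(starts)] + 1L < 2L) {
    starts <- starts[-length(starts)]
  }
  x <- rec$samples
  for (s in starts) {
    e <- min(s + piece_n - 1L, n)
    if (s == starts[length(starts)]) e <- n
    idx <- s:e
    tt <- seq_along(idx) - mean(seq_along(idx))
    b <- sum(tt * x[idx]) / sum(tt^2)
    x[idx] <- x[idx] - mean(x[idx]) - b * tt
  }
  out <- rec
  out$samples <- x
  out$meta$detrend_knots_ms <- (starts - 1L) / rec$fs * 1000
  out
}

#' Zero-phase Butterworth band-pass
#'
#' Order-4 Butterworth band-pass applied forward-backward (amplitude response
#' `|H|^2`, phase exactly zero), realized in the frequency domain with
#' reflection padding. Length is unchanged.
#'
#' @param rec an `lfp_recording`.
#' @param low,high corner frequencies, Hz; `0 < low < high < fs/2`.
#' @return an `lfp_recording`.
#' @export
bandpass_filter <- function(rec, low = 30, high = 300) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (low <= 0 || low >= high) stop("need 0 < low < high", call. = FALSE)
  if (high >= rec$fs / 2) {
    stop(sprintf("high corner %s Hz must lie below Nyquist (%s Hz)",
                 fmt_num(high), fmt_num(rec$fs / 2)), call. = FALSE)
  }
  out <- rec
  out$samples <- fft_zero_phase(rec$samples, rec$fs,
                                butter_bandpass_gain(low, high, order = 4L))
  out
}

#' Run the full preprocessing chain
#'
#' Artifact blanking, resampling, piecewise detrending and band-pass
#' filtering, in that fixed order, returning the processed recording together
#' with a provenance report.
#'
#' @param rec an `lfp_recording`.
#' @param cfg an `lfp_config` (see [pipeline_config()]).
#' @return a list with elements `recording` (processed `lfp_recording`) and
#'   `report` (an `lfp_preprocess_report`).
#' @export
preprocess <- function(rec, cfg = pipeline_config()) {
  stopifnot(inherits(rec, "lfp_recording"), inherits(cfg, "lfp_config"))
  r1 <- remove_stimulus_artifact(rec, cfg$artifact_blank_ms)
  r2 <- resample_signal(r1, cfg$target_fs)
  r3 <- piecewise_detrend(r2, cfg$detrend_breakpoint_ms)
  r4 <- bandpass_filter(r3, cfg$band[1], cfg$band[2])
  report <- structure(
    list(
      blanked_interval_ms = c(rec$stim_time_ms - cfg$artifact_blank_ms[1],
                              rec$stim_time_ms + cfg$artifact_blank_ms[2]),
      decimation_factor = as.integer(round(rec$fs / cfg$target_fs)),
      detrend_knots_ms = r3$meta$detrend_knots_ms,
      filter_description = sprintf(
        paste0("zero-phase (forward-backward) order-4 Butterworth band-pass, ",
               "corners %g and %g Hz; anti-alias: zero-phase order-16 ",
               "Butterworth low-pass at %g Hz before decimation"),
        cfg$band[1], cfg$band[2], 0.8 * cfg$target_fs / 2)
    ),
    class = "lfp_preprocess_report"
  )
  list(recording = r4, report = report)
}

#' @export
print.lfp_preprocess_report <- function(x, ...) {
  cat("<lfp_preprocess_report>\n")
  cat(sprintf("  blanked: [%.1f, %.1f) ms\n",
              x$blanked_interval_ms[1], x$blanked_interval_ms[2]))
  cat(sprintf("  decimation factor: %d\n", x$decimation_factor))
  cat(sprintf("  detrend pieces start at: %s ms\n",
              paste(round(x$detrend_knots_ms), collapse = ", ")))
  cat(sprintf("  filter: %s\n", x$filter_description))
  invisible(x)
}
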