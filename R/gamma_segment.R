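# Gamma-segment isolation and spectral verification.
#
# The published analysis isolated the oscillation "by visual inspection" with
# the power spectrum as a reference; here the fixed 150-250 ms post-stimulus
# window replaces the eye, and is_gamma_dominant() replaces the reference
# glance with an explicit peak-ratio criterion.

#' Extract the post-stimulus gamma window
#'
#' Cuts the half-open window `[stim + t0, stim + t1)` ms out of a recording.
#' For integer-commensurate windows the sample count is exact:
#' `round((t1 - t0)/1000 * fs)`.
#'
#' @param rec an `lfp_recording`.
#' @param window_ms `c(t0, t1)` ms relative to stimulus onset.
#' @return an `lfp_segment`.
#' @export
isolate_gamma_segment <- function(rec, window_ms = c(150, 250)) {
  stopifnot(inherits(rec, "lfp_recording"))
  t0 <- window_ms[1]; t1 <- window_ms[2]
  if (t1 <= t0 || t0 < 0) stop("window_ms must satisfy t1 > t0 >= 0", call. = FALSE)
  n <- length(rec$samples)
  start0 <- as.integer(round((rec$stim_time_ms + t0) / 1000 * rec$fs))  # 0-based
  len <- as.integer(round((t1 - t0) / 1000 * rec$fs))
  avail_ms <- duration_ms(rec) - rec$stim_time_ms
  if (start0 + len > n) {
    stop(sprintf(
      "trace too short: window needs %s ms post-stimulus but only %s ms available",
      fmt_num(t1), fmt_num(avail_ms)), call. = FALSE)
  }
  segment(rec$samples[(start0 + 1L):(start0 + len)], fs = rec$fs,
          window_ms = c(t0, t1), slice_id = rec$slice_id,
          condition = rec$condition)
}

#' Hann-windowed periodogram on a 1 Hz grid
#'
#' Mean-removed, Hann-windowed periodogram of a segment, zero-padded so the
#' frequency grid step is (at most) 1 Hz. Power is normalized so that
#' `sum(power) * df` equals the variance of the windowed signal (window
#' energy-normalized), i.e. Parseval holds.
#'
#' @param seg an `lfp_segment` (>= 64 samples).
#' @return an object of class `lfp_spectrum` with fields `freqs` (Hz),
#'   `power` (uV^2/Hz) and `method`.
#' @export
power_spectrum <- function(seg) {
  stopifnot(inherits(seg, "lfp_segment"))
  x <- seg$samples
  n <- length(x)
  if (n < 64L) stop("segment too short for a spectrum (need >= 64 samples)", call. = FALSE)
  x <- x - mean(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))  # Hann
  xw <- x * w
  nfft <- max(n, as.integer(round(seg$fs)))  # df = fs/nfft <= 1 Hz
  X <- stats::fft(c(xw, numeric(nfft - n)))
  half <- floor(nfft / 2) + 1L
  p <- Mod(X[seq_len(half)])^2 / (seg$fs * sum(w^2))
  # one-sided: double everything except DC (and Nyquist when nfft even)
  dbl <- rep(2, half); dbl[1L] <- 1
  if (nfft %% 2L == 0L) dbl[half] <- 1
  p <- p * dbl
  structure(
    list(freqs = (seq_len(half) - 1L) * seg$fs / nfft,
         power = p,
         method = sprintf("Hann periodogram, mean-removed, zero-padded %d -> %d (df = %g Hz)",
                          n, nfft, seg$fs / nfft)),
    class = "lfp_spectrum"
  )
}

#' Peak frequency within a search band
#'
#' Frequency of maximum power within `[lo, hi]` Hz; exact ties break toward
#' the lower frequency (which.max on the increasing grid).
#'
#' @param ps an `lfp_spectrum`.
#' @param search_band `c(lo, hi)` Hz.
#' @return peak frequency, Hz.
#' @export
dominant_frequency <- function(ps, search_band = c(30, 120)) {
  stopifnot(inherits(ps, "lfp_spectrum"))
  sel <- ps$freqs >= search_band[1] & ps$freqs <= search_band[2]
  if (!any(sel)) {
    stop(sprintf("search band [%g, %g] Hz contains no spectral bins",
                 search_band[1], search_band[2]), call. = FALSE)
  }
  f <- ps$freqs[sel]; p <- ps$power[sel]
  f[which.max(p)]
}

#' Is the spectrum gamma-dominated?
#'
#' TRUE iff the peak power inside the gamma band is at least `margin` times
#' the peak power outside it, both restricted to the analyzed extent
#' (the band-pass range, 30-300 Hz by default).
#'
#' @param ps an `lfp_spectrum`.
#' @param gamma_band `c(lo, hi)` Hz; default the widest published gamma range.
#' @param margin peak-ratio threshold.
#' @param extent `c(lo, hi)` Hz analyzed extent.
#' @return a list: `dominant` (logical), `peak_in`, `peak_out`, `ratio`,
#'   `diagnostic` (character).
#' @export
is_gamma_dominant <- function(ps, gamma_band = c(30, 120), margin = 2,
                              extent = c(30, 300)) {
  stopifnot(inherits(ps, "lfp_spectrum"))
  in_band <- ps$freqs >= gamma_band[1] & ps$freqs <= gamma_band[2] &
    ps$freqs >= extent[1] & ps$freqs <= extent[2]
  out_band <- (ps$freqs < gamma_band[1] | ps$freqs > gamma_band[2]) &
    ps$freqs >= extent[1] & ps$freqs <= extent[2]
  peak_in <- if (any(in_band)) max(ps$power[in_band]) else 0
  peak_out <- if (any(out_band)) max(ps$power[out_band]) else 0
  if (peak_in <= 0 && peak_out <= 0) {
    return(list(dominant = FALSE, peak_in = peak_in, peak_out = peak_out,
                ratio = NA_real_, diagnostic = "no power in analyzed extent"))
  }
  ratio <- if (peak_out > 0) peak_in / peak_out else Inf
  list(dominant = ratio >= margin, peak_in = peak_in, peak_out = peak_out,
       ratio = ratio, diagnostic = "ok")
}
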