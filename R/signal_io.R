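# Domain types (Recording, Segment, PipelineConfig) and on-disk formats.
#
# Native format: two-column delimited text ("time_ms,voltage_uV") plus a flat
# JSON sidecar carrying fs, stim_time_ms, condition, slice_id. Milliseconds
# throughout, 0 = trace start; analysis windows are half-open [t0, t1) and
# relative to stimulus onset.

#' Experimental condition labels
#'
#' The three within-slice recording conditions, in canonical order.
#' @export
CONDITIONS <- c("control", "nicotine", "washout")

#' Construct a field-potential recording
#'
#' A `Recording` is the whole-trace container shared across the pipeline:
#' a single-electrode voltage trace with its sampling rate, stimulus-onset
#' time, condition label and slice identity.
#'
#' @param samples numeric vector of voltages (uV), trace order.
#' @param fs sampling rate in Hz (> 0).
#' @param stim_time_ms stimulus onset relative to trace start, ms;
#'   must lie in `[0, duration)`.
#' @param condition one of `"control"`, `"nicotine"`, `"washout"`.
#' @param slice_id opaque identifier of the source slice.
#' @param meta free-form list of annotations.
#' @return an object of class `lfp_recording`.
#' @export
recording <- function(samples, fs, stim_time_ms, condition, slice_id,
                      meta = list()) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    stop("a Recording must contain at least one sample", call. = FALSE)
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("Recording samples contain missing or non-finite values",
         call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a single positive number (Hz)", call. = FALSE)
  }
  dur <- length(samples) / fs * 1000
  if (!is.numeric(stim_time_ms) || stim_time_ms < 0 || stim_time_ms >= dur) {
    stop(sprintf("stim_time_ms must lie in [0, %s) ms", fmt_num(dur)),
         call. = FALSE)
  }
  condition <- as.character(condition)
  if (length(condition) != 1L || !condition %in% CONDITIONS) {
    stop(sprintf("condition must be one of: %s (got %s)",
                 paste(CONDITIONS, collapse = ", "),
                 deparse(condition)), call. = FALSE)
  }
  structure(
    list(samples = samples, fs = as.numeric(fs),
         stim_time_ms = as.numeric(stim_time_ms),
         condition = condition, slice_id = as.character(slice_id),
         meta = meta),
    class = "lfp_recording"
  )
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf(
    "<lfp_recording> slice %s / %s: %d samples @ %g Hz (%.1f ms), stim at %.1f ms\n",
    x$slice_id, x$condition, length(x$samples), x$fs,
    duration_ms(x), x$stim_time_ms))
  invisible(x)
}

#' Trace duration in milliseconds
#' @param rec an `lfp_recording`.
#' @export
duration_ms <- function(rec) {
  length(rec$samples) / rec$fs * 1000
}

#' Construct a post-stimulus segment
#'
#' A `Segment` is a windowed excerpt of a Recording tied to a half-open
#' post-stimulus window `[t0, t1)` in ms. Its length is pinned to
#' `round((t1 - t0)/1000 * fs)` samples.
#'
#' @param samples numeric voltages (uV).
#' @param fs sampling rate, Hz.
#' @param window_ms numeric length-2, `c(t0, t1)` ms relative to stimulus.
#' @param slice_id,condition provenance of the parent Recording.
#' @return an object of class `lfp_segment`.
#' @export
segment <- function(samples, fs, window_ms, slice_id = NA_character_,
                    condition = NA_character_) {
  samples <- as.numeric(samples)
  if (length(window_ms) != 2L || window_ms[2] <= window_ms[1] || window_ms[1] < 0) {
    stop("window_ms must be c(t0, t1) with t1 > t0 >= 0", call. = FALSE)
  }
  expected <- as.integer(round(diff(window_ms) / 1000 * fs))
  if (length(samples) != expected) {
    stop(sprintf("segment length %d does not match window: expected %d samples",
                 length(samples), expected), call. = FALSE)
  }
  structure(
    list(samples = samples, fs = as.numeric(fs),
         window_ms = as.numeric(window_ms),
         slice_id = as.character(slice_id),
         condition = as.character(condition)),
    class = "lfp_segment"
  )
}

#' @export
print.lfp_segment <- function(x, ...) {
  cat(sprintf(
    "<lfp_segment> [%g, %g) ms post-stimulus, %d samples @ %g Hz (%s/%s)\n",
    x$window_ms[1], x$window_ms[2], length(x$samples), x$fs,
    x$slice_id, x$condition))
  invisible(x)
}

#' Pipeline configuration
#'
#' Holds every tunable of the analysis chain. Defaults are the published
#' analysis settings: resample to 2 kHz, band-pass 30-300 Hz, gamma window
#' 150-250 ms post-stimulus, ApEn with m = 2 and r = 0.1 x SD.
#'
#' @param target_fs resampling rate, Hz.
#' @param band band-pass corners `c(low, high)`, Hz.
#' @param gamma_window_ms analysis window `c(t0, t1)` ms post-stimulus.
#' @param artifact_blank_ms blanking extent `c(pre, post)` ms around stimulus.
#' @param detrend_breakpoint_ms spacing of piecewise-linear detrend pieces, ms.
#' @param apen_m ApEn embedding dimension.
#' @param apen_r_coeff ApEn tolerance as a multiple of the segment SD.
#' @param seed optional integer seed for simulation-mode pipelines.
#' @return an object of class `lfp_config`.
#' @export
pipeline_config <- function(target_fs = 2000,
                            band = c(30, 300),
                            gamma_window_ms = c(150, 250),
                            artifact_blank_ms = c(2, 10),
                            detrend_breakpoint_ms = 100,
                            apen_m = 2L,
                            apen_r_coeff = 0.1,
                            seed = NULL) {
  if (target_fs <= 0) stop("target_fs must be positive", call. = FALSE)
  band <- as.numeric(band)
  if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2]) {
    stop("band must be c(low, high) with 0 < low < high", call. = FALSE)
  }
  gamma_window_ms <- as.numeric(gamma_window_ms)
  if (length(gamma_window_ms) != 2L || gamma_window_ms[1] < 0 ||
      gamma_window_ms[2] <= gamma_window_ms[1]) {
    stop("gamma_window_ms must be c(t0, t1) with t1 > t0 >= 0", call. = FALSE)
  }
  if (detrend_breakpoint_ms <= 0) {
    stop("detrend_breakpoint_ms must be positive", call. = FALSE)
  }
  if (apen_m < 1) stop("apen_m must be >= 1", call. = FALSE)
  if (apen_r_coeff < 0) stop("apen_r_coeff must be >= 0", call. = FALSE)
  structure(
    list(target_fs = as.numeric(target_fs), band = band,
         gamma_window_ms = gamma_window_ms,
         artifact_blank_ms = as.numeric(artifact_blank_ms),
         detrend_breakpoint_ms = as.numeric(detrend_breakpoint_ms),
         apen_m = as.integer(apen_m), apen_r_coeff = as.numeric(apen_r_coeff),
         seed = seed),
    class = "lfp_config"
  )
}

#' Read a pipeline configuration from flat JSON
#'
#' Absent keys take the defaults of [pipeline_config()]; unknown keys are an
#' error so typos cannot silently fall back to defaults.
#'
#' @param path path to a flat JSON file.
#' @return an `lfp_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (length(raw) == 0L) raw <- list()
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0L) {
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

#' Read a recording from the native delimited-text + JSON pair
#'
#' The data file must have header `time_ms,voltage_uV` and one sample per
#' row; the sidecar is flat JSON with keys `fs`, `stim_time_ms`, `condition`,
#' `slice_id`. The declared `fs` is cross-checked against the median time
#' step of the data file to within 1 %.
#'
#' @param path_data path to the delimited data file.
#' @param path_meta path to the JSON sidecar.
#' @return an `lfp_recording`.
#' @export
read_recording <- function(path_data, path_meta) {
  dt <- data.table::fread(path_data, header = TRUE)
  if (!all(c("time_ms", "voltage_uV") %in% names(dt))) {
    stop("data file must have columns time_ms and voltage_uV", call. = FALSE)
  }
  v <- dt[["voltage_uV"]]
  t_ms <- dt[["time_ms"]]
  if (length(v) == 0L) stop("data file contains no samples", call. = FALSE)
  if (anyNA(v) || any(!is.finite(v))) {
    stop("data file contains missing or non-finite voltages", call. = FALSE)
  }
  meta <- jsonlite::fromJSON(path_meta, simplifyVector = TRUE)
  need <- c("fs", "stim_time_ms", "condition", "slice_id")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0L) {
    stop(sprintf("meta file missing key(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  fs <- as.numeric(meta$fs)
  if (length(v) > 1L) {
    implied_fs <- 1000 / stats::median(diff(t_ms))
    if (abs(implied_fs - fs) / fs > 0.01) {
      stop(sprintf(
        "sampling-rate mismatch: declared fs = %s Hz but time steps imply %s Hz",
        fmt_num(fs), fmt_num(implied_fs)), call. = FALSE)
    }
  }
  extra <- meta[setdiff(names(meta), need)]
  recording(v, fs = fs, stim_time_ms = as.numeric(meta$stim_time_ms),
            condition = meta$condition, slice_id = meta$slice_id,
            meta = as.list(extra))
}

#' Write a recording as a delimited-text + JSON pair
#'
#' Inverse of [read_recording()]: a round trip reproduces the samples to
#' better than 1e-6 uV and all metadata exactly.
#'
#' @param rec an `lfp_recording`.
#' @param path_data,path_meta output paths.
#' @return invisibly, `c(path_data, path_meta)`.
#' @export
write_recording <- function(rec, path_data, path_meta) {
  stopifnot(inherits(rec, "lfp_recording"))
  n <- length(rec$samples)
  dt <- data.table::data.table(
    time_ms = (seq_len(n) - 1L) / rec$fs * 1000,
    voltage_uV = rec$samples
  )
  data.table::fwrite(dt, path_data)
  meta <- c(list(fs = rec$fs, stim_time_ms = rec$stim_time_ms,
                 condition = rec$condition, slice_id = rec$slice_id),
            rec$meta[setdiff(names(rec$meta),
                             c("fs", "stim_time_ms", "condition", "slice_id"))])
  # digits = I(17): shortest-exact would be ideal, but 17 significant digits
  # guarantee a bit-exact double round trip
  jsonlite::write_json(meta, path_meta, auto_unbox = TRUE, digits = I(17))
  invisible(c(path_data, path_meta))
}
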