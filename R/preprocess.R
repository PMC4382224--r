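#' Band-pass filter specification
#'
#' @param band `(lo, hi)` Hz passband edges.
#' @param order filter order (per direction); default 4th-order
#'   Butterworth, the de-facto convention for sensorimotor-rhythm work.
#' @param family filter family; only `"butter"` is implemented.
#' @param zero_phase if `TRUE` (default) the filter is applied forward and
#'   backward so band power changes are not delayed in time.
#' @return an object of class `mibci_filter_spec`.
#' @export
filter_spec <- function(band, order = 4, family = "butter",
                        zero_phase = TRUE) {
  if (length(band) != 2 || band[1] <= 0 || band[1] >= band[2])
    stop_mibci("config_error", "band must satisfy 0 < lo < hi")
  if (family != "butter")
    stop_mibci("config_error", "unsupported filter family '%s'", family)
  structure(list(band = as.numeric(band), order = order, family = family,
                 zero_phase = zero_phase),
            class = "mibci_filter_spec")
}

# filter a channels x time matrix; band validated against fs here
bandpass_matrix <- function(x, fs, spec) {
  if (spec$band[2] >= fs / 2)
    stop_mibci("config_error",
               "band [%g, %g] Hz exceeds the Nyquist frequency %g Hz",
               spec$band[1], spec$band[2], fs / 2)
  bf <- signal::butter(spec$order, spec$band / (fs / 2), type = "pass")
  out <- x
  for (i in seq_len(nrow(x))) {
    out[i, ] <- if (spec$zero_phase) signal::filtfilt(bf, x[i, ])
                else as.numeric(signal::filter(bf, x[i, ]))
  }
  out
}

#' Band-pass filter a recording
#'
#' Zero-phase (forward-backward) Butterworth filtering of every channel;
#' shape, events, and sampling rate are preserved.
#'
#' @param rec a `mibci_recording`.
#' @param spec a [filter_spec()], or a numeric `(lo, hi)` band which is
#'   promoted to the default 4th-order zero-phase Butterworth spec.
#' @return the filtered `mibci_recording`.
#' @export
bandpass <- function(rec, spec) {
  if (is.numeric(spec)) spec <- filter_spec(spec)
  bci_log("bandpass %g-%g Hz (order %d, zero_phase=%s)", spec$band[1],
          spec$band[2], spec$order, spec$zero_phase)
  recording(bandpass_matrix(rec$samples, rec$fs, spec), rec$fs,
            rec$montage, rec$events)
}

#' Downsample a recording by an integer factor
#'
#' Applies an 8th-order zero-phase Butterworth anti-alias low-pass at
#' `0.4 * target_fs` and keeps every `fs/target_fs`-th sample. Event
#' onsets are in seconds and are unchanged.
#'
#' @param rec a `mibci_recording`.
#' @param target_fs target sampling rate; `rec$fs` must be an integer
#'   multiple of it.
#' @return a `mibci_recording` at `target_fs` with
#'   `ceiling(n * target_fs / fs)` samples.
#' @export
downsample <- function(rec, target_fs) {
  q <- rec$fs / target_fs
  if (abs(q - round(q)) > 1e-9)
    stop_mibci("unsupported_ratio_error",
               "fs = %g is not an integer multiple of target_fs = %g",
               rec$fs, target_fs)
  q <- round(q)
  if (q == 1) return(rec)
  bf <- signal::butter(8, 0.4 * target_fs / (rec$fs / 2), type = "low")
  x <- rec$samples
  keep <- seq(1, ncol(x), by = q)
  out <- matrix(0, nrow(x), length(keep))
  for (i in seq_len(nrow(x)))
    out[i, ] <- signal::filtfilt(bf, x[i, ])[keep]
  bci_log("downsampled %g -> %g Hz (factor %d)", rec$fs, target_fs, q)
  recording(out, target_fs, rec$montage, rec$events)
}

#' Cut cue-locked epochs from a recording
#'
#' One epoch per event, over the half-open sample window
#' `[floor((onset+start)*fs), floor((onset+start)*fs) + round((end-start)*fs))`
#' (0-based sample indices), with labels copied from the event table.
#'
#' @param rec a `mibci_recording`.
#' @param window numeric `(start_s, end_s)` relative to cue onset.
#' @return a `mibci_epochs` with one trial per event.
#' @export
epoch <- function(rec, window) {
  if (window[2] <= window[1])
    stop_mibci("validation_error", "epoch window end must exceed start")
  n_len <- round((window[2] - window[1]) * rec$fs)
  n_tot <- ncol(rec$samples)
  ev <- rec$events
  dat <- array(0, c(nrow(ev), nrow(rec$samples), n_len))
  for (i in seq_len(nrow(ev))) {
    i0 <- floor((ev$onset_s[i] + window[1]) * rec$fs) # 0-based
    if (i0 < 0 || i0 + n_len > n_tot)
      stop_mibci("boundary_error",
                 "epoch window for event %d (%s at %.2f s) leaves the recording",
                 i, ev$label[i], ev$onset_s[i])
    dat[i, , ] <- rec$samples[, (i0 + 1):(i0 + n_len)]
  }
  epoch_set(dat, ev$label, rec$fs, window, rec$montage)
}

#' Standard preprocessing chain
#'
#' Downsample to `target_fs`, then zero-phase band-pass filter the
#' continuous data (filtering precedes epoching in this package).
#'
#' @param rec a `mibci_recording`.
#' @param target_fs target rate in Hz (default 250).
#' @param band broad `(lo, hi)` Hz band (default 6-35 Hz, covering the mu
#'   and beta rhythms). A 6th-order spec is used here so that out-of-band
#'   interference (e.g. 50 Hz mains) is rejected by more than 40 dB; the
#'   narrow per-band filters downstream keep the 4th-order default.
#' @return the preprocessed `mibci_recording`.
#' @export
preprocess_recording <- function(rec, target_fs = 250, band = c(6, 35)) {
  bandpass(downsample(rec, target_fs), filter_spec(band, order = 6))
}
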