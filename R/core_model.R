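#' The closed four-class motor-imagery vocabulary
#'
#' The paradigm distinguishes rest from three kinds of imagined movement of
#' the same (right) upper limb: a hand grasp, an elbow flexion/extension,
#' and a goal-directed elbow movement. All event labels in the package are
#' drawn from this closed vocabulary, in this canonical order.
#'
#' @return character vector of the four class labels.
#' @export
mi_classes <- function() c("REST", "MI-GRASP", "MI-ELBOW", "MI-ELBOW-GOAL")

# labels as a factor in canonical order (only levels that occur are kept)
class_factor <- function(labels, classes = NULL) {
  if (is.null(classes)) classes <- mi_classes()[mi_classes() %in% labels]
  factor(as.character(labels), levels = classes)
}

# Standard schematic 2-D scalp coordinates (unit disc, nose at +y, right
# ear at +x) for the 10-20 labels this package uses.
STANDARD_POSITIONS <- local({
  p <- rbind(
    Fp1 = c(-0.31, 0.95), Fp2 = c(0.31, 0.95),
    F7  = c(-0.79, 0.59), F3  = c(-0.50, 0.55), Fz = c(0, 0.50),
    F4  = c(0.50, 0.55),  F8  = c(0.79, 0.59),
    FC3 = c(-0.55, 0.28), FC4 = c(0.55, 0.28),
    T7  = c(-0.95, 0.00), C3  = c(-0.50, 0.00), Cz = c(0, 0),
    C4  = c(0.50, 0.00),  T8  = c(0.95, 0.00),
    CP3 = c(-0.55, -0.28), CP4 = c(0.55, -0.28),
    P7  = c(-0.79, -0.59), P3 = c(-0.50, -0.55), Pz = c(0, -0.50),
    P4  = c(0.50, -0.55),  P8 = c(0.79, -0.59)
  )
  colnames(p) <- c("x", "y")
  p
})

#' Construct an EEG montage
#'
#' A montage is the ordered set of data channels with 2-D schematic scalp
#' positions (inside the unit disc, nose at the top) plus the label of the
#' reference electrode, which is not a data channel.
#'
#' @param channel_names character vector of unique channel labels.
#' @param positions numeric matrix (channels x 2) of scalp coordinates; if
#'   `NULL`, positions are looked up from the built-in 10-20 table and
#'   unknown labels are placed evenly on an inner circle.
#' @param reference_name label of the reference electrode (default "Cz").
#' @return an object of class `mibci_montage`.
#' @export
montage <- function(channel_names, positions = NULL, reference_name = "Cz") {
  channel_names <- as.character(channel_names)
  if (anyDuplicated(channel_names))
    stop_mibci("montage_error", "duplicate channel names in montage")
  if (reference_name %in% channel_names)
    stop_mibci("montage_error",
               "reference electrode '%s' must not be a data channel",
               reference_name)
  if (is.null(positions)) {
    positions <- matrix(NA_real_, length(channel_names), 2,
                        dimnames = list(channel_names, c("x", "y")))
    known <- channel_names %in% rownames(STANDARD_POSITIONS)
    positions[known, ] <- STANDARD_POSITIONS[channel_names[known], ]
    if (any(!known)) {
      k <- sum(!known)
      th <- seq(0, 2 * pi, length.out = k + 1)[seq_len(k)]
      positions[!known, ] <- 0.7 * cbind(sin(th), cos(th))
    }
  }
  positions <- as.matrix(positions)
  if (nrow(positions) != length(channel_names) || ncol(positions) != 2)
    stop_mibci("montage_error", "positions must be a channels x 2 matrix")
  rownames(positions) <- channel_names
  colnames(positions) <- c("x", "y")
  if (any(sqrt(rowSums(positions^2)) > 1 + 1e-9))
    stop_mibci("montage_error", "all positions must lie within the unit disc")
  structure(list(channel_names = channel_names, positions = positions,
                 reference_name = reference_name),
            class = "mibci_montage")
}

#' The package's canonical 20-channel montage
#'
#' Twenty 10-20 scalp electrodes referenced to the vertex (Cz). This is a
#' documented stand-in montage covering frontal, central (C3/C4 over motor
#' cortex), and parietal (Pz) sites; any montage with the same shape can be
#' substituted.
#'
#' @return a `mibci_montage` with 20 data channels and reference "Cz".
#' @export
default_montage <- function() {
  ch <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FC3", "FC4",
          "T7", "C3", "C4", "T8", "CP3", "CP4", "P7", "P3", "Pz", "P4", "P8")
  montage(ch, STANDARD_POSITIONS[ch, ], reference_name = "Cz")
}

#' @export
print.mibci_montage <- function(x, ...) {
  cat(sprintf("<montage: %d channels, reference %s>\n",
              length(x$channel_names), x$reference_name))
  cat(" ", paste(x$channel_names, collapse = " "), "\n")
  invisible(x)
}

#' Construct an event table of cue onsets
#'
#' @param onset_s numeric vector of cue-onset times in seconds, strictly
#'   increasing.
#' @param label character vector of class labels from [mi_classes()].
#' @param session integer session index per event.
#' @param min_separation_s optional minimum allowed inter-onset interval
#'   (cue duration plus minimum rest); violations raise a validation error.
#' @return a `data.frame` of class `mibci_events` with columns
#'   `onset_s`, `label`, `session`.
#' @export
event_table <- function(onset_s, label, session = 1L, min_separation_s = 0) {
  label <- as.character(label)
  n <- length(onset_s)
  if (length(label) != n)
    stop_mibci("validation_error", "onset_s and label lengths differ")
  session <- rep_len(as.integer(session), n)
  bad <- setdiff(unique(label), mi_classes())
  if (length(bad))
    stop_mibci("vocabulary_error", "unknown class label(s): %s",
               paste(bad, collapse = ", "))
  if (n > 1) {
    d <- diff(onset_s)
    if (any(d <= 0))
      stop_mibci("validation_error", "event onsets must be strictly increasing")
    if (any(d < min_separation_s - 1e-9))
      stop_mibci("validation_error",
                 "inter-onset interval below the minimum of %.2f s",
                 min_separation_s)
  }
  structure(data.frame(onset_s = as.numeric(onset_s), label = label,
                       session = session, stringsAsFactors = FALSE),
            class = c("mibci_events", "data.frame"))
}

#' Construct a continuous EEG recording
#'
#' @param samples numeric matrix, channels x time, in microvolts; row names
#'   (if present) must match the montage channel order.
#' @param fs sampling rate in Hz.
#' @param montage a [montage()].
#' @param events an [event_table()].
#' @return an object of class `mibci_recording`.
#' @export
recording <- function(samples, fs, montage, events) {
  samples <- as.matrix(samples)
  if (!inherits(montage, "mibci_montage"))
    stop_mibci("validation_error", "montage must be a mibci_montage")
  if (nrow(samples) != length(montage$channel_names))
    stop_mibci("format_error",
               "sample rows (%d) do not match montage channels (%d)",
               nrow(samples), length(montage$channel_names))
  if (!is.numeric(fs) || fs <= 0)
    stop_mibci("validation_error", "fs must be positive")
  if (!inherits(events, "mibci_events"))
    events <- do.call(event_table, as.list(events))
  dur <- ncol(samples) / fs
  if (nrow(events) && any(events$onset_s < 0 | events$onset_s >= dur))
    stop_mibci("validation_error",
               "event onsets must fall inside the recording (0, %.2f s)", dur)
  rownames(samples) <- montage$channel_names
  structure(list(samples = samples, fs = fs, montage = montage,
                 events = events),
            class = "mibci_recording")
}

#' @export
print.mibci_recording <- function(x, ...) {
  cat(sprintf("<recording: %d ch x %d samples @ %g Hz (%.1f s), %d events>\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs, nrow(x$events)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a `mibci_recording`.
#' @return numeric seconds.
#' @export
recording_duration <- function(rec) ncol(rec$samples) / rec$fs

#' Construct a set of cue-locked epochs
#'
#' An epoch set is a trial x channel x sample array of fixed-length
#' segments cut around cue onsets, with one class label per trial. The
#' sample count must equal `round((end - start) * fs)`.
#'
#' @param data 3-d numeric array, trial x channel x sample.
#' @param labels character class label per trial.
#' @param fs sampling rate in Hz.
#' @param window numeric `(start_s, end_s)` relative to cue onset,
#'   half-open `[start, end)`.
#' @param montage a [montage()] describing the channel axis.
#' @return an object of class `mibci_epochs`.
#' @export
epoch_set <- function(data, labels, fs, window, montage) {
  if (length(dim(data)) != 3)
    stop_mibci("validation_error", "data must be trial x channel x sample")
  labels <- as.character(labels)
  if (dim(data)[1] != length(labels))
    stop_mibci("validation_error", "number of trials must equal label count")
  if (dim(data)[2] != length(montage$channel_names))
    stop_mibci("validation_error", "channel axis does not match montage")
  if (window[2] <= window[1])
    stop_mibci("validation_error", "epoch window end must exceed start")
  n_expect <- round((window[2] - window[1]) * fs)
  if (dim(data)[3] != n_expect)
    stop_mibci("validation_error",
               "epoch length %d != round((end-start)*fs) = %d",
               dim(data)[3], n_expect)
  bad <- setdiff(unique(labels), mi_classes())
  if (length(bad))
    stop_mibci("vocabulary_error", "unknown class label(s): %s",
               paste(bad, collapse = ", "))
  dimnames(data) <- list(NULL, montage$channel_names, NULL)
  structure(list(data = data, labels = labels, fs = fs,
                 window = as.numeric(window), montage = montage),
            class = "mibci_epochs")
}

#' @export
print.mibci_epochs <- function(x, ...) {
  cat(sprintf(
    "<epochs: %d trials x %d ch x %d samples @ %g Hz, window [%g, %g) s>\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs,
    x$window[1], x$window[2]))
  print(table(x$labels))
  invisible(x)
}

#' Number of trials in an epoch set
#' @param x a `mibci_epochs`.
#' @return integer trial count.
#' @export
n_trials <- function(x) dim(x$data)[1]

#' Subset an epoch set by trial index
#' @param x a `mibci_epochs`.
#' @param idx integer or logical trial index.
#' @return a `mibci_epochs` with the selected trials.
#' @export
subset_epochs <- function(x, idx) {
  epoch_set(x$data[idx, , , drop = FALSE], x$labels[idx], x$fs, x$window,
            x$montage)
}

#' Read a recording from delimited text files
#'
#' The signal file is a CSV with header `time_s,<ch1>,<ch2>,...` (time in
#' seconds, potentials in microvolts); the events file has header
#' `onset_s,label,session`. The sampling rate is inferred from the time
#' column and must be constant to within 1 ppm.
#'
#' @param signal_path path to the signal CSV.
#' @param events_path path to the events CSV.
#' @param montage optional [montage()]; if `NULL` one is built from the
#'   header channel names (the default montage when the names match it).
#' @return a `mibci_recording`.
#' @export
read_recording <- function(signal_path, events_path, montage = NULL) {
  sig <- data.table::fread(signal_path, sep = ",", data.table = FALSE)
  if (ncol(sig) < 2 || names(sig)[1] != "time_s")
    stop_mibci("format_error",
               "signal file must have a leading 'time_s' column")
  tm <- sig[[1]]
  if (length(tm) < 2)
    stop_mibci("format_error", "signal file needs at least 2 samples")
  d <- diff(tm)
  if (any(d <= 0))
    stop_mibci("validation_error", "time column must be strictly increasing")
  dt <- (tm[length(tm)] - tm[1]) / (length(tm) - 1)
  if (max(abs(d - dt)) > 1e-6 * dt)
    stop_mibci("validation_error",
               "sampling interval varies by more than 1 ppm")
  fs <- 1 / dt
  ch <- names(sig)[-1]
  if (is.null(montage)) {
    def <- default_montage()
    montage <- if (identical(ch, def$channel_names)) def else montage(ch)
  } else if (!identical(ch, montage$channel_names)) {
    stop_mibci("format_error",
               "signal header channels do not match the supplied montage")
  }
  ev <- data.table::fread(events_path, sep = ",", data.table = FALSE)
  if (nrow(ev) == 0) {
    events <- event_table(numeric(0), character(0), integer(0))
  } else {
    if (!all(c("onset_s", "label", "session") %in% names(ev)))
      stop_mibci("format_error",
                 "events file must have columns onset_s, label, session")
    events <- event_table(ev$onset_s, ev$label, ev$session)
  }
  bci_log("read recording: %d ch, %d samples, fs = %g", length(ch),
          nrow(sig), fs)
  recording(t(as.matrix(sig[, -1, drop = FALSE])), fs, montage, events)
}

#' Write a recording to delimited text files
#'
#' Inverse of [read_recording()]: samples round-trip to at least 6
#' significant digits and events exactly.
#'
#' @param rec a `mibci_recording`.
#' @param signal_path,events_path output paths.
#' @return invisibly, the two paths.
#' @export
write_recording <- function(rec, signal_path, events_path) {
  n <- ncol(rec$samples)
  sig <- data.frame(time_s = (seq_len(n) - 1) / rec$fs)
  for (i in seq_len(nrow(rec$samples)))
    sig[[rec$montage$channel_names[i]]] <- rec$samples[i, ]
  data.table::fwrite(sig, signal_path)
  ev <- as.data.frame(rec$events)
  if (nrow(ev) == 0)
    ev <- data.frame(onset_s = numeric(0), label = character(0),
                     session = integer(0))
  data.table::fwrite(ev, events_path)
  invisible(c(signal_path, events_path))
}
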