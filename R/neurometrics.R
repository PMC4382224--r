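#' ERD/ERS time course of a rhythm at one channel
#'
#' Band-filters the channel (zero-phase Butterworth), squares the samples
#' to instantaneous power, smooths with a moving average, cuts one segment
#' per cue of the requested class, averages across trials, and expresses
#' the result as percent change relative to the mean power in a pre-cue
#' baseline window (the Pfurtscheller convention): negative values are
#' event-related desynchronization (ERD), positive values post-task
#' synchronization (ERS).
#'
#' @param rec a `mibci_recording` (raw or preprocessed).
#' @param label class whose trials to average.
#' @param channel channel label.
#' @param band `(lo, hi)` Hz rhythm band (mu 8-11, beta 14-18 by default
#'   convention).
#' @param baseline_window `(start_s, end_s)` relative to cue, both
#'   negative (default -2 to -0.5 s).
#' @param window segment `(start_s, end_s)` relative to cue (default -3
#'   to 7 s, covering baseline, task, and recovery).
#' @param smooth_s moving-average width for the power trace, seconds
#'   (default 0.1).
#' @return an object of class `mibci_erd`: `times` (s, cue at 0),
#'   `values` (percent change), `band`, `channel`, `baseline_window`,
#'   `n_trials`.
#' @export
erd_time_course <- function(rec, label, channel, band = c(8, 11),
                            baseline_window = c(-2, -0.5),
                            window = c(-3, 7), smooth_s = 0.1) {
  if (baseline_window[2] > 0)
    stop_mibci("config_error", "baseline window must precede the cue")
  ci <- match(channel, rec$montage$channel_names)
  if (is.na(ci))
    stop_mibci("lookup_error", "unknown channel '%s'", channel)
  ons <- rec$events$onset_s[rec$events$label == label]
  if (!length(ons))
    stop_mibci("empty_class_error", "no events with label '%s'", label)
  bf <- signal::butter(4, band / (rec$fs / 2), type = "pass")
  p <- signal::filtfilt(bf, rec$samples[ci, ])^2
  w <- max(1L, round(smooth_s * rec$fs))
  p <- as.numeric(stats::filter(p, rep(1 / w, w), sides = 2))
  n_len <- round((window[2] - window[1]) * rec$fs)
  seg <- matrix(0, length(ons), n_len)
  for (i in seq_along(ons)) {
    i0 <- floor((ons[i] + window[1]) * rec$fs)
    if (i0 < 0 || i0 + n_len > length(p))
      stop_mibci("boundary_error",
                 "ERD window for the event at %.2f s leaves the recording",
                 ons[i])
    seg[i, ] <- p[(i0 + 1):(i0 + n_len)]
  }
  avg <- colMeans(seg)
  times <- window[1] + (seq_len(n_len) - 0.5) / rec$fs
  base <- times >= baseline_window[1] & times < baseline_window[2]
  p_ref <- mean(avg[base], na.rm = TRUE)
  structure(list(times = times, values = 100 * (avg - p_ref) / p_ref,
                 band = band, channel = channel,
                 baseline_window = baseline_window,
                 n_trials = length(ons), label = label),
            class = "mibci_erd")
}

#' @export
print.mibci_erd <- function(x, ...) {
  ok <- is.finite(x$values)
  cat(sprintf(
    "<ERD %s @ %s, %g-%g Hz, %d trials; range [%.0f%%, %.0f%%]>\n",
    x$label, x$channel, x$band[1], x$band[2], x$n_trials,
    min(x$values[ok]), max(x$values[ok])))
  invisible(x)
}

#' R-squared topographic class-difference map
#'
#' For every channel and frequency bin: band-filter each trial, take the
#' log-variance (single-trial log band power), and compute the squared
#' Pearson correlation between that feature and the binary class label
#' across trials — the proportion of single-trial feature variance
#' explained by the task. Values lie in `[0, 1]`; a zero-variance feature
#' is assigned 0 with a warning.
#'
#' @param epochs a broadband-filtered `mibci_epochs` with both classes.
#' @param labelA,labelB the class pair compared.
#' @param bins list of `(lo, hi)` Hz bins (default four contiguous 4-Hz
#'   bins spanning 8-24 Hz).
#' @return an object of class `mibci_rsq`: `values` (channels x bins
#'   matrix), `bins`, `class_pair`.
#' @export
r_squared_map <- function(epochs, labelA, labelB,
                          bins = list(c(8, 12), c(12, 16), c(16, 20),
                                      c(20, 24))) {
  keep <- epochs$labels %in% c(labelA, labelB)
  if (!any(epochs$labels == labelA) || !any(epochs$labels == labelB))
    stop_mibci("empty_class_error", "both classes must be present")
  ep <- subset_epochs(epochs, keep)
  y <- as.numeric(ep$labels == labelB)
  nc <- dim(ep$data)[2]
  vals <- matrix(0, nc, length(bins),
                 dimnames = list(ep$montage$channel_names,
                                 vapply(bins, band_key, "")))
  for (j in seq_along(bins)) {
    bf <- signal::butter(4, bins[[j]] / (ep$fs / 2), type = "pass")
    for (ch in seq_len(nc)) {
      feat <- vapply(seq_len(n_trials(ep)), function(i)
        log_var(var(signal::filtfilt(bf, ep$data[i, ch, ]))), 0)
      if (sd(feat) < 1e-12) {
        warning(sprintf("zero-variance feature at %s, bin %s; R^2 set to 0",
                        ep$montage$channel_names[ch], band_key(bins[[j]])),
                call. = FALSE)
        vals[ch, j] <- 0
      } else vals[ch, j] <- cor(feat, y)^2
    }
  }
  structure(list(values = vals, bins = bins,
                 class_pair = c(labelA, labelB)),
            class = "mibci_rsq")
}

#' @export
print.mibci_rsq <- function(x, ...) {
  cat(sprintf("<R^2 map %s vs %s, %d channels x %d bins, max %.3f>\n",
              x$class_pair[1], x$class_pair[2], nrow(x$values),
              ncol(x$values), max(x$values)))
  invisible(x)
}

# inverse-distance-weighted interpolation of per-channel values onto a
# grid over the unit disc (NA outside the head)
interpolate_scalp <- function(values, positions, grid_n = 67) {
  gx <- seq(-1, 1, length.out = grid_n)
  field <- matrix(NA_real_, grid_n, grid_n)
  for (i in seq_len(grid_n)) for (j in seq_len(grid_n)) {
    if (gx[i]^2 + gx[j]^2 > 1) next
    d2 <- (positions[, 1] - gx[i])^2 + (positions[, 2] - gx[j])^2
    if (any(d2 < 1e-12)) field[i, j] <- values[which.min(d2)]
    else {
      w <- 1 / d2
      field[i, j] <- sum(w * values) / sum(w)
    }
  }
  list(x = gx, y = gx, field = field)
}

#' Render a topographic scalp map
#'
#' Interpolates per-channel values over the unit disc (inverse-distance
#' weighting) and writes a PNG; purely presentational. For an
#' [r_squared_map()], one panel per frequency bin is drawn.
#'
#' @param x a named per-channel numeric vector or a `mibci_rsq`.
#' @param montage the [montage()] supplying channel positions.
#' @param file output PNG path; `NULL` draws on the active device.
#' @param grid_n interpolation grid resolution per axis.
#' @param main plot title.
#' @return invisibly, the list of interpolated fields (`x`, `y`, `field`)
#'   per panel.
#' @export
topoplot <- function(x, montage, file = NULL, grid_n = 67, main = "") {
  if (inherits(x, "mibci_rsq")) {
    panels <- lapply(seq_len(ncol(x$values)), function(j) x$values[, j])
    names(panels) <- paste0(colnames(x$values), " Hz")
  } else {
    panels <- list(x)
    names(panels) <- main
  }
  for (v in panels) {
    if (is.null(names(v)) ||
        !setequal(names(v), montage$channel_names))
      stop_mibci("montage_error",
                 "value names must match the montage channels")
  }
  pos <- montage$positions
  fields <- lapply(panels, function(v)
    interpolate_scalp(v[montage$channel_names], pos, grid_n))
  if (!is.null(file)) {
    grDevices::png(file, width = 320 * length(fields), height = 340)
    on.exit(grDevices::dev.off())
  }
  if (length(fields) > 1) {
    op <- graphics::par(mfrow = c(1, length(fields)), mar = c(1, 1, 2, 1))
    on.exit(graphics::par(op), add = TRUE)
  }
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    graphics::image(f$x, f$y, f$field, asp = 1, axes = FALSE,
                    xlab = "", ylab = "", main = names(fields)[k],
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE))
    th <- seq(0, 2 * pi, length.out = 181)
    graphics::lines(cos(th), sin(th))
    graphics::points(pos[, 1], pos[, 2], pch = 20, cex = 0.5)
  }
  invisible(fields)
}
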