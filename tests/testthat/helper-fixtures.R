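# Small simulation configurations and toy builders shared across tests.
# Everything is generated in code; sizes are scaled down from the full
# paradigm (4 sessions x 20 trials/class at 1000 Hz) to keep the suite
# fast while preserving the trial structure.

quick_cfg <- function(classes = c("REST", "MI-GRASP"), trials = 10,
                      sessions = 1, fs = 250, seed = 42, ...) {
  sim_config(fs = fs, n_sessions = sessions,
             trials_per_class_per_session = trials,
             class_specs = default_class_specs()[classes],
             seed = seed, ...)
}

quick_bank <- function(cfg, bands = list(c(7, 30)), window = c(1, 3)) {
  rec <- preprocess_recording(generate_recording(cfg), min(cfg$fs, 250))
  band_epochs(rec, bands, window)
}

all_bands <- function() list(c(7, 30), c(7, 15), c(15, 25), c(25, 30))

# toy epoch set with explicit per-trial channel x sample matrices
toy_epochs <- function(trials, labels, fs = NULL) {
  nc <- nrow(trials[[1]])
  ns <- ncol(trials[[1]])
  if (is.null(fs)) fs <- ns # => window (0, 1) s
  mt <- montage(paste0("ch", seq_len(nc)), reference_name = "REF")
  dat <- array(0, c(length(trials), nc, ns))
  for (i in seq_along(trials)) dat[i, , ] <- trials[[i]]
  epoch_set(dat, labels, fs, c(0, ns / fs), mt)
}

# two zero-mean, unit-power, orthogonal 4-sample carriers
CARRIER_U <- c(1, -1, 1, -1)
CARRIER_V <- c(1, 1, -1, -1)

# Gaussian feature clouds for classifier tests
gauss_features <- function(n_per_class, centers, sd = 1, seed = 1,
                           labels = c("REST", "MI-GRASP")) {
  with_seed(seed, {
    x <- do.call(rbind, lapply(seq_along(labels), function(k)
      matrix(rnorm(n_per_class * length(centers[[k]]), sd = sd),
             n_per_class) +
        matrix(centers[[k]], n_per_class, length(centers[[k]]),
               byrow = TRUE)))
    list(x = x, y = rep(labels, each = n_per_class))
  })
}

# mean band power at one channel over windows relative to given onsets
windowed_band_power <- function(rec, channel, band, onsets, window) {
  ci <- match(channel, rec$montage$channel_names)
  bf <- signal::butter(4, band / (rec$fs / 2), type = "pass")
  x <- signal::filtfilt(bf, rec$samples[ci, ])
  mean(vapply(onsets, function(on) {
    i0 <- floor((on + window[1]) * rec$fs)
    i1 <- i0 + round(diff(window) * rec$fs)
    mean(x[(i0 + 1):i1]^2)
  }, 0))
}
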