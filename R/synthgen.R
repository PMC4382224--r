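#' Per-class specification of the planted sensorimotor modulation
#'
#' Each imagery class modulates a mu-band and a beta-band oscillatory
#' source projected to the scalp through a class-specific topography.
#' During that class's trials the source amplitude is attenuated (event-
#' related desynchronization, ERD) from `erd_onset_s` after the cue until
#' the end of the cue, then returns to baseline over `recovery_s`; the
#' beta source may additionally rebound above baseline after the task
#' (event-related synchronization, ERS).
#'
#' @param label class label from [mi_classes()].
#' @param topography named numeric vector of per-channel gains in `[0, 1]`
#'   for the modulated source (names are montage channels; missing
#'   channels get gain 0).
#' @param mu_erd_depth fractional attenuation of mu-band source *power*
#'   during imagery (0 = none, 1 = complete).
#' @param beta_erd_depth same for the beta band.
#' @param beta_ers_gain fractional post-task beta power rebound (>= 0; 0
#'   means no ERS).
#' @param erd_onset_s latency from cue onset to the start of attenuation,
#'   in seconds (reaction/decision time; about 0.7 s in this paradigm).
#' @param recovery_s time from task end back to baseline power, seconds.
#' @return an object of class `mibci_class_spec`.
#' @export
class_spec <- function(label, topography = numeric(0), mu_erd_depth = 0,
                       beta_erd_depth = 0, beta_ers_gain = 0,
                       erd_onset_s = 0.7, recovery_s = 1.0) {
  if (!label %in% mi_classes())
    stop_mibci("vocabulary_error", "unknown class label '%s'", label)
  if (mu_erd_depth < 0 || mu_erd_depth > 1 ||
      beta_erd_depth < 0 || beta_erd_depth > 1)
    stop_mibci("config_error", "ERD depths must lie in [0, 1]")
  if (beta_ers_gain < 0)
    stop_mibci("config_error", "beta_ers_gain must be >= 0")
  if (erd_onset_s < 0 || recovery_s < 0)
    stop_mibci("config_error", "onset and recovery must be >= 0")
  if (length(topography) && (any(topography < 0) || any(topography > 1)))
    stop_mibci("config_error", "topography gains must lie in [0, 1]")
  structure(list(label = label, topography = topography,
                 mu_erd_depth = mu_erd_depth, beta_erd_depth = beta_erd_depth,
                 beta_ers_gain = beta_ers_gain, erd_onset_s = erd_onset_s,
                 recovery_s = recovery_s),
            class = "mibci_class_spec")
}

#' Default class specifications for the four-class paradigm
#'
#' Modeling choices, not measurements: MI-GRASP is focal over contralateral
#' motor cortex (C3); MI-ELBOW is broader (C3 + FC3); MI-ELBOW-GOAL adds a
#' posterior parietal (Pz) component and a deeper mu ERD, and shows no
#' post-task beta rebound; REST plants no modulation. Depths and latencies
#' follow the qualitative ERD/ERS ordering of the paradigm (attenuation
#' starting ~0.7 s after the cue, recovery ~1 s after task end, slower for
#' the goal-directed task).
#'
#' @return named list of [class_spec()] objects, one per class.
#' @export
default_class_specs <- function() {
  list(
    "REST" = class_spec("REST"),
    "MI-GRASP" = class_spec("MI-GRASP",
      topography = c(C3 = 1.0, CP3 = 0.3, FC3 = 0.25),
      mu_erd_depth = 0.5, beta_erd_depth = 0.4, beta_ers_gain = 0.4),
    "MI-ELBOW" = class_spec("MI-ELBOW",
      topography = c(C3 = 0.8, FC3 = 0.8, CP3 = 0.3, F3 = 0.2),
      mu_erd_depth = 0.45, beta_erd_depth = 0.35, beta_ers_gain = 0.3),
    "MI-ELBOW-GOAL" = class_spec("MI-ELBOW-GOAL",
      topography = c(C3 = 0.8, FC3 = 0.5, Pz = 0.7, P3 = 0.3),
      mu_erd_depth = 0.6, beta_erd_depth = 0.45, beta_ers_gain = 0,
      recovery_s = 1.4)
  )
}

#' Simulation configuration
#'
#' Describes one synthetic study: the montage, acquisition rate, session
#' and trial structure (cues of `cue_duration_s` seconds followed by a
#' uniformly random rest drawn from `rest_range_s`), the per-class planted
#' modulation, the mu/beta source bands and amplitudes, and the broadband
#' background noise level.
#'
#' @param montage a [montage()].
#' @param fs acquisition sampling rate, Hz.
#' @param n_sessions number of sessions.
#' @param trials_per_class_per_session trials of each class in a session.
#' @param cue_duration_s cue (task) duration, seconds.
#' @param rest_range_s `(min, max)` rest duration after each cue, seconds.
#' @param class_specs named list of [class_spec()]; the simulated classes.
#' @param mu_band,beta_band `(lo, hi)` Hz of the two oscillatory sources.
#' @param noise_scale RMS amplitude of the broadband background noise per
#'   channel, microvolts.
#' @param mu_amp,beta_amp RMS amplitude of each source at a unit-gain
#'   channel at baseline, microvolts.
#' @param lead_in_s quiet time before the first cue (>= 2 s so that epochs
#'   never touch filter edge transients), seconds.
#' @param tail_s quiet time after the last trial, seconds.
#' @param seed integer root seed; all randomness derives from it.
#' @return an object of class `mibci_sim_config`.
#' @export
sim_config <- function(montage = default_montage(), fs = 1000,
                       n_sessions = 4, trials_per_class_per_session = 20,
                       cue_duration_s = 3, rest_range_s = c(5, 7),
                       class_specs = default_class_specs(),
                       mu_band = c(8, 11), beta_band = c(14, 18),
                       noise_scale = 10, mu_amp = 6, beta_amp = 4,
                       lead_in_s = 5, tail_s = 5, seed = 1L) {
  if (rest_range_s[1] > rest_range_s[2])
    stop_mibci("config_error", "rest_range min must be <= max")
  for (b in list(mu_band, beta_band))
    if (b[1] <= 0 || b[2] >= fs / 2 || b[1] >= b[2])
      stop_mibci("config_error", "source bands must lie within (0, fs/2)")
  if (n_sessions < 1 || trials_per_class_per_session < 1)
    stop_mibci("config_error", "session and trial counts must be positive")
  if (lead_in_s < 2)
    stop_mibci("config_error",
               "lead_in_s must be >= 2 s to keep epochs clear of edges")
  for (cs in class_specs) {
    extra <- setdiff(names(cs$topography), montage$channel_names)
    if (length(extra))
      stop_mibci("config_error",
                 "topography of %s names channels not in the montage: %s",
                 cs$label, paste(extra, collapse = ", "))
  }
  names(class_specs) <- vapply(class_specs, `[[`, "", "label")
  structure(list(montage = montage, fs = fs, n_sessions = n_sessions,
                 trials_per_class_per_session = trials_per_class_per_session,
                 cue_duration_s = cue_duration_s, rest_range_s = rest_range_s,
                 class_specs = class_specs, mu_band = mu_band,
                 beta_band = beta_band, noise_scale = noise_scale,
                 mu_amp = mu_amp, beta_amp = beta_amp,
                 lead_in_s = lead_in_s, tail_s = tail_s,
                 seed = as.integer(seed)),
            class = "mibci_sim_config")
}

# full per-channel gain vector for a class on the config montage
full_topography <- function(cfg, label) {
  g <- stats::setNames(numeric(length(cfg$montage$channel_names)),
                       cfg$montage$channel_names)
  tp <- cfg$class_specs[[label]]$topography
  g[names(tp)] <- tp
  g
}

# amplitude envelope for one source over the whole recording
# power envelope = env^2: 1 at baseline, 1-depth during the task,
# 1+gain during a post-task rebound where configured
build_envelope <- function(n, fs, onsets, cue_s, depth, gain, onset_s,
                           recovery_s, ramp_s = 0.2) {
  env <- rep(1, n)
  lo <- sqrt(max(0, 1 - depth))
  hi <- sqrt(1 + gain)
  seg <- function(t0, t1, v0, v1) {
    i0 <- max(1L, floor(t0 * fs) + 1L)
    i1 <- min(n, floor(t1 * fs))
    if (i1 >= i0) env[i0:i1] <<- seq(v0, v1, length.out = i1 - i0 + 1L)
  }
  for (on in onsets) {
    t_drop <- on + onset_s
    t_end <- on + cue_s
    seg(t_drop, t_drop + ramp_s, 1, lo)
    seg(t_drop + ramp_s, t_end, lo, lo)
    if (gain > 0) {
      # rebound completes within recovery_s of the task end
      seg(t_end, t_end + 0.25 * recovery_s, lo, hi)
      seg(t_end + 0.25 * recovery_s, t_end + 0.6 * recovery_s, hi, hi)
      seg(t_end + 0.6 * recovery_s, t_end + recovery_s, hi, 1)
    } else {
      seg(t_end, t_end + recovery_s, lo, 1)
    }
  }
  env
}

# background: AR(1)-smoothed Gaussian noise (lowpass knee ~20 Hz, shape
# roughly invariant to fs), spatially mixed across channels
make_background <- function(n, nc, fs, scale, seed) {
  a <- exp(-2 * pi * 20 / fs)
  sd_ar <- sqrt(1 / (1 - a^2))
  W <- with_seed(seed, matrix(rnorm(nc * n), nc, n))
  for (i in seq_len(nc))
    W[i, ] <- stats::filter(W[i, ], a, method = "recursive") / sd_ar
  A <- with_seed(sub_seed(seed, "mixing"),
                 diag(nc) + 0.3 * matrix(rnorm(nc * nc), nc, nc))
  A <- A / sqrt(rowSums(A^2))
  scale * (A %*% W)
}

# narrowband source: band-filtered white noise, unit RMS
make_source <- function(n, fs, band, seed) {
  x <- with_seed(seed, rnorm(n))
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  y / sd(y)
}

# schedule of cue onsets: randomized class order within each session,
# inter-onset interval = cue + Uniform(rest_range)
make_schedule <- function(cfg) {
  classes <- names(cfg$class_specs)
  per <- cfg$trials_per_class_per_session
  onsets <- numeric(0); labels <- character(0); sessions <- integer(0)
  t_cur <- cfg$lead_in_s
  for (s in seq_len(cfg$n_sessions)) {
    lab <- with_seed(sub_seed(cfg$seed, "order", s),
                     sample(rep(classes, per)))
    iti <- with_seed(sub_seed(cfg$seed, "iti", s),
                     cfg$cue_duration_s +
                       runif(length(lab), cfg$rest_range_s[1],
                             cfg$rest_range_s[2]))
    for (k in seq_along(lab)) {
      onsets <- c(onsets, t_cur); labels <- c(labels, lab[k])
      sessions <- c(sessions, s)
      t_cur <- t_cur + iti[k]
    }
  }
  # t_cur already includes the last trial's cue and rest
  list(onsets = onsets, labels = labels, sessions = sessions,
       t_total = t_cur + cfg$tail_s)
}

#' Generate a seeded synthetic motor-imagery recording
#'
#' Builds a continuous multi-channel recording emulating the cue-based
#' paradigm: per session, a randomized balanced sequence of cues (one per
#' class per trial slot), each cue lasting `cue_duration_s` and followed by
#' a uniformly random rest. The signal is spatially mixed broadband
#' background noise plus, for every class with a non-empty topography, a
#' mu-band and a beta-band narrowband source projected through that class's
#' topography and amplitude-modulated around that class's cues per its
#' [class_spec()]. REST (or any class with zero depths) plants no
#' modulation. Identical seeds give bit-identical recordings.
#'
#' @param cfg a [sim_config()].
#' @return a `mibci_recording` with the full event table.
#' @export
generate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "mibci_sim_config"))
  sched <- make_schedule(cfg)
  n <- ceiling(sched$t_total * cfg$fs)
  nc <- length(cfg$montage$channel_names)
  bci_log("generating %d ch x %d samples (%.0f s) at %g Hz", nc, n,
          n / cfg$fs, cfg$fs)
  X <- make_background(n, nc, cfg$fs, cfg$noise_scale,
                       sub_seed(cfg$seed, "noise"))
  for (label in names(cfg$class_specs)) {
    cs <- cfg$class_specs[[label]]
    g <- full_topography(cfg, label)
    if (all(g == 0)) next
    ons <- sched$onsets[sched$labels == label]
    mu <- make_source(n, cfg$fs, cfg$mu_band, sub_seed(cfg$seed, "mu", label))
    env_mu <- build_envelope(n, cfg$fs, ons, cfg$cue_duration_s,
                             cs$mu_erd_depth, 0, cs$erd_onset_s,
                             cs$recovery_s)
    X <- X + (cfg$mu_amp * g) %o% (mu * env_mu)
    be <- make_source(n, cfg$fs, cfg$beta_band,
                      sub_seed(cfg$seed, "beta", label))
    env_be <- build_envelope(n, cfg$fs, ons, cfg$cue_duration_s,
                             cs$beta_erd_depth, cs$beta_ers_gain,
                             cs$erd_onset_s, cs$recovery_s)
    X <- X + (cfg$beta_amp * g) %o% (be * env_be)
  }
  events <- event_table(sched$onsets, sched$labels, sched$sessions,
                        min_separation_s = cfg$cue_duration_s +
                          cfg$rest_range_s[1])
  recording(X, cfg$fs, cfg$montage, events)
}

#' Analytically planted band-power change for a class
#'
#' Self-documentation of the generator: the steady-state fractional change
#' of the modulated *source* power during (ERD) or just after (ERS) the
#' task, read off the [class_spec()] without synthesizing any signal. The
#' change measured at a scalp channel is smaller because background noise
#' adds band power; see [dilution_factor()].
#'
#' @param cfg a [sim_config()].
#' @param label class label present in `cfg$class_specs`.
#' @param band one of `"mu"`, `"beta"` (task-period ERD) or `"beta_ers"`
#'   (post-task rebound).
#' @return planted percent power change (e.g. -50 for a 0.5 mu ERD depth).
#' @export
planted_effect_oracle <- function(cfg, label,
                                  band = c("mu", "beta", "beta_ers")) {
  band <- match.arg(band)
  cs <- cfg$class_specs[[label]]
  if (is.null(cs))
    stop_mibci("lookup_error", "class '%s' not in the configuration", label)
  100 * switch(band,
               mu = -cs$mu_erd_depth,
               beta = -cs$beta_erd_depth,
               beta_ers = cs$beta_ers_gain)
}

#' Fraction of scalp band power attributable to the modulated source
#'
#' At a scalp channel, the band power is the sum of the class's modulated
#' source, the other classes' (unmodulated, baseline-level) sources in the
#' same band, and band-limited background noise; an ERD of the source
#' therefore appears diluted at the channel by the factor returned here.
#' The expected measured percent change is
#' `dilution_factor(...) * planted_effect_oracle(...)`. Component powers
#' are measured on short component-wise syntheses using the configuration's
#' own generator pieces (internal fixed sub-streams of `cfg$seed`), not on
#' the analysis pipeline under test.
#'
#' @param cfg a [sim_config()].
#' @param label class label.
#' @param band `"mu"` or `"beta"`.
#' @param channel channel at which to evaluate; default the class
#'   topography's peak channel.
#' @param dur_s length of the component syntheses, seconds.
#' @return dilution factor in `(0, 1]`.
#' @export
dilution_factor <- function(cfg, label, band = c("mu", "beta"),
                            channel = NULL, dur_s = 60) {
  band <- match.arg(band)
  g <- full_topography(cfg, label)
  if (is.null(channel)) channel <- names(which.max(g))
  if (!channel %in% cfg$montage$channel_names)
    stop_mibci("lookup_error", "unknown channel '%s'", channel)
  band_hz <- if (band == "mu") cfg$mu_band else cfg$beta_band
  amp <- if (band == "mu") cfg$mu_amp else cfg$beta_amp
  n <- round(dur_s * cfg$fs)
  nc <- length(cfg$montage$channel_names)
  bf <- signal::butter(4, band_hz / (cfg$fs / 2), type = "pass")
  # background band power at the channel
  bg <- make_background(n, nc, cfg$fs, cfg$noise_scale,
                        sub_seed(cfg$seed, "noise"))
  p_noise <- var(signal::filtfilt(bf, bg[match(channel,
                                               cfg$montage$channel_names), ]))
  # in-band source power: this class's source plus other classes' baseline
  # sources of the same band at this channel
  src <- make_source(n, cfg$fs, band_hz, sub_seed(cfg$seed, "oracle-src"))
  p_unit <- var(signal::filtfilt(bf, src)) # ~1; band-edge losses included
  gain_here <- function(lb) full_topography(cfg, lb)[channel]
  p_self <- (amp * gain_here(label))^2 * p_unit
  others <- setdiff(names(cfg$class_specs), label)
  p_other <- sum(vapply(others, function(lb) (amp * gain_here(lb))^2,
                        0)) * p_unit
  as.numeric(p_self / (p_self + p_other + p_noise))
}
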