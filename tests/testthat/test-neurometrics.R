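# mean of an ERD curve over a time window (steady-state readout that
# averages down the chi-square noise of narrowband power estimates)
erd_window_mean <- function(erd, lo, hi) {
  mean(erd$values[erd$times >= lo & erd$times < hi], na.rm = TRUE)
}

test_that("a stationary recording yields a flat ERD curve", {
  # REST plants no modulation: the curve is pure estimation noise
  cfg <- quick_cfg(classes = "REST", trials = 150, seed = 51)
  rec <- generate_recording(cfg)
  erd <- erd_time_course(rec, "REST", "C3", c(8, 11), smooth_s = 0.4)
  # band-limited power estimates carry chi-square noise of relative sd
  # ~1/sqrt(2*B*T*M); bounds sized for 150 trials of a 3 Hz band
  expect_lt(abs(erd_window_mean(erd, -3, 7)), 8)
  expect_lt(max(abs(erd$values), na.rm = TRUE), 30)
})

test_that("the planted mu ERD appears at the expected diluted depth", {
  cfg <- quick_cfg(classes = c("REST", "MI-GRASP"), trials = 40,
                   sessions = 2, seed = 52)
  rec <- generate_recording(cfg)
  erd <- erd_time_course(rec, "MI-GRASP", "C3", cfg$mu_band)
  cs <- cfg$class_specs[["MI-GRASP"]]
  expected <- dilution_factor(cfg, "MI-GRASP", "mu") *
    planted_effect_oracle(cfg, "MI-GRASP", "mu")
  steady <- erd_window_mean(erd, cs$erd_onset_s + 0.4, cfg$cue_duration_s)
  expect_lt(abs(steady - expected), 10) # percentage points
  # trough sits inside the cue interval and is negative
  expect_lt(min(erd$values[erd$times > 0 & erd$times < 3]), expected / 2)
  # baseline segment stays near zero
  expect_lt(abs(erd_window_mean(erd, -2, -0.5)), 5)
})

test_that("beta rebound is present for MI-GRASP, absent for the goal task", {
  cfg <- quick_cfg(classes = c("REST", "MI-GRASP", "MI-ELBOW-GOAL"),
                   trials = 60, seed = 53)
  rec <- generate_recording(cfg)
  erd_g <- erd_time_course(rec, "MI-GRASP", "C3", cfg$beta_band)
  erd_e <- erd_time_course(rec, "MI-ELBOW-GOAL", "C3", cfg$beta_band)
  # post-task second: rebound above baseline for MI-GRASP; the goal task
  # (no planted ERS) is still recovering from its ERD there
  reb_g <- erd_window_mean(erd_g, 3, 4)
  reb_e <- erd_window_mean(erd_e, 3, 4)
  expect_gt(reb_g, 3)  # positive post-task excursion
  expect_lt(reb_e, 3)  # none planted for the goal-directed task
  # and both show a negative task-period deflection
  expect_lt(erd_window_mean(erd_g, 1.5, 3), 0)
  expect_lt(erd_window_mean(erd_e, 1.5, 3), 0)
})

test_that("ERD estimates stabilize as trial count doubles", {
  erd_at <- function(trials, seed) {
    cfg <- quick_cfg(classes = "MI-GRASP", trials = trials, seed = seed)
    rec <- generate_recording(cfg)
    erd_time_course(rec, "MI-GRASP", "C3", c(8, 11))
  }
  a <- erd_at(40, 54)
  b <- erd_at(80, 55)
  sa <- erd_window_mean(a, 1.5, 3)
  sb <- erd_window_mean(b, 1.5, 3)
  expect_lt(abs(sa - sb), 12)
})

test_that("ERD errors on unknown channels and empty classes", {
  cfg <- quick_cfg(trials = 4, seed = 56)
  rec <- generate_recording(cfg)
  expect_error(erd_time_course(rec, "MI-GRASP", "Oz", c(8, 11)),
               class = "lookup_error")
  expect_error(erd_time_course(rec, "MI-ELBOW", "C3", c(8, 11)),
               class = "empty_class_error")
  expect_error(erd_time_course(rec, "REST", "C3", c(8, 11),
                               baseline_window = c(0.5, 1)),
               class = "config_error")
})

test_that("R^2 is 1 for perfectly separating features, 0 for orthogonal", {
  base <- sin(2 * pi * 10 * (0:499) / 250) # in-band carrier
  mk <- function(scales, labels) {
    trials <- lapply(scales, function(s) matrix(sqrt(s) * base, 1))
    toy_epochs(trials, labels, fs = 250)
  }
  sep <- r_squared_map(mk(c(1, 1, 2, 2), c("REST", "REST", "MI-GRASP",
                                           "MI-GRASP")),
                       "REST", "MI-GRASP", bins = list(c(8, 12)))
  expect_equal(unname(sep$values[1, 1]), 1, tolerance = 1e-9)
  ort <- r_squared_map(mk(c(1, 2, 1, 2), c("REST", "REST", "MI-GRASP",
                                           "MI-GRASP")),
                       "REST", "MI-GRASP", bins = list(c(8, 12)))
  expect_equal(unname(ort$values[1, 1]), 0, tolerance = 1e-9)
})

test_that("R^2 is symmetric in the class pair and affine-invariant", {
  cfg <- quick_cfg(trials = 10, seed = 57)
  ep <- epoch(preprocess_recording(generate_recording(cfg), 250), c(1, 3))
  m1 <- r_squared_map(ep, "REST", "MI-GRASP", bins = list(c(8, 12)))
  m2 <- r_squared_map(ep, "MI-GRASP", "REST", bins = list(c(8, 12)))
  expect_equal(m1$values, m2$values)
  # a global amplitude rescale is affine in the log-power feature
  ep3 <- ep; ep3$data <- ep$data * 3
  m3 <- r_squared_map(ep3, "REST", "MI-GRASP", bins = list(c(8, 12)))
  expect_equal(m1$values, m3$values, tolerance = 1e-6)
})

test_that("label-independent epochs give a near-zero R^2 map", {
  cfg <- quick_cfg(classes = c("REST", "MI-GRASP"), trials = 40,
                   sessions = 2, seed = 58)
  rec <- generate_recording(cfg)
  ep <- epoch(preprocess_recording(rec, 250), c(1, 3))
  ep$labels <- with_seed(4, sample(ep$labels)) # break the association
  map <- r_squared_map(ep, "REST", "MI-GRASP")
  expect_lt(mean(map$values), 0.05)
  expect_true(all(map$values >= 0 & map$values <= 1))
  expect_equal(dim(map$values), c(20, 4))
})

test_that("the planted effect produces a C3-focused R^2 map", {
  cfg <- quick_cfg(classes = c("REST", "MI-GRASP"), trials = 30,
                   sessions = 2, seed = 59)
  ep <- epoch(preprocess_recording(generate_recording(cfg), 250), c(1, 3))
  map <- r_squared_map(ep, "REST", "MI-GRASP", bins = list(c(8, 12)))
  expect_equal(rownames(map$values)[which.max(map$values[, 1])], "C3")
})

test_that("topoplot interpolates with the hottest point at the hot channel", {
  mt <- default_montage()
  v <- stats::setNames(rep(0.1, 20), mt$channel_names)
  v["C3"] <- 1
  f <- tempfile(fileext = ".png")
  fields <- topoplot(v, mt, file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
  fld <- fields[[1]]
  peak <- arrayInd(which.max(fld$field), dim(fld$field))
  pos_peak <- c(fld$x[peak[1]], fld$y[peak[2]])
  expect_lt(sqrt(sum((pos_peak - mt$positions["C3", ])^2)), 0.1)
  # constant map renders a uniform field over the disc
  const <- topoplot(stats::setNames(rep(0.5, 20), mt$channel_names), mt,
                    file = tempfile(fileext = ".png"))
  rng <- range(const[[1]]$field, na.rm = TRUE)
  expect_equal(rng[1], rng[2], tolerance = 1e-9)
  expect_error(topoplot(v[-1], mt, file = tempfile()),
               class = "montage_error")
})
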