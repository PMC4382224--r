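#' The seven classification tasks of the paradigm
#'
#' Five binary pairs (REST vs each imagery class, and the imagery pairs
#' involving MI-GRASP) plus the two three-class tasks.
#'
#' @return named list of class-label vectors.
#' @export
default_tasks <- function() {
  list(
    "REST vs MI-GRASP" = c("REST", "MI-GRASP"),
    "REST vs MI-ELBOW" = c("REST", "MI-ELBOW"),
    "REST vs MI-ELBOW-GOAL" = c("REST", "MI-ELBOW-GOAL"),
    "MI-GRASP vs MI-ELBOW" = c("MI-GRASP", "MI-ELBOW"),
    "MI-GRASP vs MI-ELBOW-GOAL" = c("MI-GRASP", "MI-ELBOW-GOAL"),
    "REST vs MI-GRASP vs MI-ELBOW" = c("REST", "MI-GRASP", "MI-ELBOW"),
    "REST vs MI-GRASP vs MI-ELBOW-GOAL" =
      c("REST", "MI-GRASP", "MI-ELBOW-GOAL")
  )
}

#' Study run configuration
#'
#' @param sim a [sim_config()] describing one virtual participant's
#'   recording (the seed is re-derived per participant).
#' @param n_participants number of virtual participants (default 12).
#' @param tasks named list of class-label vectors; default all seven
#'   tasks of [default_tasks()].
#' @param target_fs,band,window preprocessing parameters (defaults
#'   250 Hz, 6-35 Hz, 1-3 s epochs).
#' @param n_folds,n_repeats CV protocol (default 10 x 10).
#' @param jitter fractional between-participant jitter of the class-spec
#'   parameters (default 0.2, i.e. +/-20%); modeling of inter-subject
#'   spread, not inference.
#' @param extractors,classifiers optional restricted combination lists
#'   passed to [best_of_nine()].
#' @param seed root seed for the whole study.
#' @return an object of class `mibci_run_config`.
#' @export
run_config <- function(sim = sim_config(), n_participants = 12,
                       tasks = default_tasks(), target_fs = 250,
                       band = c(6, 35), window = c(1, 3), n_folds = 10,
                       n_repeats = 10, jitter = 0.2, extractors = NULL,
                       classifiers = NULL, seed = 1L) {
  for (nm in names(tasks)) {
    if (!all(tasks[[nm]] %in% mi_classes()))
      stop_mibci("config_error", "task '%s' uses unknown classes", nm)
    if (!all(tasks[[nm]] %in% names(sim$class_specs)))
      stop_mibci("config_error",
                 "task '%s' needs classes absent from the simulation", nm)
  }
  structure(list(sim = sim, n_participants = n_participants, tasks = tasks,
                 target_fs = target_fs, band = band, window = window,
                 n_folds = n_folds, n_repeats = n_repeats, jitter = jitter,
                 extractors = extractors, classifiers = classifiers,
                 seed = as.integer(seed)),
            class = "mibci_run_config")
}

#' Read a study configuration from a YAML file
#'
#' Recognized top-level keys mirror the [run_config()] and [sim_config()]
#' arguments; unspecified values keep their defaults. Class specs may be
#' given under `sim$class_specs` as named lists of [class_spec()] fields.
#'
#' @param path YAML file path.
#' @return a `mibci_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$class_specs))
    sim_args$class_specs <- lapply(sim_args$class_specs, function(cs) {
      cs$topography <- unlist(cs$topography)
      do.call(class_spec, cs)
    })
  if (!is.null(sim_args$montage))
    sim_args$montage <- montage(unlist(sim_args$montage))
  for (nm in c("rest_range_s", "mu_band", "beta_band"))
    if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- unlist(sim_args[[nm]])
  sim <- do.call(sim_config, sim_args)
  args <- y[setdiff(names(y), "sim")]
  for (nm in c("band", "window"))
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  if (!is.null(args$tasks)) args$tasks <- lapply(args$tasks, unlist)
  do.call(run_config, c(list(sim = sim), args))
}

# jitter the numeric modulation parameters of one class spec by a
# multiplicative factor drawn uniformly from [1-j, 1+j], clamped to range
jitter_class_spec <- function(cs, j, seed) {
  if (j <= 0) return(cs)
  with_seed(seed, {
    jit <- function(v, lo = 0, hi = Inf) pmin(hi, pmax(lo, v * runif(1, 1 - j, 1 + j)))
    class_spec(cs$label, cs$topography,
               mu_erd_depth = jit(cs$mu_erd_depth, 0, 1),
               beta_erd_depth = jit(cs$beta_erd_depth, 0, 1),
               beta_ers_gain = jit(cs$beta_ers_gain),
               erd_onset_s = jit(cs$erd_onset_s),
               recovery_s = jit(cs$recovery_s))
  })
}

#' Run a full synthetic study
#'
#' Simulates `n_participants` independent virtual participants (each with
#' its own derived seed and a +/-`jitter` perturbation of the class-spec
#' modulation parameters), preprocesses each recording, and runs
#' [best_of_nine()] for every configured task on that participant's
#' trials. Identical configurations and seeds give bit-identical reports.
#'
#' @param cfg a [run_config()].
#' @return an object of class `mibci_study_report`: per-task data frames
#'   (participant, best combination, mean, sd) plus the configuration.
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "mibci_run_config"))
  rows <- lapply(names(cfg$tasks), function(nm)
    data.frame(participant = character(0), combination = character(0),
               mean = numeric(0), sd = numeric(0)))
  names(rows) <- names(cfg$tasks)
  for (p in seq_len(cfg$n_participants)) {
    pid <- sprintf("P%02d", p)
    pseed <- sub_seed(cfg$seed, "participant", p)
    sim <- cfg$sim
    sim$seed <- pseed
    sim$class_specs <- lapply(sim$class_specs, function(cs)
      jitter_class_spec(cs, cfg$jitter, sub_seed(pseed, "jitter", cs$label)))
    names(sim$class_specs) <- vapply(sim$class_specs, `[[`, "", "label")
    bci_log("participant %s: simulating", pid)
    rec <- preprocess_recording(generate_recording(sim), cfg$target_fs,
                                cfg$band)
    ext <- cfg$extractors %||% lapply(c("csp", "fbcsp", "bp"),
                                      extractor_spec)
    bank <- band_epochs(rec, extractor_bands(ext), cfg$window)
    for (nm in names(cfg$tasks)) {
      keep <- which(bank$labels %in% cfg$tasks[[nm]])
      rep_task <- best_of_nine(subset_bank(bank, keep),
                               seed = sub_seed(pseed, "task", nm),
                               n_folds = cfg$n_folds,
                               n_repeats = cfg$n_repeats,
                               extractors = cfg$extractors,
                               classifiers = cfg$classifiers)
      rows[[nm]] <- rbind(rows[[nm]], data.frame(
        participant = pid, combination = rep_task$best,
        mean = rep_task$mean, sd = rep_task$sd))
    }
  }
  structure(list(tables = rows, config = cfg), class = "mibci_study_report")
}

#' @export
print.mibci_study_report <- function(x, ...) {
  for (nm in names(x$tables)) {
    tb <- x$tables[[nm]]
    cat(nm, "\n")
    for (i in seq_len(nrow(tb)))
      cat(sprintf("  %-4s %-10s %s\n", tb$participant[i], tb$combination[i],
                  format_accuracy(tb$mean[i], tb$sd[i])))
    cat(sprintf("  %-4s %-10s %s\n", "Mean", "",
                format_accuracy(mean(tb$mean), sd(tb$mean))))
  }
  invisible(x)
}

#' Paired comparison of two task result tables
#'
#' Per-participant accuracy differences between two tasks of the same
#' study, with a paired t-test (a thin reporting convenience). When the
#' differences have zero variance the t statistic is 0 and p is 1 if the
#' mean difference is 0, otherwise +/-Inf and p = 0, by documented
#' convention.
#'
#' @param reportA,reportB data frames with columns `participant` and
#'   `mean` (as produced per task by [run_study()]), over the same
#'   participants.
#' @return list with `differences`, `mean_difference`, `t`, `p`.
#' @export
compare_tasks <- function(reportA, reportB) {
  if (!identical(reportA$participant, reportB$participant))
    stop_mibci("pairing_error", "participant sets differ between reports")
  d <- reportA$mean - reportB$mean
  if (length(d) < 2 || sd(d) == 0) {
    md <- mean(d)
    t_stat <- if (isTRUE(all.equal(md, 0))) 0 else sign(md) * Inf
    p <- if (t_stat == 0) 1 else 0
  } else {
    tt <- t.test(reportA$mean, reportB$mean, paired = TRUE)
    md <- unname(tt$estimate)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  list(differences = d, mean_difference = md, t = t_stat, p = p)
}
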