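#' Binary classifier specification
#'
#' @param kind one of `"LDA"` (linear discriminant analysis), `"LOGREG"`
#'   (L2-regularized maximum-likelihood logistic regression with the ridge
#'   strength chosen by inner cross-validation), or `"SVM_RBF"` (support
#'   vector machine with a radial-basis-function kernel and `(c, gamma)`
#'   chosen by inner-CV grid search).
#' @param c_grid SVM penalty grid; default `2^seq(-5, 15, 2)` (11 values).
#' @param gamma_grid SVM kernel-width grid; default `2^seq(-15, 3, 2)`
#'   (10 values, so 110 candidate pairs).
#' @param l2_grid ridge (lambda) grid for LOGREG, searched largest first.
#' @param inner_folds folds of the inner selection CV (default 5).
#' @return an object of class `mibci_classifier_spec`.
#' @export
classifier_spec <- function(kind = c("LDA", "LOGREG", "SVM_RBF"),
                            c_grid = 2^seq(-5, 15, 2),
                            gamma_grid = 2^seq(-15, 3, 2),
                            l2_grid = 10^seq(2, -4, -1),
                            inner_folds = 5) {
  kind <- match.arg(kind)
  if (kind == "SVM_RBF" && (!length(c_grid) || !length(gamma_grid)))
    stop_mibci("config_error", "SVM grids must be non-empty")
  if (any(l2_grid < 0))
    stop_mibci("config_error", "l2 strengths must be >= 0")
  structure(list(kind = kind, c_grid = sort(c_grid),
                 gamma_grid = sort(gamma_grid),
                 l2_grid = sort(l2_grid, decreasing = TRUE),
                 inner_folds = inner_folds),
            class = "mibci_classifier_spec")
}

clf_display <- c(LDA = "LDA", LOGREG = "LR", SVM_RBF = "SVM")

# ridge logistic fit; glmnet's small-class caution is routine at the fold
# sizes of a 10-fold CV on few trials, so it is muffled
ridge_logistic <- function(x, y, lambda) {
  withCallingHandlers(
    glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = lambda,
                   standardize = FALSE),
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}
ext_display <- c(csp = "CSP", fbcsp = "FBCSP", bp = "BP")

# stratified fold assignment: within each class, shuffled round-robin
stratified_folds <- function(y, k, seed) {
  y <- as.factor(y)
  cnt <- table(y)
  if (any(cnt < k))
    stop_mibci("stratification_error",
               "class '%s' has %d trials, fewer than %d folds",
               names(cnt)[which.min(cnt)], min(cnt), k)
  fold <- integer(length(y))
  with_seed(seed, for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  })
  fold
}

standardize_fit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  list(center = ctr, scale = scl)
}
standardize_apply <- function(x, st)
  sweep(sweep(x, 2, st$center), 2, st$scale, "/")

as_feature_xy <- function(features, labels = NULL) {
  if (inherits(features, "mibci_features")) {
    list(x = features$values, y = features$labels)
  } else list(x = as.matrix(features), y = labels)
}

#' Train a binary classifier
#'
#' Features are standardized (training statistics stored in the model);
#' model selection for LOGREG and SVM_RBF uses inner stratified
#' cross-validation on the training data only. The returned model predicts
#' labels via [predict_binary()] and signed confidences via
#' [score_binary()] (positive scores favor the first of the two class
#' labels in canonical order).
#'
#' @param features a [feature_matrix()], or a plain trials x features
#'   matrix together with `labels`.
#' @param spec a [classifier_spec()].
#' @param labels per-trial labels when `features` is a plain matrix.
#' @param seed seed for the inner selection CV.
#' @return an object of class `mibci_binary_model`.
#' @export
train_binary <- function(features, spec, labels = NULL, seed = 0L) {
  fx <- as_feature_xy(features, labels)
  y <- class_factor(fx$y)
  if (nlevels(y) != 2)
    stop_mibci("degenerate_training_error",
               "exactly 2 classes required, got %d", nlevels(y))
  if (any(table(y) < 2))
    stop_mibci("degenerate_training_error",
               "each class needs at least 2 training samples")
  st <- standardize_fit(fx$x)
  xs <- standardize_apply(fx$x, st)
  model <- list(kind = spec$kind, levels = levels(y), std = st, spec = spec)
  if (spec$kind == "LDA") {
    keep <- apply(xs, 2, sd) > 1e-10
    if (!any(keep)) keep[1] <- TRUE
    model$keep <- keep
    # collinear features are routine for band-power features at small n;
    # lda handles them by generalized inverse, so the warning is muffled
    model$fit <- withCallingHandlers(
      MASS::lda(xs[, keep, drop = FALSE], grouping = y),
      warning = function(w) {
        if (grepl("collinear", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  } else if (spec$kind == "LOGREG") {
    sel <- select_l2(xs, y, spec, seed)
    model$fit <- ridge_logistic(xs, y, spec$l2_grid)
    model$l2 <- sel$lambda
    model$inner_accuracy <- sel$accuracy
  } else { # SVM_RBF
    sel <- select_svm(xs, y, spec, seed)
    model$c <- sel$c
    model$gamma <- sel$gamma
    model$inner_accuracy <- sel$accuracy
    model$fit <- e1071::svm(xs, y, kernel = "radial", cost = sel$c,
                            gamma = sel$gamma, scale = FALSE)
  }
  class(model) <- "mibci_binary_model"
  model
}

# inner-CV ridge selection; ties resolved to the largest (most
# regularized) lambda by searching the grid largest-first
select_l2 <- function(xs, y, spec, seed) {
  k <- min(spec$inner_folds, min(table(y)))
  if (k < 2 || length(spec$l2_grid) == 1)
    return(list(lambda = spec$l2_grid[1], accuracy = NA_real_))
  fold <- stratified_folds(y, k, sub_seed(seed, "l2"))
  correct <- numeric(length(spec$l2_grid))
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- ridge_logistic(xs[tr, , drop = FALSE], y[tr], spec$l2_grid)
    pred <- predict(fit, xs[!tr, , drop = FALSE], s = spec$l2_grid,
                    type = "class")
    correct <- correct + colSums(pred == as.character(y[!tr]))
  }
  acc <- correct / length(y)
  best <- which.max(acc) # grid is sorted decreasing: first max = largest l2
  list(lambda = spec$l2_grid[best], accuracy = acc[best])
}

# inner-CV grid search for (c, gamma); candidates scanned in ascending
# (c, gamma) lexicographic order with strict improvement, so ties resolve
# to the smallest c then the smallest gamma
select_svm <- function(xs, y, spec, seed) {
  k <- min(spec$inner_folds, min(table(y)))
  fold <- if (k >= 2) stratified_folds(y, k, sub_seed(seed, "svm"))
          else rep(1L, length(y))
  best <- list(c = NA, gamma = NA, accuracy = -1)
  for (cc in spec$c_grid) for (gg in spec$gamma_grid) {
    if (k >= 2) {
      correct <- 0
      for (f in seq_len(k)) {
        tr <- fold != f
        fit <- e1071::svm(xs[tr, , drop = FALSE], y[tr], kernel = "radial",
                          cost = cc, gamma = gg, scale = FALSE)
        correct <- correct +
          sum(predict(fit, xs[!tr, , drop = FALSE]) == y[!tr])
      }
      acc <- correct / length(y)
    } else acc <- 0
    if (acc > best$accuracy) best <- list(c = cc, gamma = gg, accuracy = acc)
  }
  best
}

#' Grid search for the RBF-kernel SVM
#'
#' Selects the `(c, gamma)` pair maximizing inner stratified CV accuracy
#' on the training data only, with deterministic tie-breaking (smallest
#' `c`, then smallest `gamma`), and returns the selected pair together
#' with the model refitted on all training data.
#'
#' @inheritParams train_binary
#' @return list with elements `c`, `gamma`, `model` (a
#'   `mibci_binary_model`), and `inner_accuracy`.
#' @export
grid_search_svm <- function(features, spec = classifier_spec("SVM_RBF"),
                            labels = NULL, seed = 0L) {
  if (spec$kind != "SVM_RBF")
    stop_mibci("config_error", "grid_search_svm needs an SVM_RBF spec")
  m <- train_binary(features, spec, labels, seed)
  list(c = m$c, gamma = m$gamma, model = m,
       inner_accuracy = m$inner_accuracy)
}

#' Predict labels with a binary model
#' @param model a `mibci_binary_model`.
#' @param x trials x features matrix (raw scale; standardization is
#'   applied internally).
#' @return character vector of predicted labels.
#' @export
predict_binary <- function(model, x) {
  lv <- model$levels
  ifelse(score_binary(model, x) >= 0, lv[1], lv[2])
}

#' Signed confidence of a binary model
#'
#' Positive values favor the first of the model's two classes (canonical
#' order): the posterior-probability difference for LDA, the negated
#' logistic link for LOGREG, and the signed decision value for SVM_RBF.
#'
#' @inheritParams predict_binary
#' @return numeric vector of signed scores.
#' @export
score_binary <- function(model, x) {
  xs <- standardize_apply(as.matrix(x), model$std)
  lv <- model$levels
  if (model$kind == "LDA") {
    p <- predict(model$fit, xs[, model$keep, drop = FALSE])$posterior
    as.numeric(p[, lv[1]] - p[, lv[2]])
  } else if (model$kind == "LOGREG") {
    # glmnet links model the probability of the second factor level
    -as.numeric(predict(model$fit, xs, s = model$l2, type = "link"))
  } else {
    dv <- attr(predict(model$fit, xs, decision.values = TRUE),
               "decision.values")
    if (colnames(dv)[1] == paste(lv[1], lv[2], sep = "/"))
      as.numeric(dv[, 1]) else -as.numeric(dv[, 1])
  }
}

#' Train a one-vs-one multiclass model
#'
#' Fits one (feature bank, binary classifier) pair per unordered class
#' pair — `K(K-1)/2` classifiers for `K` classes. For CSP/FBCSP the
#' spatial filters are fitted per pair on that pair's trials only.
#'
#' @param x a `mibci_epoch_bank` (from [band_epochs()]) or a single
#'   `mibci_epochs` whose band matches the extractor's.
#' @param extractor an [extractor_spec()].
#' @param clf_spec a [classifier_spec()].
#' @param seed seed for inner selection CV.
#' @param idx optional training-trial index into the bank (used by
#'   cross-validation); default all trials.
#' @return an object of class `mibci_ovo_model`.
#' @export
ovo_train <- function(x, extractor, clf_spec, seed = 0L, idx = NULL) {
  bank <- as_epoch_bank(x, extractor)
  if (is.null(idx)) idx <- seq_along(bank$labels)
  labs <- bank$labels[idx]
  classes <- mi_classes()[mi_classes() %in% labs]
  if (length(classes) < 2)
    stop_mibci("degenerate_training_error", "need at least 2 classes")
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  sub <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    pidx <- idx[labs %in% pr]
    res <- tryCatch({
      ef <- fit_extractor(bank, extractor, pr[1], pr[2], pidx)
      fm <- extract_features(ef, bank, pidx)
      list(extractor = ef,
           model = train_binary(fm, clf_spec,
                                seed = sub_seed(seed, "pair", i)))
    }, error = function(e)
      stop_mibci("training_error", "pair %s vs %s failed: %s",
                 pr[1], pr[2], conditionMessage(e)))
    sub[[i]] <- res
  }
  structure(list(classes = classes, pairs = pairs, sub = sub,
                 extractor = extractor, clf_spec = clf_spec),
            class = "mibci_ovo_model")
}

# promote a bare epoch set to a single-band bank matching the extractors
as_epoch_bank <- function(x, extractors) {
  if (inherits(x, "mibci_epoch_bank")) return(x)
  if (!inherits(x, "mibci_epochs"))
    stop_mibci("validation_error", "expected an epoch bank or epoch set")
  if (inherits(extractors, "mibci_extractor_spec"))
    extractors <- list(extractors)
  bands <- extractor_bands(extractors)
  if (length(bands) != 1)
    stop_mibci("config_error",
               "a bare epoch set can only serve a single-band extractor")
  bank <- list(bands = stats::setNames(list(x), band_key(bands[[1]])),
               labels = x$labels, montage = x$montage, window = x$window)
  structure(bank, class = "mibci_epoch_bank")
}

#' Predict with a one-vs-one model
#'
#' Every binary sub-classifier votes; the class with the most votes wins.
#' Ties are broken by the summed signed confidence accumulated for each
#' class, then by the lowest class index in canonical order.
#'
#' @param model a [ovo_train()] model.
#' @param x a `mibci_epoch_bank` or `mibci_epochs` with the training
#'   montage.
#' @param idx optional trial index to predict (default all).
#' @return character vector of predicted labels.
#' @export
ovo_predict <- function(model, x, idx = NULL) {
  bank <- as_epoch_bank(x, model$extractor)
  if (!identical(bank$montage$channel_names,
                 model$sub[[1]]$extractor$montage %||%
                 bank$montage$channel_names))
    stop_mibci("shape_error", "montage does not match the trained model")
  if (is.null(idx)) idx <- seq_along(bank$labels)
  scores <- lapply(seq_along(model$pairs), function(i) {
    fm <- extract_features(model$sub[[i]]$extractor, bank, idx)
    score_binary(model$sub[[i]]$model, fm$values)
  })
  tally_votes(model$classes, model$pairs, scores)
}

# one-vs-one vote aggregation: scores[[i]] is the signed confidence of
# pair i (positive favors the pair's first class); argmax of votes, ties
# broken by summed confidence, then by lowest canonical class index
tally_votes <- function(classes, pairs, scores) {
  n <- length(scores[[1]])
  votes <- matrix(0, n, length(classes), dimnames = list(NULL, classes))
  conf <- votes
  for (i in seq_along(pairs)) {
    a <- pairs[[i]][1]; b <- pairs[[i]][2]; s <- scores[[i]]
    votes[, a] <- votes[, a] + (s >= 0)
    votes[, b] <- votes[, b] + (s < 0)
    conf[, a] <- conf[, a] + pmax(s, 0)
    conf[, b] <- conf[, b] + pmax(-s, 0)
  }
  out <- character(n)
  for (t in seq_len(n)) {
    cand <- which(votes[t, ] == max(votes[t, ]))
    if (length(cand) > 1) cand <- cand[conf[t, cand] == max(conf[t, cand])]
    out[t] <- classes[cand[1]] # lowest canonical index on full ties
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a repeated stratified fold plan
#'
#' @param labels per-trial labels.
#' @param n_folds folds per repeat.
#' @param n_repeats repeats (fold assignment re-randomized each repeat).
#' @param seed integer seed.
#' @return list of `n_repeats` integer vectors of fold ids.
#' @export
make_fold_plan <- function(labels, n_folds = 10, n_repeats = 10, seed = 1L) {
  lapply(seq_len(n_repeats), function(r)
    stratified_folds(labels, n_folds, sub_seed(seed, "repeat", r)))
}

#' Repeated stratified cross-validation of the full pipeline
#'
#' For each repeat, trials are shuffled into stratified folds; for each
#' fold, the feature extractor *and* the classifier are fitted on the nine
#' training folds only and tested on the held-out fold (no information
#' from test trials reaches the spatial filters). The default 10-fold,
#' 10-repeat protocol yields 100 fold accuracies.
#'
#' @param x a `mibci_epoch_bank` or single-band `mibci_epochs`.
#' @param extractor an [extractor_spec()].
#' @param clf_spec a [classifier_spec()].
#' @param n_folds,n_repeats protocol size (default 10 x 10).
#' @param seed seed driving fold assignment and inner selection.
#' @param fold_plan optional precomputed [make_fold_plan()] (lets several
#'   pipelines share identical folds).
#' @return an object of class `mibci_cv_result`: `fold_accuracies`
#'   (length `n_folds * n_repeats`), `mean`, `sd`, `confusion` (true x
#'   predicted counts summed over folds and repeats), `spec_id`.
#' @export
cross_validate <- function(x, extractor, clf_spec, n_folds = 10,
                           n_repeats = 10, seed = 1L, fold_plan = NULL) {
  bank <- as_epoch_bank(x, extractor)
  labs <- bank$labels
  classes <- mi_classes()[mi_classes() %in% labs]
  if (is.null(fold_plan))
    fold_plan <- make_fold_plan(labs, n_folds, n_repeats,
                                sub_seed(seed, "folds"))
  acc <- numeric(0)
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(true = classes, predicted = classes))
  for (r in seq_along(fold_plan)) {
    fold <- fold_plan[[r]]
    for (f in sort(unique(fold))) {
      test <- which(fold == f)
      train <- which(fold != f)
      model <- ovo_train(bank, extractor, clf_spec,
                         seed = sub_seed(seed, "fit", r, f), idx = train)
      pred <- ovo_predict(model, bank, idx = test)
      acc <- c(acc, mean(pred == labs[test]))
      for (t in seq_along(test))
        confusion[labs[test[t]], pred[t]] <-
          confusion[labs[test[t]], pred[t]] + 1L
    }
  }
  structure(list(fold_accuracies = acc, mean = mean(acc), sd = sd(acc),
                 confusion = confusion,
                 spec_id = c(extractor = extractor$kind,
                             classifier = clf_spec$kind),
                 n_folds = n_folds, n_repeats = length(fold_plan)),
            class = "mibci_cv_result")
}

#' @export
print.mibci_cv_result <- function(x, ...) {
  cat(sprintf("<CV %s+%s: %s over %d folds>\n",
              ext_display[x$spec_id[["extractor"]]],
              clf_display[x$spec_id[["classifier"]]],
              format_accuracy(x$mean, x$sd), length(x$fold_accuracies)))
  invisible(x)
}

#' Format an accuracy as "mean±sd" percent with one decimal
#' @param mean,sd accuracy mean and standard deviation in `[0, 1]`.
#' @return character like `"85.0±8.9"`.
#' @export
format_accuracy <- function(mean, sd)
  sprintf("%.1f±%.1f", 100 * mean, 100 * sd)

#' Run all nine extractor x classifier combinations
#'
#' Cross-validates every combination of the three feature extractors
#' (CSP, FBCSP, BP) with the three classifiers (LDA, LR, SVM) under a
#' shared fold plan, and reports the combination with the highest mean
#' accuracy (ties go to the first combination in extractor-major order
#' CSP+LDA, CSP+LR, ..., BP+SVM).
#'
#' @param x a `mibci_epoch_bank` covering bands 7-30, 7-15, 15-25,
#'   25-30 Hz, or a preprocessed `mibci_recording` (the bank is built).
#' @param seed integer seed (folds + inner selection).
#' @param n_folds,n_repeats CV protocol (default 10 x 10).
#' @param extractors,classifiers optional restricted lists of
#'   [extractor_spec()] / [classifier_spec()] (defaults: all three each).
#' @param window epoch window used when `x` is a recording.
#' @return an object of class `mibci_bon_report`: named list `results` of
#'   [cross_validate()] outputs, `best` (combination name), `mean`, `sd`.
#' @export
best_of_nine <- function(x, seed = 1L, n_folds = 10, n_repeats = 10,
                         extractors = NULL, classifiers = NULL,
                         window = c(1, 3)) {
  if (is.null(extractors))
    extractors <- lapply(c("csp", "fbcsp", "bp"), extractor_spec)
  if (is.null(classifiers))
    classifiers <- lapply(c("LDA", "LOGREG", "SVM_RBF"), classifier_spec)
  if (inherits(x, "mibci_recording"))
    x <- band_epochs(x, extractor_bands(extractors), window)
  fold_plan <- make_fold_plan(x$labels, n_folds, n_repeats,
                              sub_seed(seed, "folds"))
  results <- list()
  for (ex in extractors) for (cl in classifiers) {
    nm <- paste(ext_display[ex$kind], clf_display[cl$kind], sep = "+")
    bci_log("cross-validating %s", nm)
    results[[nm]] <- cross_validate(x, ex, cl, n_folds, n_repeats,
                                    seed = sub_seed(seed, "combo", nm),
                                    fold_plan = fold_plan)
  }
  means <- vapply(results, `[[`, 0, "mean")
  best <- names(results)[which.max(means)] # first max in documented order
  structure(list(results = results, best = best,
                 mean = results[[best]]$mean, sd = results[[best]]$sd),
            class = "mibci_bon_report")
}

#' @export
print.mibci_bon_report <- function(x, ...) {
  for (nm in names(x$results)) {
    r <- x$results[[nm]]
    cat(sprintf("  %-10s %s%s\n", nm, format_accuracy(r$mean, r$sd),
                if (nm == x$best) "  <- best" else ""))
  }
  invisible(x)
}
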