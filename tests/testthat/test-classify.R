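small_svm <- function() classifier_spec("SVM_RBF", c_grid = 2^seq(-1, 7, 2),
                                        gamma_grid = 2^seq(-5, 1, 2))

test_that("well-separated Gaussian clouds are learned perfectly by LDA", {
  g <- gauss_features(30, list(c(-4, 0), c(4, 0)), sd = 0.5, seed = 1)
  m <- train_binary(g$x, classifier_spec("LDA"), labels = g$y)
  expect_equal(mean(predict_binary(m, g$x) == g$y), 1.0)
  # scores are signed toward the first canonical class (REST)
  expect_true(all(score_binary(m, g$x)[g$y == "REST"] > 0))
})

test_that("indistinguishable classes train near chance", {
  g <- gauss_features(100, list(c(0, 0), c(0, 0)), seed = 2)
  for (kind in c("LDA", "LOGREG")) {
    m <- train_binary(g$x, classifier_spec(kind), labels = g$y, seed = 3)
    acc <- mean(predict_binary(m, g$x) == g$y)
    expect_gt(acc, 0.4); expect_lt(acc, 0.62) # binomial band at n = 200
  }
})

test_that("degenerate training inputs are rejected", {
  g <- gauss_features(10, list(c(0, 0), c(1, 1)))
  expect_error(train_binary(g$x[g$y == "REST", ], classifier_spec("LDA"),
                            labels = g$y[g$y == "REST"]),
               class = "degenerate_training_error")
  expect_error(train_binary(g$x[c(1, 11), ], classifier_spec("LDA"),
                            labels = g$y[c(1, 11)]),
               class = "degenerate_training_error")
})

test_that("RBF-SVM solves XOR clusters that defeat LDA", {
  with_seed(7, {
    n <- 40
    cx <- matrix(rnorm(4 * 2 * n, sd = 0.2), ncol = 2) +
      cbind(rep(c(-1, 1, -1, 1), each = n), rep(c(-1, 1, 1, -1), each = n))
  })
  y <- rep(c("REST", "REST", "MI-GRASP", "MI-GRASP"), each = 40)
  lda <- train_binary(cx, classifier_spec("LDA"), labels = y)
  expect_lte(mean(predict_binary(lda, cx) == y), 0.75)
  svm <- train_binary(cx, small_svm(), labels = y, seed = 1)
  expect_equal(mean(predict_binary(svm, cx) == y), 1.0)
})

test_that("the default SVM grid spans 110 candidate pairs", {
  spec <- classifier_spec("SVM_RBF")
  expect_length(spec$c_grid, 11)
  expect_length(spec$gamma_grid, 10)
  expect_equal(range(log2(spec$c_grid)), c(-5, 15))
  expect_equal(range(log2(spec$gamma_grid)), c(-15, 3))
})

test_that("grid search reaches perfect inner-CV accuracy when separable", {
  g <- gauss_features(15, list(c(-4, 0), c(4, 0)), sd = 0.3, seed = 5)
  gs <- grid_search_svm(g$x, small_svm(), labels = g$y, seed = 2)
  expect_equal(gs$inner_accuracy, 1.0)
  expect_true(gs$c %in% small_svm()$c_grid)
  expect_equal(mean(predict_binary(gs$model, g$x) == g$y), 1.0)
})

test_that("grid-search ties resolve to smallest c then smallest gamma", {
  # a trivially learnable pattern: every candidate reaches the same
  # inner-CV accuracy, so the scan must return the lexicographically
  # smallest pair
  g <- list(x = matrix(rep(c(0, 1), 20), ncol = 2),
            y = rep(c("REST", "MI-GRASP"), 10))
  gs <- grid_search_svm(g$x, small_svm(), labels = g$y, seed = 1)
  expect_equal(gs$c, min(small_svm()$c_grid))
  expect_equal(gs$gamma, min(small_svm()$gamma_grid))
})

test_that("one-vs-one trains K(K-1)/2 classifiers", {
  cfg <- quick_cfg(classes = c("REST", "MI-GRASP", "MI-ELBOW"),
                   trials = 6, seed = 17)
  bank <- quick_bank(cfg)
  m3 <- ovo_train(bank, extractor_spec("bp"), classifier_spec("LDA"))
  expect_length(m3$sub, 3)
  cfg4 <- quick_cfg(classes = mi_classes(), trials = 5, seed = 18)
  m4 <- ovo_train(quick_bank(cfg4), extractor_spec("bp"),
                  classifier_spec("LDA"))
  expect_length(m4$sub, 6)
})

test_that("with K = 2 voting reduces to the single binary classifier", {
  cfg <- quick_cfg(trials = 8, seed = 19)
  bank <- quick_bank(cfg)
  m <- ovo_train(bank, extractor_spec("bp"), classifier_spec("LDA"),
                 seed = 1)
  expect_length(m$sub, 1)
  pred <- ovo_predict(m, bank)
  fm <- mibci:::extract_features(m$sub[[1]]$extractor, bank)
  expect_identical(pred, unname(predict_binary(m$sub[[1]]$model,
                                               fm$values)))
})

test_that("vote tallying follows votes, confidence, then class order", {
  classes <- c("REST", "MI-GRASP", "MI-ELBOW")
  pairs <- list(c("REST", "MI-GRASP"), c("REST", "MI-ELBOW"),
                c("MI-GRASP", "MI-ELBOW"))
  # unanimity: everyone votes REST
  expect_equal(mibci:::tally_votes(classes, pairs,
                                   list(1, 1, 0.5)), "REST")
  # cyclic votes REST>GRASP, ELBOW>REST, GRASP>ELBOW with confidences
  # 0.9 / 0.1 / 0.2: one vote each, REST has the largest summed
  # confidence and wins
  expect_equal(mibci:::tally_votes(classes, pairs,
                                   list(0.9, -0.1, 0.2)), "REST")
  # full tie in votes and confidence: lowest canonical index
  expect_equal(mibci:::tally_votes(classes, pairs,
                                   list(0, 0, 0)), "REST")
})

test_that("cross-validation records n_folds x n_repeats accuracies", {
  cfg <- quick_cfg(trials = 12, seed = 23)
  bank <- quick_bank(cfg)
  cv <- cross_validate(bank, extractor_spec("csp"), classifier_spec("LDA"),
                       n_folds = 4, n_repeats = 3, seed = 1)
  expect_length(cv$fold_accuracies, 12)
  expect_equal(cv$mean, mean(cv$fold_accuracies))
  # confusion totals: every trial tested once per repeat
  expect_equal(sum(cv$confusion), n_trials(bank$bands[[1]]) * 3)
  rs <- rowSums(cv$confusion)
  expect_equal(as.vector(rs), rep(12 * 3, 2))
})

test_that("stratification refuses classes smaller than the fold count", {
  cfg <- quick_cfg(trials = 4, seed = 29)
  bank <- quick_bank(cfg)
  expect_error(cross_validate(bank, extractor_spec("bp"),
                              classifier_spec("LDA"), n_folds = 10,
                              n_repeats = 1),
               class = "stratification_error")
})

test_that("separable planted classes cross-validate perfectly", {
  # large topography separation and deep ERD: CSP+LDA should saturate
  specs <- list(class_spec("REST"),
                class_spec("MI-GRASP", c(C3 = 1, CP3 = 0.3),
                           mu_erd_depth = 0.9, beta_erd_depth = 0.9))
  cfg <- quick_cfg(trials = 12, seed = 31, noise_scale = 3)
  cfg$class_specs <- stats::setNames(specs, c("REST", "MI-GRASP"))
  bank <- quick_bank(cfg)
  cv <- cross_validate(bank, extractor_spec("csp"), classifier_spec("LDA"),
                       n_folds = 4, n_repeats = 2, seed = 2)
  expect_equal(cv$mean, 1.0)
})

test_that("binary label permutation scores at chance", {
  cfg <- quick_cfg(trials = 30, sessions = 2, seed = 37)
  bank <- quick_bank(cfg)
  bank$labels <- with_seed(11, sample(bank$labels))
  for (b in names(bank$bands)) bank$bands[[b]]$labels <- bank$labels
  cv <- cross_validate(bank, extractor_spec("bp"), classifier_spec("LDA"),
                       n_folds = 10, n_repeats = 5, seed = 3)
  expect_gt(cv$mean, 0.40); expect_lt(cv$mean, 0.60)
})

test_that("the held-out fold never influences the fitted pipeline", {
  cfg <- quick_cfg(trials = 10, seed = 41)
  bank <- quick_bank(cfg)
  n <- n_trials(bank$bands[[1]])
  test_idx <- seq_len(5)
  train_idx <- setdiff(seq_len(n), test_idx)
  m_full <- ovo_train(bank, extractor_spec("csp"), classifier_spec("LDA"),
                      seed = 7, idx = train_idx)
  # physically delete the test trials and refit: identical pipeline
  bank_cut <- subset_bank(bank, train_idx)
  m_cut <- ovo_train(bank_cut, extractor_spec("csp"),
                     classifier_spec("LDA"), seed = 7)
  expect_equal(m_full$sub[[1]]$extractor$banks[[1]]$weights,
               m_cut$sub[[1]]$extractor$banks[[1]]$weights)
  expect_equal(m_full$sub[[1]]$model$fit$scaling,
               m_cut$sub[[1]]$model$fit$scaling)
})

test_that("best_of_nine runs all combinations under a shared fold plan", {
  cfg <- quick_cfg(trials = 10, seed = 43)
  bank <- quick_bank(cfg, all_bands())
  rep9 <- best_of_nine(bank, seed = 5, n_folds = 3, n_repeats = 2,
                       classifiers = list(classifier_spec("LDA"),
                                          classifier_spec("LOGREG")))
  expect_length(rep9$results, 6) # 3 extractors x 2 classifiers here
  expect_named(rep9$results,
               c("CSP+LDA", "CSP+LR", "FBCSP+LDA", "FBCSP+LR",
                 "BP+LDA", "BP+LR"))
  expect_true(rep9$best %in% names(rep9$results))
  expect_equal(rep9$mean, max(vapply(rep9$results, `[[`, 0, "mean")))
  expect_match(format_accuracy(rep9$mean, rep9$sd), "^\\d+\\.\\d±")
})

test_that("a strongly CSP-separable source makes CSP the best extractor", {
  wins <- 0L
  for (s in 1:5) {
    specs <- list(class_spec("REST"),
                  class_spec("MI-GRASP", c(C3 = 1),
                             mu_erd_depth = 0.85, beta_erd_depth = 0.85))
    cfg <- quick_cfg(trials = 10, seed = 100 + s)
    cfg$class_specs <- stats::setNames(specs, c("REST", "MI-GRASP"))
    bank <- quick_bank(cfg, all_bands())
    rep9 <- best_of_nine(bank, seed = s, n_folds = 3, n_repeats = 2,
                         extractors = list(extractor_spec("csp"),
                                           extractor_spec("bp")),
                         classifiers = list(classifier_spec("LDA")))
    if (startsWith(rep9$best, "CSP")) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})
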