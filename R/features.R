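#' Trial x feature matrix with provenance
#'
#' @param values numeric matrix, trials x features.
#' @param labels per-trial class labels.
#' @param feature_names character ledger, e.g. `"csp[7-30Hz]/f1"` or
#'   `"bp/C3"`.
#' @param extractor_id provenance tag, e.g. `"csp"`.
#' @return an object of class `mibci_features`.
#' @export
feature_matrix <- function(values, labels, feature_names, extractor_id) {
  values <- as.matrix(values)
  if (nrow(values) != length(labels))
    stop_mibci("validation_error", "feature rows must equal label count")
  if (ncol(values) != length(feature_names))
    stop_mibci("validation_error", "feature columns must equal name count")
  if (!all(is.finite(values)))
    stop_mibci("validation_error", "all feature values must be finite")
  colnames(values) <- feature_names
  structure(list(values = values, labels = as.character(labels),
                 feature_names = feature_names, extractor_id = extractor_id),
            class = "mibci_features")
}

#' @export
print.mibci_features <- function(x, ...) {
  cat(sprintf("<features '%s': %d trials x %d features>\n", x$extractor_id,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

# per-trial spatial covariance (channels x channels), trace-normalized so
# every trial contributes unit total band energy
trial_covariance <- function(S) {
  S <- S - rowMeans(S)
  C <- tcrossprod(S) / ncol(S)
  C / sum(diag(C))
}

#' Class-average spatial covariance
#'
#' Mean over all trials of a class of the trace-normalized per-trial
#' spatial covariance. Symmetric positive semi-definite with unit trace.
#'
#' @param epochs a `mibci_epochs`.
#' @param label class whose trials to average.
#' @return channels x channels covariance matrix.
#' @export
class_covariance <- function(epochs, label) {
  idx <- which(epochs$labels == label)
  if (!length(idx))
    stop_mibci("empty_class_error", "no trials with label '%s'", label)
  nc <- dim(epochs$data)[2]
  C <- matrix(0, nc, nc)
  for (i in idx) C <- C + trial_covariance(epochs$data[i, , ])
  C <- C / length(idx)
  dimnames(C) <- list(epochs$montage$channel_names,
                      epochs$montage$channel_names)
  (C + t(C)) / 2
}

#' Fit common spatial patterns for a class pair
#'
#' Solves the generalized eigenproblem `C_A w = lambda (C_A + C_B) w` on
#' the two class-average covariances (composite covariance regularized by
#' `eps * trace/N_c` on the diagonal, then whitened). Eigenvalues lambda in
#' `[0, 1]` give the fraction of composite variance explained by class A;
#' the returned bank holds the `n_pairs` filters with largest lambda
#' (maximal class-A variance, minimal class-B) followed by the `n_pairs`
#' with smallest lambda (the converse). Every filter satisfies
#' `w' (C_A + C_B) w = 1`. Filters are sign-fixed so the largest-magnitude
#' coefficient is positive; equal eigenvalues are ordered by the channel
#' index of that coefficient.
#'
#' @param epochs a `mibci_epochs` containing both classes.
#' @param labelA,labelB the two class labels (class A plays "Class 1").
#' @param n_pairs filters kept from each end of the spectrum (default 3,
#'   giving 6 filters).
#' @param reg_eps diagonal regularization strength (default 1e-9).
#' @param band `(lo, hi)` Hz provenance recorded on the bank (default the
#'   epochs are assumed 7-30 Hz filtered).
#' @return an object of class `mibci_csp_bank` with fields `weights`
#'   (channels x 2*n_pairs), `eigenvalues`, `patterns` (composite
#'   covariance times weights, column-normalized), `band`, `class_pair`,
#'   `n_pairs`.
#' @export
fit_csp <- function(epochs, labelA, labelB, n_pairs = 3, reg_eps = 1e-9,
                    band = c(7, 30)) {
  C_A <- class_covariance(epochs, labelA)
  C_B <- class_covariance(epochs, labelB)
  nc <- nrow(C_A)
  if (2 * n_pairs > nc)
    stop_mibci("config_error", "n_pairs too large for %d channels", nc)
  Cc_raw <- C_A + C_B
  Cc <- Cc_raw + diag(reg_eps * sum(diag(Cc_raw)) / nc, nc)
  eg <- eigen(Cc, symmetric = TRUE)
  if (min(eg$values) <= 0)
    stop_mibci("numerical_error", paste(
      "composite covariance is singular after regularization;",
      "check for duplicated or constant channels"))
  Wh <- diag(1 / sqrt(eg$values)) %*% t(eg$vectors) # whitener
  Sa <- Wh %*% C_A %*% t(Wh)
  e2 <- eigen((Sa + t(Sa)) / 2, symmetric = TRUE)
  lambda <- pmin(pmax(e2$values, 0), 1)
  W <- t(Wh) %*% e2$vectors # all nc filters, w' Cc w = 1
  # enforce the unit composite-variance constraint exactly (against the
  # unregularized composite; the regularizer only stabilizes the solve)
  W <- sweep(W, 2, sqrt(colSums(W * (Cc_raw %*% W))), "/")
  # sign convention + deterministic tie-break
  peak <- integer(nc)
  for (j in seq_len(nc)) {
    p <- which.max(abs(W[, j]))
    if (W[p, j] < 0) W[, j] <- -W[, j]
    peak[j] <- p
  }
  ord <- order(-lambda, peak)
  lambda <- lambda[ord]; W <- W[, ord, drop = FALSE]; peak <- peak[ord]
  sel <- c(seq_len(n_pairs), seq(nc - n_pairs + 1, nc))
  W <- W[, sel, drop = FALSE]
  lambda <- lambda[sel]
  pat <- Cc %*% W
  pat <- sweep(pat, 2, sqrt(colSums(pat^2)), "/")
  rownames(W) <- rownames(pat) <- epochs$montage$channel_names
  structure(list(weights = W, eigenvalues = lambda, patterns = pat,
                 band = as.numeric(band),
                 class_pair = c(labelA, labelB), n_pairs = n_pairs),
            class = "mibci_csp_bank")
}

#' @export
print.mibci_csp_bank <- function(x, ...) {
  cat(sprintf("<CSP bank %s vs %s, band %g-%g Hz, %d filters>\n",
              x$class_pair[1], x$class_pair[2], x$band[1], x$band[2],
              ncol(x$weights)))
  cat(" eigenvalues:", paste(sprintf("%.3f", x$eigenvalues), collapse = " "),
      "\n")
  invisible(x)
}

# guarded log-variance used by all extractors (degenerate flat signals
# must not produce -Inf)
log_var <- function(v) {
  if (any(v < 1e-12)) {
    warning("variance floored at 1e-12 uV^2 before log", call. = FALSE)
    v <- pmax(v, 1e-12)
  }
  log(v)
}

#' CSP log-variance features
#'
#' Feature `j` of trial `i` is `log(var(w_j' S_i))` for the bank's `j`-th
#' spatial filter.
#'
#' @param epochs a `mibci_epochs` (same montage as the bank).
#' @param bank a [fit_csp()] bank.
#' @return a [feature_matrix()] with `2 * n_pairs` columns.
#' @export
csp_features <- function(epochs, bank) {
  if (nrow(bank$weights) != dim(epochs$data)[2])
    stop_mibci("validation_error", "bank channel count does not match epochs")
  M <- n_trials(epochs)
  nf <- ncol(bank$weights)
  vals <- matrix(0, M, nf)
  for (i in seq_len(M)) {
    proj <- crossprod(bank$weights, epochs$data[i, , ]) # filters x samples
    vals[i, ] <- log_var(apply(proj, 1, var))
  }
  tag <- sprintf("csp[%g-%gHz]", bank$band[1], bank$band[2])
  feature_matrix(vals, epochs$labels,
                 sprintf("%s/f%d", tag, seq_len(nf)), "csp")
}

#' Log band-power features
#'
#' One feature per channel: the log-variance of that channel's (already
#' band-filtered) samples within the epoch.
#'
#' @param epochs a `mibci_epochs`, band-filtered upstream (7-30 Hz in the
#'   default pipeline).
#' @return a [feature_matrix()] with one column per channel.
#' @export
bp_features <- function(epochs) {
  M <- n_trials(epochs)
  nc <- dim(epochs$data)[2]
  vals <- matrix(0, M, nc)
  for (i in seq_len(M))
    vals[i, ] <- log_var(apply(epochs$data[i, , ], 1, var))
  feature_matrix(vals, epochs$labels,
                 paste0("bp/", epochs$montage$channel_names), "bp")
}

#' Build per-band epoch sets from a preprocessed recording
#'
#' For each requested band: zero-phase band-pass filter the continuous
#' recording, then cut cue-locked epochs. All bands share trials, labels,
#' and window; the result feeds the extractor machinery and filter-bank
#' CSP.
#'
#' @param rec a preprocessed `mibci_recording` (downsampled, broadband
#'   filtered).
#' @param bands list of `(lo, hi)` Hz bands.
#' @param window epoch window `(start_s, end_s)` relative to cue (default
#'   1-3 s).
#' @return an object of class `mibci_epoch_bank`: a named list of
#'   `mibci_epochs` (names like `"7-30"`) plus shared `labels`.
#' @export
band_epochs <- function(rec, bands, window = c(1, 3)) {
  if (!length(bands)) stop_mibci("config_error", "empty band list")
  if (is.numeric(bands)) bands <- list(bands)
  out <- list()
  for (b in bands) {
    key <- band_key(b)
    if (!is.null(out[[key]])) next
    out[[key]] <- epoch(bandpass(rec, b), window)
  }
  structure(list(bands = out, labels = out[[1]]$labels,
                 montage = rec$montage, window = window),
            class = "mibci_epoch_bank")
}

band_key <- function(b) sprintf("%g-%g", b[1], b[2])

#' Subset every band of an epoch bank by trial index
#' @param bank a `mibci_epoch_bank`.
#' @param idx trial index.
#' @return a `mibci_epoch_bank`.
#' @export
subset_bank <- function(bank, idx) {
  structure(list(bands = lapply(bank$bands, subset_epochs, idx = idx),
                 labels = bank$labels[idx], montage = bank$montage,
                 window = bank$window),
            class = "mibci_epoch_bank")
}

#' Fit filter-bank CSP for a class pair
#'
#' Per band: band-pass filter the continuous recording, epoch, and fit CSP;
#' one spatial filter bank per band, each with band provenance.
#'
#' @param rec a preprocessed `mibci_recording` spanning all events, or a
#'   ready-made [band_epochs()] bank covering the requested bands.
#' @param bands list of `(lo, hi)` Hz bands (default the three-band bank
#'   7-15, 15-25, 25-30 Hz).
#' @param labelA,labelB the class pair.
#' @param n_pairs filters kept per spectral end per band (default 3).
#' @param window epoch window (default 1-3 s).
#' @return list of `mibci_csp_bank`, one per band.
#' @export
fit_fbcsp <- function(rec, bands = list(c(7, 15), c(15, 25), c(25, 30)),
                      labelA, labelB, n_pairs = 3, window = c(1, 3)) {
  if (!length(bands)) stop_mibci("config_error", "empty band list")
  eb <- if (inherits(rec, "mibci_epoch_bank")) rec
        else band_epochs(rec, bands, window)
  lapply(bands, function(b)
    fit_csp(eb$bands[[band_key(b)]], labelA, labelB, n_pairs, band = b))
}

#' Filter-bank CSP log-variance features
#'
#' Concatenates [csp_features()] across the per-band banks of
#' [fit_fbcsp()].
#'
#' @param eb a `mibci_epoch_bank` covering the banks' bands.
#' @param banks list of `mibci_csp_bank` from [fit_fbcsp()].
#' @return a [feature_matrix()] with `2 * n_pairs * length(banks)` columns.
#' @export
fbcsp_features <- function(eb, banks) {
  parts <- lapply(banks, function(bk)
    csp_features(eb$bands[[band_key(bk$band)]], bk))
  feature_matrix(do.call(cbind, lapply(parts, function(p) p$values)),
                 eb$labels,
                 unlist(lapply(parts, function(p) p$feature_names)),
                 "fbcsp")
}

#' Feature-extractor specification
#'
#' Declares one of the three extractors and the band(s) it consumes:
#' `"csp"` (one 7-30 Hz band, 6 features), `"fbcsp"` (7-15, 15-25,
#' 25-30 Hz, 18 features), or `"bp"` (log band power per channel on the
#' 7-30 Hz band, one feature per channel).
#'
#' @param kind `"csp"`, `"fbcsp"`, or `"bp"`.
#' @param bands band list; defaults depend on `kind` as above.
#' @param n_pairs CSP filter pairs per band (default 3).
#' @return an object of class `mibci_extractor_spec`.
#' @export
extractor_spec <- function(kind = c("csp", "fbcsp", "bp"), bands = NULL,
                           n_pairs = 3) {
  kind <- match.arg(kind)
  if (is.null(bands))
    bands <- switch(kind,
                    csp = list(c(7, 30)),
                    fbcsp = list(c(7, 15), c(15, 25), c(25, 30)),
                    bp = list(c(7, 30)))
  if (is.numeric(bands)) bands <- list(bands)
  if (!length(bands)) stop_mibci("config_error", "empty band list")
  structure(list(kind = kind, bands = bands, n_pairs = n_pairs),
            class = "mibci_extractor_spec")
}

# all bands needed by a set of extractor specs
extractor_bands <- function(specs) {
  out <- list()
  for (sp in specs) for (b in sp$bands) out[[band_key(b)]] <- b
  unname(out)
}

# fit an extractor on (a subset of) an epoch bank for one class pair;
# returns an object whose features can be computed for any trials
fit_extractor <- function(bank, spec, labelA, labelB, idx = NULL) {
  train <- if (is.null(idx)) bank else subset_bank(bank, idx)
  banks <- switch(spec$kind,
    bp = NULL,
    csp = list(fit_csp(train$bands[[band_key(spec$bands[[1]])]],
                       labelA, labelB, spec$n_pairs,
                       band = spec$bands[[1]])),
    fbcsp = lapply(spec$bands, function(b)
      fit_csp(train$bands[[band_key(b)]], labelA, labelB, spec$n_pairs,
              band = b)))
  structure(list(spec = spec, banks = banks,
                 class_pair = c(labelA, labelB),
                 montage = train$montage$channel_names),
            class = "mibci_extractor_fit")
}

# features for the given trials of an epoch bank under a fitted extractor
extract_features <- function(fit, bank, idx = NULL) {
  eb <- if (is.null(idx)) bank else subset_bank(bank, idx)
  switch(fit$spec$kind,
         bp = bp_features(eb$bands[[band_key(fit$spec$bands[[1]])]]),
         csp = csp_features(eb$bands[[band_key(fit$spec$bands[[1]])]],
                            fit$banks[[1]]),
         fbcsp = fbcsp_features(eb, fit$banks))
}
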