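## zero-phase band filtering of epoched trials via a frequency-domain mask
## with raised-cosine transitions; returns trials x channels x samples
band_mask_filter <- function(data, sampling_rate, band, transition = 2) {
  d <- dim(data)
  n <- d[3]
  freqs <- (seq_len(n) - 1L) / n * sampling_rate
  freqs[freqs > sampling_rate / 2] <- freqs[freqs > sampling_rate / 2] - sampling_rate
  af <- abs(freqs)
  gain <- numeric(n)
  gain[af >= band[1] & af <= band[2]] <- 1
  lo_t <- af > band[1] - transition & af < band[1]
  gain[lo_t] <- (1 + cos(pi * (band[1] - af[lo_t]) / transition)) / 2
  hi_t <- af > band[2] & af < band[2] + transition
  gain[hi_t] <- (1 + cos(pi * (af[hi_t] - band[2]) / transition)) / 2
  out <- data
  for (ch in seq_len(d[2])) {
    x <- t(matrix(data[, ch, ], d[1], n))
    out[, ch, ] <- t(Re(mvfft(mvfft(x) * gain, inverse = TRUE)) / n)
  }
  out
}

## per-trial spatial covariances normalized by trace, averaged over trials
mean_normalized_cov <- function(trials) {
  d <- dim(trials)
  acc <- matrix(0, d[2], d[2])
  for (k in seq_len(d[1])) {
    x <- matrix(trials[k, , ], d[2], d[3])
    C <- tcrossprod(x) / d[3]
    acc <- acc + C / sum(diag(C))
  }
  acc / d[1]
}

#' Fit common spatial pattern (CSP) filters
#'
#' Computes the spatial filters that extremize the variance ratio between two
#' classes of multichannel trials: eigenvectors of the whitened class-a
#' covariance, equivalently the generalized eigenvectors of the two average
#' trace-normalized class covariances. Filters are returned sorted by
#' decreasing class-a variance fraction, so the first rows maximize class-a
#' variance and the last rows maximize class-b variance.
#'
#' @param trials_a,trials_b Numeric 3-D arrays, trials x channels x samples,
#'   one per class.
#' @param reg Diagonal-loading fraction applied when the composite covariance
#'   is near-singular (default `1e-8`, scaled by the mean diagonal).
#' @return An object of class `csp_filters`: `filters` (n_filters x
#'   n_channels matrix), `eigenvalues` (class-a variance fractions, sorted
#'   decreasing) and the class covariances.
#' @export
csp_fit <- function(trials_a, trials_b, reg = 1e-8) {
  stopifnot(length(dim(trials_a)) == 3L, length(dim(trials_b)) == 3L,
            dim(trials_a)[2] == dim(trials_b)[2])
  if (dim(trials_a)[1] < 2L || dim(trials_b)[1] < 2L) {
    abort("CSP requires at least 2 trials per class.")
  }
  Ca <- mean_normalized_cov(trials_a)
  Cb <- mean_normalized_cov(trials_b)
  Cc <- Ca + Cb
  e <- eigen(Cc, symmetric = TRUE)
  tol <- max(e$values) * 1e-10
  if (min(e$values) < tol) {
    inform("rank-deficient composite covariance; applying diagonal loading.")
    Cc <- Cc + diag(reg * mean(diag(Cc)), nrow(Cc))
    e <- eigen(Cc, symmetric = TRUE)
  }
  P <- diag(1 / sqrt(e$values)) %*% t(e$vectors)
  S <- P %*% Ca %*% t(P)
  eb <- eigen((S + t(S)) / 2, symmetric = TRUE)
  filters <- t(eb$vectors) %*% P
  structure(
    list(filters = filters, eigenvalues = eb$values,
         cov_a = Ca, cov_b = Cb),
    class = "csp_filters"
  )
}

#' @export
print.csp_filters <- function(x, ...) {
  cat(sprintf("<csp_filters> %d filters over %d channels; eigenvalues %s\n",
              nrow(x$filters), ncol(x$filters),
              paste(sprintf("%.3f", x$eigenvalues), collapse = ", ")))
  invisible(x)
}

#' Log-variance CSP features
#'
#' Projects trials through fitted CSP filters and returns the log of the
#' variance of each projected signal, the canonical band-power feature.
#' Zero-variance projections are floored at a tiny positive constant.
#'
#' @param filters A [csp_fit()] result.
#' @param trials Numeric 3-D array, trials x channels x samples.
#' @return Numeric matrix, trials x n_filters.
#' @export
csp_features <- function(filters, trials) {
  stopifnot(inherits(filters, "csp_filters"), length(dim(trials)) == 3L)
  d <- dim(trials)
  W <- filters$filters
  out <- matrix(0, d[1], nrow(W))
  for (k in seq_len(d[1])) {
    proj <- W %*% matrix(trials[k, , ], d[2], d[3])
    v <- apply(proj, 1L, var)
    v[v <= 0] <- 1e-12
    out[k, ] <- log(v)
  }
  out
}

## seeded stratified fold assignment; every fold receives a near-equal share
## of each class
stratified_folds <- function(labels, folds, seed) {
  fold_id <- integer(length(labels))
  withr::with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold_id
}

#' Cross-validated motor-attempt vs rest classification accuracy
#'
#' Stratified k-fold cross-validation of the full decoding chain on a subset
#' of channels: per fold, CSP filters are fitted in the alpha and beta bands
#' on the training trials only, log-variance features from both bands are
#' concatenated (feature dimension = 2 x number of selected channels), and a
#' linear soft-margin support-vector classifier (cost 1) is trained and
#' scored on the held-out fold. With the default 5 folds each fold uses 80%
#' of the trials for training and 20% for testing.
#'
#' @param epochs An [epoch_set()] holding both classes.
#' @param channels Channel labels to analyse.
#' @param seed Integer seed for the fold assignment.
#' @param folds Number of folds (default 5).
#' @param bands Named list of band edges (Hz) for per-band CSP.
#' @param window Time window (s) of each trial entering the features; the
#'   default `c(4, 7)` is the movement state.
#' @param classes Length-2 character, the two trial classes.
#' @return An object of class `cv_result` with per-fold accuracies, their
#'   mean, per-class trial counts and the seed.
#' @export
crossval_accuracy <- function(epochs, channels, seed = 1L, folds = 5L,
                              bands = list(alpha = c(8, 13),
                                           beta = c(13, 30)),
                              window = c(4, 7),
                              classes = c("attempt", "blank")) {
  stopifnot(inherits(epochs, "epoch_set"))
  ch_idx <- match(channels, epochs$channel_labels)
  if (anyNA(ch_idx)) {
    abort(sprintf("Unknown channel(s): %s",
                  paste(channels[is.na(ch_idx)], collapse = ", ")))
  }
  labels <- epochs$labels
  if (!all(classes %in% labels)) {
    abort("both classes must be present in the epochs.")
  }
  use <- labels %in% classes
  if (any(table(labels[use]) < folds)) {
    abort(sprintf(
      "class missing from a training or test split: each class needs at least %d trials for %d-fold cross-validation.",
      folds, folds
    ))
  }
  fs <- epochs$sampling_rate
  widx <- window_samples(window, fs, dim(epochs$data)[3])
  sub <- epochs$data[use, ch_idx, widx, drop = FALSE]
  labels <- labels[use]
  per_band <- lapply(bands, function(b) band_mask_filter(sub, fs, b))

  fold_id <- stratified_folds(labels, folds, seed)
  fold_acc <- numeric(folds)
  for (f in seq_len(folds)) {
    train <- fold_id != f
    test <- !train
    if (length(unique(labels[train])) < 2L) {
      abort(sprintf("class missing from the training split of fold %d.", f))
    }
    feats_train <- feats_test <- NULL
    for (b in per_band) {
      filt <- csp_fit(b[train & labels == classes[1], , , drop = FALSE],
                      b[train & labels == classes[2], , , drop = FALSE])
      feats_train <- cbind(feats_train,
                           csp_features(filt, b[train, , , drop = FALSE]))
      feats_test <- cbind(feats_test,
                          csp_features(filt, b[test, , , drop = FALSE]))
    }
    fit <- e1071::svm(feats_train, factor(labels[train], levels = classes),
                      kernel = "linear", cost = 1, scale = TRUE)
    pred <- stats::predict(fit, feats_test)
    fold_acc[f] <- mean(pred == labels[test])
  }
  structure(
    list(
      fold_accuracies = fold_acc,
      mean_accuracy = mean(fold_acc),
      n_trials_per_class = table(labels),
      channels = channels,
      folds = folds,
      seed = seed
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> mean accuracy %.3f over %d folds (%s) on channels %s\n",
    x$mean_accuracy, x$folds,
    paste(sprintf("%.2f", x$fold_accuracies), collapse = ", "),
    paste(x$channels, collapse = ", ")
  ))
  invisible(x)
}

#' Tidy per-fold cross-validation accuracies
#'
#' @param x A [crossval_accuracy()] result.
#' @param ... Unused.
#' @return A tibble with columns `fold` and `accuracy`.
#' @exportS3Method generics::tidy
#' @export
tidy.cv_result <- function(x, ...) {
  tibble(fold = seq_along(x$fold_accuracies), accuracy = x$fold_accuracies)
}

#' One-row summary of a cross-validation result
#'
#' @param x A [crossval_accuracy()] result.
#' @param ... Unused.
#' @return A one-row tibble with the mean accuracy, fold count, trial count
#'   and seed.
#' @exportS3Method generics::glance
#' @export
glance.cv_result <- function(x, ...) {
  tibble(
    mean_accuracy = x$mean_accuracy,
    folds = x$folds,
    n_trials = sum(x$n_trials_per_class),
    seed = x$seed
  )
}
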