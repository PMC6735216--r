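#' Construct an epoched trial set
#'
#' @param data Numeric 3-D array, trials x channels x samples, in microvolts.
#' @param labels Character vector of per-trial class labels
#'   (`"attempt"`/`"blank"`).
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_labels Channel names, one per second array dimension.
#' @param kept_mask Logical vector over the original trials indicating which
#'   survived rejection.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels, sampling_rate, channel_labels,
                      kept_mask = rep(TRUE, length(labels))) {
  stopifnot(length(dim(data)) == 3L)
  if (dim(data)[1] != length(labels)) {
    abort("one label per trial is required.")
  }
  if (dim(data)[2] != length(channel_labels)) {
    abort("one channel label per channel is required.")
  }
  structure(
    list(
      data = data, labels = as.character(labels),
      sampling_rate = sampling_rate,
      channel_labels = as.character(channel_labels),
      kept_mask = kept_mask
    ),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d trials (%s) x %d channels x %d samples @ %g Hz\n",
    d[1], paste(sprintf("%d %s", table(x$labels), names(table(x$labels))),
                collapse = ", "),
    d[2], d[3], x$sampling_rate
  ))
  invisible(x)
}

#' Number of trials in an epoch set
#' @param epochs An `epoch_set`.
#' @return Integer trial count.
#' @export
n_trials <- function(epochs) dim(epochs$data)[1]

#' Remove the EOG channel from a session
#'
#' Drops the electro-oculogram channel (recorded at montage position 32)
#' before any scalp analysis, leaving the 63 analysis channels in their
#' original order.
#'
#' @param raw A [raw_session()].
#' @param eog_index 1-based index of the EOG channel; defaults to the
#'   session montage's EOG position, or 32.
#' @return A [raw_session()] without the EOG channel.
#' @export
drop_eog <- function(raw, eog_index = NULL) {
  stopifnot(inherits(raw, "raw_session"))
  eog_index <- eog_index %||% raw$montage$eog_index %||% 32L
  n_ch <- nrow(raw$signal)
  if (eog_index < 1L || eog_index > n_ch) {
    abort(sprintf("EOG index %d out of range (session has %d channels).",
                  eog_index, n_ch))
  }
  if (!is.null(raw$montage) &&
      !identical(raw$channel_labels, raw$montage$labels)) {
    ## already subset once; a second removal would hit a scalp channel
    abort("EOG channel already absent from this session.")
  }
  keep <- setdiff(seq_len(n_ch), eog_index)
  out <- raw
  out$signal <- raw$signal[keep, , drop = FALSE]
  out$channel_labels <- raw$channel_labels[keep]
  out
}

#' Re-reference to the common average
#'
#' Subtracts, at every sample, the instantaneous mean across channels, so the
#' average-referenced signal sums to zero over channels.
#'
#' @param raw A [raw_session()].
#' @return The re-referenced [raw_session()].
#' @export
average_reference <- function(raw) {
  stopifnot(inherits(raw, "raw_session"))
  if (nrow(raw$signal) < 2L) {
    abort("average reference requires at least 2 channels.")
  }
  out <- raw
  out$signal <- sweep(raw$signal, 2L, colMeans(raw$signal))
  out
}

## smallest 2/3/5-smooth FFT length >= n
next_fast_len <- function(n) nextn(n, c(2, 3, 5))

## zero-phase linear-phase FIR filtering via FFT convolution with exact
## group-delay compensation (filter order must be even); channels are packed
## in pairs into the real and imaginary parts of one complex FFT, which is
## exact for a real-valued impulse response
fir_filtfft <- function(signal, h) {
  ntap <- length(h)
  delay <- (ntap - 1L) / 2L
  stopifnot(delay == floor(delay))
  nc <- nrow(signal)
  ns <- ncol(signal)
  nfft <- next_fast_len(ns + ntap - 1L)
  H <- fft(c(h, numeric(nfft - ntap)))
  n_pair <- ceiling(nc / 2)
  x <- matrix(0i, nfft, n_pair)
  for (p in seq_len(n_pair)) {
    i1 <- 2L * p - 1L
    im <- if (2L * p <= nc) signal[2L * p, ] else numeric(ns)
    x[seq_len(ns), p] <- complex(real = signal[i1, ], imaginary = im)
  }
  y <- mvfft(mvfft(x) * H, inverse = TRUE) / nfft
  y <- y[(delay + 1L):(delay + ns), , drop = FALSE]
  out <- matrix(0, nc, ns)
  for (p in seq_len(n_pair)) {
    out[2L * p - 1L, ] <- Re(y[, p])
    if (2L * p <= nc) out[2L * p, ] <- Im(y[, p])
  }
  out
}

#' Zero-phase FIR band-pass filter
#'
#' Windowed-sinc (Hamming) finite-impulse-response band-pass applied with
#' exact linear-phase delay compensation, so the output is zero-phase. The
#' default 1-40 Hz band with a 1 Hz transition at the low edge attenuates
#' 0.5 Hz and 60 Hz by well over 20 dB while leaving in-band sinusoids
#' untouched.
#'
#' @param raw A [raw_session()].
#' @param low,high Band edges in Hz.
#' @param order FIR order (number of taps minus one); chosen from the
#'   transition width when `NULL`.
#' @return The filtered [raw_session()].
#' @export
bandpass_fir <- function(raw, low = 1, high = 40, order = NULL) {
  stopifnot(inherits(raw, "raw_session"))
  fs <- raw$sampling_rate
  if (!(low > 0 && low < high && high < fs / 2)) {
    abort("invalid band: need 0 < low < high < sampling_rate/2.")
  }
  ## Hamming transition width ~ 3.3/N normalized; target 1 Hz at the low edge
  order <- order %||% (2L * ceiling(3.3 * fs / 1 / 2))
  h <- signal::fir1(order, c(low, high) / (fs / 2), type = "pass")
  out <- raw
  out$signal <- fir_filtfft(raw$signal, as.numeric(h))
  dimnames(out$signal) <- dimnames(raw$signal)
  out
}

#' Cut a continuous session into fixed-length trials
#'
#' One epoch is extracted per `trial_start` event mark. A final trial whose
#' window would run past the end of the recording is dropped with a warning.
#' At 500 Hz a 7 s epoch of 63 channels holds 63 x 3500 = 220500 data points.
#'
#' @param raw A [raw_session()].
#' @param trial_length Epoch duration in seconds (default 7).
#' @return An [epoch_set()] with one trial per surviving trial mark.
#' @export
epoch_trials <- function(raw, trial_length = 7) {
  stopifnot(inherits(raw, "raw_session"))
  fs <- raw$sampling_rate
  n_samp <- as.integer(round(trial_length * fs))
  starts <- raw$events[raw$events$code == "trial_start", ]
  n_ch <- nrow(raw$signal)
  if (nrow(starts) == 0L) {
    return(epoch_set(array(numeric(0), c(0L, n_ch, n_samp)),
                     character(0), fs, raw$channel_labels, logical(0)))
  }
  fits <- starts$sample + n_samp - 1L <= ncol(raw$signal)
  if (any(!fits)) {
    warn(sprintf("dropping %d truncated trial(s) at the end of the session.",
                 sum(!fits)))
    starts <- starts[fits, ]
  }
  data <- array(0, c(nrow(starts), n_ch, n_samp))
  for (k in seq_len(nrow(starts))) {
    i0 <- starts$sample[k]
    data[k, , ] <- raw$signal[, i0:(i0 + n_samp - 1L)]
  }
  epoch_set(data, starts$kind, fs, raw$channel_labels)
}

#' Subtract the per-trial baseline
#'
#' For every trial and channel, subtracts the mean over the baseline window
#' (default the first second of the trial, during the pre-cue fixation).
#'
#' @param epochs An [epoch_set()].
#' @param baseline Length-2 numeric, baseline window in seconds, half-open
#'   `[start, end)` relative to trial start.
#' @return The baseline-corrected [epoch_set()].
#' @export
remove_baseline <- function(epochs, baseline = c(0, 1)) {
  stopifnot(inherits(epochs, "epoch_set"))
  fs <- epochs$sampling_rate
  idx <- window_samples(baseline, fs, dim(epochs$data)[3])
  if (length(idx) == 0L) abort("baseline window contains no samples.")
  means <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  out <- epochs
  out$data <- epochs$data - as.vector(means) # recycles over the sample dim
  out
}

## sample indices of the half-open window [start, end) seconds, 0-based time
window_samples <- function(window, sampling_rate, n_samp) {
  i0 <- floor(window[1] * sampling_rate) + 1L
  i1 <- ceiling(window[2] * sampling_rate)
  if (i0 < 1L || i1 > n_samp || i0 > i1) {
    abort(sprintf("window [%g, %g) falls outside the epoch.",
                  window[1], window[2]))
  }
  seq.int(i0, i1)
}

#' Downsample epoched trials
#'
#' Keeps every `factor`-th sample of each trial. Intended for use after the
#' 1-40 Hz band-pass, which acts as the anti-alias filter as long as the
#' reduced Nyquist frequency stays above the band edge.
#'
#' @param epochs An [epoch_set()].
#' @param factor Integer subsampling factor.
#' @return The downsampled [epoch_set()] with its `sampling_rate` updated.
#' @export
downsample_epochs <- function(epochs, factor) {
  stopifnot(inherits(epochs, "epoch_set"))
  factor <- as.integer(factor)
  if (factor < 1L) abort("`factor` must be a positive integer.")
  if (factor == 1L) return(epochs)
  keep <- seq.int(1L, dim(epochs$data)[3], by = factor)
  out <- epochs
  out$data <- epochs$data[, , keep, drop = FALSE]
  out$sampling_rate <- epochs$sampling_rate / factor
  out
}

#' Reject trials containing large-amplitude artifacts
#'
#' Removes every trial in which any sample of any channel exceeds the peak
#' threshold in absolute value. This deterministic amplitude criterion stands
#' in for interactive artifact screening.
#'
#' @param epochs An [epoch_set()].
#' @param peak_threshold_uV Rejection threshold in microvolts (default 100).
#' @return The cleaned [epoch_set()], with `kept_mask` updated.
#' @export
reject_artifact_trials <- function(epochs, peak_threshold_uV = 100) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (peak_threshold_uV <= 0) abort("`peak_threshold_uV` must be positive.")
  peaks <- apply(abs(epochs$data), 1L, max)
  keep <- peaks <= peak_threshold_uV
  if (!any(keep)) {
    abort(paste0(
      "all trials exceed the ", peak_threshold_uV,
      " uV peak threshold; review the threshold or the recording."
    ))
  }
  out <- epochs
  out$data <- epochs$data[keep, , , drop = FALSE]
  out$labels <- epochs$labels[keep]
  prev <- epochs$kept_mask
  prev[which(prev)[!keep]] <- FALSE
  out$kept_mask <- prev
  out
}

#' Standard preprocessing chain for a raw session
#'
#' Applies, in order: EOG removal, common-average re-referencing, zero-phase
#' FIR band-pass, epoching on the trial marks, baseline removal and
#' amplitude-threshold trial rejection.
#'
#' @param raw A [raw_session()].
#' @param low,high Band-pass edges in Hz.
#' @param trial_length Epoch duration in seconds.
#' @param baseline Baseline window in seconds.
#' @param reject_uV Peak rejection threshold in microvolts; `Inf` disables
#'   rejection.
#' @param channels Optional channel subset carried past the average
#'   reference (which always uses all 63 scalp channels); `NULL` keeps every
#'   channel.
#' @return An [epoch_set()] ready for spectral analysis.
#' @export
preprocess_session <- function(raw, low = 1, high = 40, trial_length = 7,
                               baseline = c(0, 1), reject_uV = 100,
                               channels = NULL) {
  out <- raw |>
    drop_eog() |>
    average_reference()
  if (!is.null(channels)) {
    idx <- match(channels, out$channel_labels)
    if (anyNA(idx)) {
      abort(sprintf("Unknown channel(s): %s",
                    paste(channels[is.na(idx)], collapse = ", ")))
    }
    out$signal <- out$signal[idx, , drop = FALSE]
    out$channel_labels <- out$channel_labels[idx]
  }
  out |>
    bandpass_fir(low = low, high = high) |>
    epoch_trials(trial_length = trial_length) |>
    remove_baseline(baseline = baseline) |>
    reject_artifact_trials(peak_threshold_uV = reject_uV)
}
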