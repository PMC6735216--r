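#' Construct a raw continuous EEG session
#'
#' Low-level constructor for the in-memory container used by the whole
#' pipeline: a channels-by-samples matrix in microvolts plus event marks.
#' Most users will obtain sessions from [synthesize_session()] or
#' [read_session()] rather than calling this directly.
#'
#' @param signal Numeric matrix, channels x samples, in microvolts.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_labels Character vector of channel names, one per row of
#'   `signal`.
#' @param events A data frame with columns `sample` (1-based sample index),
#'   `code` (`"trial_start"` or `"cue"`) and `kind` (`"attempt"` or
#'   `"blank"`).
#' @param montage Optional [standard_montage()] object retained for
#'   bookkeeping.
#' @return An object of class `raw_session`.
#' @export
raw_session <- function(signal, sampling_rate, channel_labels,
                        events = empty_events(), montage = NULL) {
  signal <- as.matrix(signal)
  if (!is.numeric(signal)) abort("`signal` must be a numeric matrix.")
  channel_labels <- as.character(channel_labels)
  if (nrow(signal) != length(channel_labels)) {
    abort(sprintf(
      "header/payload mismatch: %d channel labels but %d signal rows.",
      length(channel_labels), nrow(signal)
    ))
  }
  if (anyDuplicated(channel_labels)) {
    abort("channel labels must be unique.")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    abort("`sampling_rate` must be a single positive number.")
  }
  events <- as_tibble(events)
  required <- c("sample", "code", "kind")
  if (!all(required %in% names(events))) {
    abort("`events` must have columns sample, code, kind.")
  }
  if (nrow(events) > 0) {
    if (any(events$sample < 1L) || any(events$sample > ncol(signal))) {
      abort("event sample indices must lie within the signal.")
    }
    if (is.unsorted(events$sample)) {
      abort("event sample indices must be nondecreasing.")
    }
  }
  rownames(signal) <- channel_labels
  structure(
    list(
      signal = signal,
      sampling_rate = sampling_rate,
      channel_labels = channel_labels,
      events = events,
      montage = montage
    ),
    class = "raw_session"
  )
}

empty_events <- function() {
  tibble(sample = integer(), code = character(), kind = character())
}

#' @export
print.raw_session <- function(x, ...) {
  dur <- ncol(x$signal) / x$sampling_rate
  n_trial <- sum(x$events$code == "trial_start")
  cat(sprintf(
    "<raw_session> %d channels x %d samples (%.1f s @ %g Hz), %d trial marks\n",
    nrow(x$signal), ncol(x$signal), dur, x$sampling_rate, n_trial
  ))
  invisible(x)
}

#' Tidy a raw session into a long tibble
#'
#' @param x A `raw_session`.
#' @param channels Optional subset of channel labels to extract.
#' @param ... Unused.
#' @return A tibble with columns `channel`, `time` (s) and `value` (uV).
#' @exportS3Method generics::tidy
#' @export
tidy.raw_session <- function(x, channels = NULL, ...) {
  channels <- channels %||% x$channel_labels
  idx <- match(channels, x$channel_labels)
  if (anyNA(idx)) {
    abort(sprintf("Unknown channel(s): %s",
                  paste(channels[is.na(idx)], collapse = ", ")))
  }
  times <- (seq_len(ncol(x$signal)) - 1L) / x$sampling_rate
  purrr::map_dfr(idx, function(i) {
    tibble(channel = x$channel_labels[i], time = times, value = x$signal[i, ])
  })
}
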