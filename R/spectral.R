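#' Frequency-band specification
#'
#' The two sensorimotor-rhythm bands used throughout: alpha 8-13 Hz and beta
#' 13-30 Hz, analysed on a 0.5 Hz frequency grid inclusive of both edges.
#'
#' @param low,high Band edges in Hz.
#' @param step Frequency grid step in Hz (default 0.5).
#' @param name Band name.
#' @return An object of class `band_spec` with a `freqs` grid.
#' @examples
#' alpha_band()
#' beta_band()$freqs
#' @export
band_spec <- function(low, high, step = 0.5, name = NULL) {
  if (!(low < high) || step <= 0) {
    abort("invalid band: need low < high and step > 0.")
  }
  k <- (high - low) / step
  if (abs(k - round(k)) > 1e-8) {
    abort("(high - low) must be an integer multiple of `step`.")
  }
  structure(
    list(low = low, high = high, step = step,
         name = name %||% sprintf("%g-%g Hz", low, high),
         freqs = seq(low, high, by = step)),
    class = "band_spec"
  )
}

#' @rdname band_spec
#' @export
alpha_band <- function(step = 0.5) band_spec(8, 13, step, name = "alpha")

#' @rdname band_spec
#' @export
beta_band <- function(step = 0.5) band_spec(13, 30, step, name = "beta")

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> %s: %g-%g Hz in steps of %g\n",
              x$name, x$low, x$high, x$step))
  invisible(x)
}

## complex Morlet wavelet at frequency f, unit energy under the 1/fs measure
morlet_wavelet <- function(f, sampling_rate, n_cycles = 7) {
  sd_t <- n_cycles / (2 * pi * f)
  half <- as.integer(ceiling(5 * sd_t * sampling_rate))
  t <- (-half:half) / sampling_rate
  w <- exp(-t^2 / (2 * sd_t^2)) * exp(2i * pi * f * t)
  w / sqrt(sum(Mod(w)^2) / sampling_rate)
}

#' Morlet-wavelet time-frequency decomposition of epoched trials
#'
#' Convolves every trial and channel with complex Morlet wavelets (fixed
#' number of cycles) on the band's 0.5 Hz frequency grid and returns
#' per-epoch power spectral density in uV^2/Hz. Power is stored on a
#' decimated time grid; the map records its own frame rate, which is the
#' sampling rate entering subsequent time-frequency integrals.
#'
#' @param epochs An [epoch_set()].
#' @param band A [band_spec()].
#' @param n_cycles Morlet width in cycles (default 7 at every frequency).
#' @param decim Integer decimation factor for the stored time axis
#'   (default 20, i.e. 25 frames/s at 500 Hz).
#' @return An object of class `tfr_epochs`: `psd` array
#'   trials x channels x frequencies x frames, plus `freqs`, `times`,
#'   `frame_rate`, `labels` (per-trial classes) and `band`.
#' @export
morlet_tfr <- function(epochs, band, n_cycles = 7, decim = 20L) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(band, "band_spec"))
  fs <- epochs$sampling_rate
  if (band$high >= fs / 2) {
    abort("band extends beyond the Nyquist frequency.")
  }
  d <- dim(epochs$data)
  n_ep <- d[1]; n_ch <- d[2]; n_samp <- d[3]
  if (n_ep == 0L) abort("no epochs to transform.")
  freqs <- band$freqs
  idx_dec <- seq.int(1L, n_samp, by = as.integer(decim))
  times <- (idx_dec - 1L) / fs
  frame_rate <- fs / decim

  wavelets <- lapply(freqs, morlet_wavelet, sampling_rate = fs,
                     n_cycles = n_cycles)
  halves <- vapply(wavelets, function(w) (length(w) - 1L) %/% 2L, integer(1))
  nfft <- next_fast_len(n_samp + max(lengths(wavelets)) - 1L)
  wfts <- lapply(wavelets, function(w) fft(c(w, numeric(nfft - length(w)))))

  psd <- array(0, c(n_ep, n_ch, length(freqs), length(idx_dec)))
  pad <- matrix(0, nfft - n_samp, n_ep)
  for (ch in seq_len(n_ch)) {
    x <- rbind(t(matrix(epochs$data[, ch, ], n_ep, n_samp)), pad)
    X <- mvfft(x)
    for (fi in seq_along(freqs)) {
      y <- mvfft(X * wfts[[fi]], inverse = TRUE) / nfft
      sel <- y[halves[fi] + idx_dec, , drop = FALSE]
      psd[, ch, fi, ] <- t(2 * Mod(sel / fs)^2)
    }
  }
  structure(
    list(psd = psd, freqs = freqs, times = times, frame_rate = frame_rate,
         sampling_rate = fs, channel_labels = epochs$channel_labels,
         labels = epochs$labels, band = band$name, n_cycles = n_cycles),
    class = "tfr_epochs"
  )
}

#' @export
print.tfr_epochs <- function(x, ...) {
  d <- dim(x$psd)
  cat(sprintf(
    "<tfr_epochs> %s band: %d trials x %d channels x %d freqs x %d frames (%g fps)\n",
    x$band, d[1], d[2], d[3], d[4], x$frame_rate
  ))
  invisible(x)
}

#' Construct a time-frequency map directly
#'
#' Mainly useful for tests and for feeding externally computed spectrograms
#' into the ERD-ratio machinery.
#'
#' @param psd Numeric 3-D array, channels x frequencies x frames, uV^2/Hz.
#' @param freqs Frequency grid in Hz.
#' @param times Frame times in seconds.
#' @param frame_rate Frames per second of the time axis.
#' @param channel_labels Channel names.
#' @param n_epochs_averaged Number of epochs averaged into the map.
#' @return An object of class `tfr_map`.
#' @export
tfr_map <- function(psd, freqs, times, frame_rate, channel_labels,
                    n_epochs_averaged = 1L) {
  stopifnot(length(dim(psd)) == 3L,
            dim(psd)[1] == length(channel_labels),
            dim(psd)[2] == length(freqs),
            dim(psd)[3] == length(times))
  if (any(psd < 0)) abort("power spectral density must be nonnegative.")
  structure(
    list(psd = psd, freqs = freqs, times = times, frame_rate = frame_rate,
         channel_labels = as.character(channel_labels),
         n_epochs_averaged = as.integer(n_epochs_averaged)),
    class = "tfr_map"
  )
}

#' @export
print.tfr_map <- function(x, ...) {
  d <- dim(x$psd)
  cat(sprintf(
    "<tfr_map> %d channels x %d freqs x %d frames, average of %d epoch(s)\n",
    d[1], d[2], d[3], x$n_epochs_averaged
  ))
  invisible(x)
}

#' Average per-epoch time-frequency power over a trial class
#'
#' Element-wise mean of the per-epoch power maps belonging to one class
#' (e.g. all motor-attempt trials), the standard step that stabilizes the
#' induced-power estimate before ERD quantification.
#'
#' @param tfr A [morlet_tfr()] result.
#' @param group Trial class to average (`"attempt"` or `"blank"`); `NULL`
#'   averages every epoch.
#' @return A [tfr_map()] with `n_epochs_averaged` recorded.
#' @export
average_tfr <- function(tfr, group = NULL) {
  stopifnot(inherits(tfr, "tfr_epochs"))
  sel <- if (is.null(group)) seq_along(tfr$labels) else which(tfr$labels == group)
  if (length(sel) == 0L) {
    abort(sprintf("no epochs in group '%s'.", group %||% "<all>"))
  }
  m <- apply(tfr$psd[sel, , , , drop = FALSE], c(2, 3, 4), mean)
  tfr_map(m, tfr$freqs, tfr$times, tfr$frame_rate, tfr$channel_labels,
          n_epochs_averaged = length(sel))
}

#' Integrate time-frequency power over a band and time window
#'
#' Per-channel double sum of the power spectral density over the band's
#' frequency grid (both edges inclusive) and the half-open time window
#' `[start, end)`, divided by the map's frame rate -- the energy term of the
#' ERD-ratio statistic.
#'
#' @param map A [tfr_map()].
#' @param window Length-2 numeric, time window in seconds `[start, end)`.
#' @param band Optional [band_spec()] restricting the frequency rows; by
#'   default every frequency in the map is used.
#' @return A tibble with columns `channel` and `energy`.
#' @export
integrate_band_window <- function(map, window, band = NULL) {
  stopifnot(inherits(map, "tfr_map"))
  f_keep <- if (is.null(band)) {
    rep(TRUE, length(map$freqs))
  } else {
    map$freqs >= band$low & map$freqs <= band$high
  }
  if (!any(f_keep)) abort("no map frequencies inside the requested band.")
  eps <- 1e-9
  t_keep <- map$times >= window[1] - eps & map$times < window[2] - eps
  if (window[1] < min(map$times) - eps ||
      window[2] > max(map$times) + 1 / map$frame_rate + eps) {
    abort(sprintf("window [%g, %g) lies outside the epoch time axis.",
                  window[1], window[2]))
  }
  if (!any(t_keep)) abort("time window contains no frames.")
  sub <- map$psd[, f_keep, t_keep, drop = FALSE]
  tibble(
    channel = map$channel_labels,
    energy = apply(sub, 1L, sum) / map$frame_rate
  )
}
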