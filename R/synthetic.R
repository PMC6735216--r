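#' Simulation configuration for synthetic motor-attempt EEG
#'
#' Bundles every parameter of the synthetic cue-paradigm generator. The
#' defaults reproduce the recording conditions of the experiment the package
#' models: 500 Hz sampling, 7 s trials, 20 motor-attempt cues plus 20 blank
#' controls per session in randomized order with 5-6 s inter-trial intervals.
#'
#' @param n_attempt,n_blank Number of motor-attempt and blank-control trials.
#' @param sampling_rate Sampling rate in Hz.
#' @param trial_length Trial duration in seconds.
#' @param iti_range Length-2 numeric, min and max inter-trial interval (s)
#'   between the end of one trial and the onset of the next.
#' @param cue_onset Cue time in seconds from trial start (the arrow appears
#'   after the fixation period).
#' @param noise Named list of background amplitudes in microvolts:
#'   `pink_uV` (approximately 1/f background), `white_uV` (broadband sensor
#'   noise), `eog_uV` (slow ocular activity on the EOG channel).
#' @param oscillation_uV Named numeric, RMS amplitude in microvolts of the
#'   band-limited alpha (8-13 Hz) and beta (13-30 Hz) components.
#' @param spatial_mixing Mixing weight in `[0, 1)` for optional
#'   volume-conduction-like blending with neighboring channels; 0 (default)
#'   disables mixing.
#' @param seed Integer seed that fully determines the generated session.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_attempt = 2, n_blank = 2, seed = 1)
#' @export
sim_config <- function(n_attempt = 20L, n_blank = 20L,
                       sampling_rate = 500, trial_length = 7,
                       iti_range = c(5, 6), cue_onset = 3,
                       noise = list(pink_uV = 1.5, white_uV = 0.5,
                                    eog_uV = 15),
                       oscillation_uV = c(alpha = 6, beta = 5),
                       spatial_mixing = 0, seed = 1L) {
  if (n_attempt < 1L || n_blank < 1L) {
    abort("configuration error: trial counts must be positive.")
  }
  if (sampling_rate <= 2 * 30) {
    abort("`sampling_rate` must exceed twice the highest synthesized frequency.")
  }
  if (length(iti_range) != 2L || iti_range[1] > iti_range[2] ||
      iti_range[1] < 0) {
    abort("`iti_range` must be c(min, max) with 0 <= min <= max.")
  }
  if (cue_onset < 0 || cue_onset >= trial_length) {
    abort("`cue_onset` must lie within the trial.")
  }
  if (spatial_mixing < 0 || spatial_mixing >= 1) {
    abort("`spatial_mixing` must be in [0, 1).")
  }
  defaults <- list(pink_uV = 1.5, white_uV = 0.5, eog_uV = 15)
  noise <- utils::modifyList(defaults, as.list(noise))
  structure(
    list(
      n_attempt = as.integer(n_attempt), n_blank = as.integer(n_blank),
      sampling_rate = sampling_rate, trial_length = trial_length,
      iti_range = iti_range, cue_onset = cue_onset,
      noise = noise, oscillation_uV = oscillation_uV,
      spatial_mixing = spatial_mixing, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' ERD ground truth for the synthetic generator
#'
#' Describes where, in which band and how deeply band power is attenuated
#' during the movement window of attempt trials. `depth = 0.5` halves band
#' power on the affected channels; `depth = 0` disables the effect.
#'
#' @param channels Character vector of montage channel labels carrying ERD.
#' @param band `"alpha"`, `"beta"` or `"both"`.
#' @param depth Fractional band-power attenuation in `[0, 1]`.
#' @param window Length-2 numeric, attenuation window in seconds within
#'   attempt trials (default `c(4, 7)`, the movement state).
#' @return An object of class `erd_ground_truth`.
#' @export
erd_ground_truth <- function(channels, band = c("alpha", "beta", "both"),
                             depth = 0.5, window = c(4, 7)) {
  band <- match.arg(band)
  if (depth < 0 || depth > 1) abort("`depth` must lie in [0, 1].")
  if (length(window) != 2L || window[1] >= window[2]) {
    abort("`window` must be c(start, end) with start < end.")
  }
  structure(
    list(channels = as.character(channels), band = band, depth = depth,
         window = window),
    class = "erd_ground_truth"
  )
}

#' Build a randomized cue/blank trial schedule
#'
#' Draws a seeded random permutation of attempt and blank trials and
#' randomized inter-trial intervals, mirroring the cue-based paradigm
#' (randomized trial order, 5-6 s intervals between trials).
#'
#' @param config A [sim_config()].
#' @return A tibble of class `trial_schedule` with columns `onset` (s from
#'   session start) and `kind` (`"attempt"`/`"blank"`), carrying the trial
#'   length, cue window and ITI range as attributes.
#' @examples
#' sched <- build_schedule(sim_config(n_attempt = 2, n_blank = 2, seed = 1))
#' @export
build_schedule <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_attempt + config$n_blank
  withr::with_seed(config$seed + 101L, {
    kinds <- sample(c(rep("attempt", config$n_attempt),
                      rep("blank", config$n_blank)))
    itis <- runif(n, config$iti_range[1], config$iti_range[2])
  })
  onsets <- cumsum(itis + c(0, rep(config$trial_length, n - 1L)))
  out <- tibble(onset = onsets, kind = kinds)
  structure(
    out,
    trial_length = config$trial_length,
    cue_window = c(config$cue_onset, config$cue_onset + 1),
    iti_range = config$iti_range,
    class = c("trial_schedule", class(out))
  )
}

## column standard deviations without forming per-column copies
col_sds <- function(x) {
  n <- nrow(x)
  sqrt((colSums(x^2) - n * colMeans(x)^2) / (n - 1))
}

## one-pole lowpass stages at log-spaced corner frequencies with equalised
## variances, summed: plateau PSD ~ 1/fc gives an approximately 1/f spectrum
## over the EEG band; columns are channels, normalised to unit sd
pink_noise <- function(x, sampling_rate) {
  corners <- c(1.5, 6, 24)
  poles <- exp(-2 * pi * corners / sampling_rate)
  y <- onepole_cascade(x, poles, sqrt(1 - poles^2))
  y * rep(1 / col_sds(y), each = nrow(y))
}

## narrowband gaussian noise, one channel per column: complex baseband
## generated at a low rate in the frequency domain, linearly upsampled, then
## shifted onto the band-centre carrier; unit sd per column
band_noise <- function(n, sampling_rate, band, carrier_cos, carrier_sin,
                       n_channels, block = 16L) {
  half_bw <- diff(band) / 2
  fs_low <- max(8 * half_bw, 16)
  m <- next_fast_len(as.integer(ceiling(n * fs_low / sampling_rate)) + 4L)
  freqs <- (seq_len(m) - 1L) / m * fs_low
  freqs[freqs > fs_low / 2] <- freqs[freqs > fs_low / 2] - fs_low
  keep <- which(abs(freqs) <= half_bw)
  ## shared linear-interpolation stencil from the low-rate grid to full rate
  pos <- (seq_len(n) - 1L) * (fs_low / sampling_rate)
  i0 <- pmin(as.integer(floor(pos)) + 1L, m - 1L)
  frac <- pos - (i0 - 1L)
  out <- matrix(0, n, n_channels)
  for (j0 in seq.int(1L, n_channels, by = block)) {
    cols <- j0:min(j0 + block - 1L, n_channels)
    spec <- matrix(0i, m, length(cols))
    spec[keep, ] <- complex(
      real = rnorm(length(keep) * length(cols)),
      imaginary = rnorm(length(keep) * length(cols))
    )
    z <- mvfft(spec, inverse = TRUE) / m
    out[, cols] <- band_carrier_interp(z, i0, frac, carrier_cos, carrier_sin)
  }
  out * rep(1 / col_sds(out), each = n)
}

## multiplicative ERD envelope: full attenuation inside [S, E) of each attempt
## trial, raised-cosine transitions over 0.2 s immediately outside the window
erd_envelope <- function(n, sampling_rate, onsets, window, depth,
                         ramp = 0.2) {
  g <- rep(1, n)
  lo <- sqrt(1 - depth)
  n_ramp <- max(1L, round(ramp * sampling_rate))
  ramp_down <- lo + (1 - lo) * (1 + cos(seq(0, pi, length.out = n_ramp))) / 2
  for (o in onsets) {
    s0 <- floor((o + window[1]) * sampling_rate) + 1L
    s1 <- floor((o + window[2]) * sampling_rate)
    if (s0 > n) next
    s1 <- min(s1, n)
    g[s0:s1] <- lo
    d0 <- s0 - n_ramp
    if (d0 >= 1L) g[d0:(s0 - 1L)] <- ramp_down
    u0 <- s1 + 1L
    u1 <- min(s1 + n_ramp, n)
    if (u0 <= u1) g[u0:u1] <- rev(ramp_down)[seq_len(u1 - u0 + 1L)]
  }
  g
}

#' Synthesize a continuous multi-channel EEG session
#'
#' Generates 64-channel scalp EEG as approximately 1/f pink background plus
#' band-limited alpha and beta oscillations plus white sensor noise, all
#' independent across channels. During the movement window of attempt trials
#' the configured band's oscillatory envelope on the ground-truth channels is
#' attenuated so that band power drops by the factor `1 - depth`. The EOG
#' channel carries unrelated slow (< 5 Hz) activity. Event marks are placed
#' at every trial onset and at the cue onset of attempt trials. Output is
#' fully determined by the configuration seed.
#'
#' @param config A [sim_config()].
#' @param schedule A [build_schedule()] result; built from `config` if `NULL`.
#' @param truth An [erd_ground_truth()], or `NULL` for a session without any
#'   movement-related modulation.
#' @param montage A [standard_montage()].
#' @return A [raw_session()].
#' @examples
#' cfg <- sim_config(n_attempt = 2, n_blank = 2, seed = 7)
#' ses <- synthesize_session(cfg, truth = erd_ground_truth("C3", depth = 0.5))
#' @export
synthesize_session <- function(config, schedule = NULL, truth = NULL,
                               montage = standard_montage()) {
  stopifnot(inherits(config, "sim_config"))
  schedule <- schedule %||% build_schedule(config)
  fs <- config$sampling_rate
  labels <- montage$labels
  n_ch <- length(labels)
  scalp <- setdiff(labels, labels[montage$eog_index])
  if (!is.null(truth)) {
    missing_ch <- setdiff(truth$channels, scalp)
    if (length(missing_ch) > 0) {
      abort(sprintf("Unknown ERD ground-truth channel(s): %s",
                    paste(missing_ch, collapse = ", ")))
    }
  }
  duration <- max(schedule$onset) + attr(schedule, "trial_length") + 2
  n <- as.integer(ceiling(duration * fs))
  t_hi <- (seq_len(n) - 1L) / fs
  alpha_band <- c(8, 13)
  beta_band <- c(13, 30)
  attempt_onsets <- schedule$onset[schedule$kind == "attempt"]

  env_alpha <- env_beta <- NULL
  if (!is.null(truth) && truth$depth > 0) {
    g <- erd_envelope(n, fs, attempt_onsets, truth$window, truth$depth)
    if (truth$band %in% c("alpha", "both")) env_alpha <- g
    if (truth$band %in% c("beta", "both")) env_beta <- g
  }

  withr::with_seed(config$seed + 202L, {
    ca <- cos(2 * pi * mean(alpha_band) * t_hi)
    sa <- sin(2 * pi * mean(alpha_band) * t_hi)
    cb <- cos(2 * pi * mean(beta_band) * t_hi)
    sb <- sin(2 * pi * mean(beta_band) * t_hi)
    amp_a <- unname(config$oscillation_uV["alpha"])
    amp_b <- unname(config$oscillation_uV["beta"])
    alpha_m <- band_noise(n, fs, alpha_band, ca, sa, n_ch) * amp_a
    beta_m <- band_noise(n, fs, beta_band, cb, sb, n_ch) * amp_b
    truth_cols <- match(truth$channels %||% character(), labels)
    if (!is.null(env_alpha)) {
      alpha_m[, truth_cols] <- alpha_m[, truth_cols] * env_alpha
    }
    if (!is.null(env_beta)) {
      beta_m[, truth_cols] <- beta_m[, truth_cols] * env_beta
    }
    ## the white matrix doubles as the pink-filter input, so the broadband
    ## floor is one jointly filtered white-noise process per channel
    white <- matrix(rnorm(n * n_ch), n, n_ch)
    sig <- config$noise$pink_uV * pink_noise(white, fs) +
      alpha_m + beta_m + config$noise$white_uV * white
    a <- exp(-2 * pi * 1.5 / fs)
    slow <- onepole_cascade(matrix(rnorm(n), n, 1L), a, 1)[, 1]
    sig[, montage$eog_index] <- config$noise$eog_uV * slow / sd(slow)
  })
  signal <- t(sig)
  dimnames(signal) <- list(labels, NULL)

  if (config$spatial_mixing > 0) {
    signal <- mix_neighbors(signal, labels, montage, config$spatial_mixing)
  }

  ev_start <- tibble(
    sample = as.integer(floor(schedule$onset * fs)) + 1L,
    code = "trial_start",
    kind = schedule$kind
  )
  cue_t <- attr(schedule, "cue_window")[1]
  ev_cue <- tibble(
    sample = as.integer(floor((attempt_onsets + cue_t) * fs)) + 1L,
    code = "cue",
    kind = "attempt"
  )
  events <- dplyr::arrange(dplyr::bind_rows(ev_start, ev_cue), .data$sample)
  raw_session(signal, fs, labels, events, montage)
}

## volume-conduction-like blending: each scalp channel is averaged with its
## spatial neighbours (schematic positions within unit radius)
mix_neighbors <- function(signal, labels, montage, alpha) {
  pos <- montage_positions(labels)
  keep <- labels != labels[montage$eog_index]
  xy <- as.matrix(pos[, c("x", "y")])
  d <- as.matrix(stats::dist(xy))
  adj <- (d > 0 & d <= 0.9)
  adj[!keep, ] <- FALSE
  adj[, !keep] <- FALSE
  mixed <- signal
  for (i in which(keep)) {
    nb <- which(adj[i, ])
    if (length(nb) == 0) next
    mixed[i, ] <- (1 - alpha) * signal[i, ] +
      alpha * colMeans(signal[nb, , drop = FALSE])
  }
  mixed
}
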