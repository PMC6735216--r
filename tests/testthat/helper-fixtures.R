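## shared fixtures, built once per test file and reused

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

## small session: 4 attempt + 4 blank trials, alpha ERD on four left
## sensorimotor channels
small_truth_channels <- c("C3", "C1", "FC3", "CP3")

small_session <- function() {
  cached("small_session", function() {
    synthesize_session(
      sim_config(n_attempt = 4, n_blank = 4, seed = 42),
      truth = erd_ground_truth(small_truth_channels, band = "alpha",
                               depth = 0.6)
    )
  })
}

small_epochs <- function() {
  cached("small_epochs", function() preprocess_session(small_session()))
}

## a raw_session wrapper around an arbitrary matrix, without montage
toy_session <- function(signal, fs = 500, labels = NULL, events = NULL) {
  labels <- labels %||% paste0("ch", seq_len(nrow(signal)))
  raw_session(signal, fs, labels,
              events = events %||% tibble::tibble(
                sample = integer(), code = character(), kind = character()
              ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

## an erd_ratio_map built directly from ratio vectors
make_ratio_map <- function(channels, alpha, beta = NULL) {
  out <- tibble::tibble(channel = channels, alpha = alpha)
  if (!is.null(beta)) out$beta <- beta
  structure(out, montage_labels = channels,
            class = c("erd_ratio_map", class(tibble::tibble())))
}

## gaussian epochs with per-class, per-channel scales
## scales: list(attempt = numeric(n_ch), blank = numeric(n_ch))
toy_epochs <- function(n_per_class = 10, n_ch = 4, n_samp = 700, fs = 100,
                       scales = NULL, seed = 1) {
  labels <- rep(c("attempt", "blank"), each = n_per_class)
  scales <- scales %||% list(attempt = rep(1, n_ch), blank = rep(1, n_ch))
  withr::with_seed(seed, {
    data <- array(rnorm(2 * n_per_class * n_ch * n_samp),
                  c(2 * n_per_class, n_ch, n_samp))
  })
  for (k in seq_along(labels)) {
    data[k, , ] <- data[k, , ] * scales[[labels[k]]]
  }
  epoch_set(data, labels, fs, paste0("ch", seq_len(n_ch)))
}

## independent ERD-ratio oracle: explicit loops over the frequency grid and
## the half-open time windows, explicit duration normalization
erd_ratio_oracle <- function(map, rest_window, move_window) {
  n_ch <- length(map$channel_labels)
  out <- numeric(n_ch)
  eps <- 1e-9
  for (c in seq_len(n_ch)) {
    e_rest <- 0
    e_move <- 0
    for (fi in seq_along(map$freqs)) {
      for (ti in seq_along(map$times)) {
        t <- map$times[ti]
        v <- map$psd[c, fi, ti] / map$frame_rate
        if (t >= rest_window[1] - eps && t < rest_window[2] - eps) {
          e_rest <- e_rest + v
        }
        if (t >= move_window[1] - eps && t < move_window[2] - eps) {
          e_move <- e_move + v
        }
      }
    }
    dur_rest <- rest_window[2] - rest_window[1]
    dur_move <- move_window[2] - move_window[1]
    out[c] <- (dur_rest / dur_move) * e_move / e_rest
  }
  out
}

## random time-frequency map for oracle checks
random_tfr_map <- function(n_ch = 6, n_freq = 11, frame_rate = 25,
                           t_max = 7, seed = 1) {
  withr::with_seed(seed, {
    times <- seq(0, t_max - 1 / frame_rate, by = 1 / frame_rate)
    psd <- array(stats::rexp(n_ch * n_freq * length(times)),
                 c(n_ch, n_freq, length(times)))
    tfr_map(psd, seq(8, by = 0.5, length.out = n_freq), times, frame_rate,
            paste0("ch", seq_len(n_ch)))
  })
}

## independent average trace-normalized covariance, explicit loops
oracle_cov <- function(trials) {
  d <- dim(trials)
  acc <- matrix(0, d[2], d[2])
  for (k in seq_len(d[1])) {
    x <- matrix(trials[k, , ], d[2], d[3])
    C <- x %*% t(x) / d[3]
    acc <- acc + C / sum(diag(C))
  }
  acc / d[1]
}

gauss_trials <- function(n_trials, chol_cov, n_samp = 500, seed = 1) {
  n_ch <- nrow(chol_cov)
  withr::with_seed(seed, {
    out <- array(0, c(n_trials, n_ch, n_samp))
    for (k in seq_len(n_trials)) {
      out[k, , ] <- t(chol_cov) %*% matrix(rnorm(n_ch * n_samp), n_ch, n_samp)
    }
    out
  })
}
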