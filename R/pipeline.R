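#' Pipeline configuration
#'
#' All stage parameters of the end-to-end analysis, validated up front so a
#' contradictory configuration fails before any computation starts.
#'
#' @param filter_low,filter_high Band-pass edges in Hz.
#' @param trial_length Epoch duration in seconds.
#' @param baseline Baseline window in seconds.
#' @param rest_window,move_window ERD state windows in seconds.
#' @param n_cycles Morlet width in cycles.
#' @param decimate Integer factor by which epochs are downsampled after the
#'   band-pass (anti-aliased by the filter) before spectral and CSP
#'   analysis; 4 gives a 125 Hz analysis rate at 500 Hz acquisition.
#' @param frame_rate Frames per second of the stored time-frequency maps.
#' @param theta_active ERD activity threshold on the ratio.
#' @param reject_uV Peak artifact-rejection threshold in microvolts.
#' @param k Number of channels for the lowest-ERD-ratio strategy.
#' @param folds Cross-validation folds.
#' @param paretic_side `"left"` or `"right"`.
#' @param seed Root seed for the cross-validation fold assignment.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(filter_low = 1, filter_high = 40,
                            trial_length = 7, baseline = c(0, 1),
                            rest_window = c(1, 3), move_window = c(4, 7),
                            n_cycles = 7, decimate = 4L, frame_rate = 25,
                            theta_active = 0.8,
                            reject_uV = 100, k = 4L, folds = 5L,
                            paretic_side = "right", seed = 1L) {
  if (!(filter_low > 0 && filter_low < filter_high)) {
    abort("need 0 < filter_low < filter_high.")
  }
  check_window <- function(w, what) {
    if (length(w) != 2L || w[1] < 0 || w[1] >= w[2] || w[2] > trial_length) {
      abort(sprintf("%s window must satisfy 0 <= start < end <= trial_length.",
                    what))
    }
  }
  check_window(baseline, "baseline")
  check_window(rest_window, "resting")
  check_window(move_window, "moving")
  if (rest_window[2] > move_window[1]) {
    abort("resting window must end before the moving window starts.")
  }
  if (decimate < 1L) abort("`decimate` must be a positive integer.")
  if (frame_rate <= 0) abort("`frame_rate` must be positive.")
  if (theta_active <= 0) abort("`theta_active` must be positive.")
  if (reject_uV <= 0) abort("`reject_uV` must be positive.")
  if (k < 1L) abort("`k` must be at least 1.")
  if (folds < 2L) abort("`folds` must be at least 2.")
  contralateral_hemisphere(paretic_side) # validates the side
  structure(
    list(
      filter_low = filter_low, filter_high = filter_high,
      trial_length = trial_length, baseline = baseline,
      rest_window = rest_window, move_window = move_window,
      n_cycles = n_cycles, decimate = as.integer(decimate),
      frame_rate = frame_rate,
      theta_active = theta_active, reject_uV = reject_uV,
      k = as.integer(k), folds = as.integer(folds),
      paretic_side = paretic_side, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Run the full ERD channel-selection analysis on one session
#'
#' Executes preprocessing, Morlet time-frequency analysis of the attempt
#' trials, ERD-ratio topography with band selection, the three
#' channel-selection strategies and cross-validated attempt-vs-rest
#' classification for each strategy.
#'
#' @param session A [raw_session()].
#' @param config A [pipeline_config()].
#' @param unaffected_has_erd Optional logical used to classify the
#'   topography pattern; `NA` skips pattern classification.
#' @return An object of class `erd_pipeline_report` with elements `config`,
#'   `n_trials_kept`, `erd_map`, `band_selected`, `pattern` (or `NULL`),
#'   `strategies` (a tibble with one row per strategy) and `cv` (the raw
#'   [crossval_accuracy()] results).
#' @export
run_pipeline <- function(session, config = pipeline_config(),
                         unaffected_has_erd = NA) {
  stopifnot(inherits(session, "raw_session"),
            inherits(config, "pipeline_config"))
  epochs <- preprocess_session(
    session,
    low = config$filter_low, high = config$filter_high,
    trial_length = config$trial_length, baseline = config$baseline,
    reject_uV = config$reject_uV
  )
  epochs <- downsample_epochs(epochs, config$decimate)
  attempt_idx <- epochs$labels == "attempt"
  if (!any(attempt_idx)) abort("stage erd: no attempt trials survived.")
  attempt <- epoch_set(
    epochs$data[attempt_idx, , , drop = FALSE],
    epochs$labels[attempt_idx], epochs$sampling_rate, epochs$channel_labels
  )
  tfr_decim <- max(1L, round(epochs$sampling_rate / config$frame_rate))
  maps <- list(
    alpha = average_tfr(morlet_tfr(attempt, alpha_band(),
                                   n_cycles = config$n_cycles,
                                   decim = tfr_decim), "attempt"),
    beta = average_tfr(morlet_tfr(attempt, beta_band(),
                                  n_cycles = config$n_cycles,
                                  decim = tfr_decim), "attempt")
  )
  emap <- erd_ratio_map(maps, rest_window = config$rest_window,
                        move_window = config$move_window)
  band <- select_band(emap)
  pattern <- if (!is.na(unaffected_has_erd)) {
    classify_pattern(emap, config$paretic_side, unaffected_has_erd,
                     theta_active = config$theta_active, band = band)
  }
  strategy_sets <- list(
    sm1_4 = sm1_4(config$paretic_side),
    sm1_5 = sm1_5(config$paretic_side),
    erd = erd_lowest_k(emap, k = config$k, band = band)
  )
  cv <- purrr::map(strategy_sets, function(chs) {
    crossval_accuracy(epochs, chs, seed = config$seed, folds = config$folds,
                      window = config$move_window)
  })
  strategies <- tibble(
    strategy = names(strategy_sets),
    channels = purrr::map_chr(strategy_sets, paste, collapse = " "),
    mean_accuracy = purrr::map_dbl(cv, "mean_accuracy")
  )
  structure(
    list(
      config = config,
      n_trials_kept = n_trials(epochs),
      erd_map = emap,
      band_selected = band,
      pattern = pattern,
      strategies = strategies,
      cv = cv
    ),
    class = "erd_pipeline_report"
  )
}

#' @export
print.erd_pipeline_report <- function(x, ...) {
  cat("== ERD channel-selection report ==\n")
  cat(sprintf("trials kept: %d; representative band: %s\n",
              x$n_trials_kept, x$band_selected))
  if (!is.null(x$pattern)) {
    cat(sprintf("topography pattern: %s\n", x$pattern$group))
  }
  for (i in seq_len(nrow(x$strategies))) {
    cat(sprintf("  %-6s %-28s accuracy %.3f\n",
                x$strategies$strategy[i], x$strategies$channels[i],
                x$strategies$mean_accuracy[i]))
  }
  invisible(x)
}

#' Tidy the per-strategy results of a pipeline report
#'
#' @param x An [run_pipeline()] report.
#' @param ... Unused.
#' @return The `strategies` tibble with per-fold accuracies nested in a
#'   list-column.
#' @exportS3Method generics::tidy
#' @export
tidy.erd_pipeline_report <- function(x, ...) {
  dplyr::mutate(x$strategies,
                fold_accuracies = purrr::map(x$cv, "fold_accuracies"))
}
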