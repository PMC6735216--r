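#' State windows for the ERD-ratio statistic
#'
#' A labelled half-open time window `[start, end)` within the trial. The
#' defaults follow the trial timeline: resting during seconds 1-3 (fixation,
#' before the cue) and moving during seconds 4-7 (motor attempt).
#'
#' @param start,end Window edges in seconds from trial start.
#' @param state `"resting"` or `"moving"`.
#' @return An object of class `state_window`.
#' @export
state_window <- function(start, end, state = c("resting", "moving")) {
  state <- match.arg(state)
  if (!(start >= 0 && start < end)) {
    abort("`start` must be nonnegative and smaller than `end`.")
  }
  structure(list(start = start, end = end, state = state),
            class = "state_window")
}

as_state_window <- function(x, state) {
  if (inherits(x, "state_window")) return(x)
  state_window(x[1], x[2], state)
}

#' Per-channel ERD ratio from state energies
#'
#' The duration-normalized ratio of moving-state to resting-state
#' time-frequency energy:
#' \deqn{\mathrm{ERD\ ratio} = \frac{E_1 - S_1}{E_2 - S_2}\cdot
#'   \frac{\mathrm{energy}_{move}}{\mathrm{energy}_{rest}}}
#' where `[S1, E1)` is the resting and `[S2, E2)` the moving window. Values
#' below 1 indicate a power decrease during movement, i.e.
#' event-related desynchronization.
#'
#' @param rest_energy,move_energy Band-window energies (vectorized).
#' @param rest_window,move_window [state_window()]s or length-2 numerics.
#' @return Numeric vector of dimensionless ERD ratios.
#' @examples
#' erd_ratio(rest_energy = 1, move_energy = 1.5,
#'           rest_window = c(1, 3), move_window = c(4, 7))
#' @export
erd_ratio <- function(rest_energy, move_energy, rest_window = c(1, 3),
                      move_window = c(4, 7)) {
  rest_window <- as_state_window(rest_window, "resting")
  move_window <- as_state_window(move_window, "moving")
  if (any(rest_energy <= 0)) {
    abort("resting-state energy must be strictly positive.")
  }
  dur_rest <- rest_window$end - rest_window$start
  dur_move <- move_window$end - move_window$start
  (dur_rest / dur_move) * move_energy / rest_energy
}

#' ERD-ratio topography over channels and bands
#'
#' Computes the per-channel ERD ratio in each supplied band from
#' class-averaged time-frequency maps, yielding the ratio map that is
#' thresholded and ranked by the channel-selection strategies.
#'
#' @param maps A named list of [tfr_map()]s, one per band (typically
#'   `list(alpha = ..., beta = ...)`, both averaged over attempt trials).
#' @param rest_window,move_window State windows (seconds).
#' @param bands Optional named list of [band_spec()]s used to restrict each
#'   map's frequency rows; by default each map's full grid is integrated.
#' @return A tibble of class `erd_ratio_map` with a `channel` column and one
#'   ratio column per band; the state windows and the canonical montage
#'   channel order are carried as attributes.
#' @export
erd_ratio_map <- function(maps, rest_window = c(1, 3), move_window = c(4, 7),
                          bands = NULL) {
  if (inherits(maps, "tfr_map")) maps <- list(ratio = maps)
  stopifnot(length(maps) >= 1, !is.null(names(maps)))
  rest_window <- as_state_window(rest_window, "resting")
  move_window <- as_state_window(move_window, "moving")
  channels <- maps[[1]]$channel_labels
  cols <- purrr::imap(maps, function(map, band_name) {
    stopifnot(identical(map$channel_labels, channels))
    band <- bands[[band_name]]
    rest <- integrate_band_window(map, c(rest_window$start, rest_window$end),
                                  band = band)
    move <- integrate_band_window(map, c(move_window$start, move_window$end),
                                  band = band)
    erd_ratio(rest$energy, move$energy, rest_window, move_window)
  })
  out <- tibble(channel = channels, !!!cols)
  structure(
    out,
    rest_window = rest_window, move_window = move_window,
    montage_labels = channels,
    class = c("erd_ratio_map", class(out))
  )
}

ratio_bands <- function(map) setdiff(names(map), "channel")

#' Select the band representing motor intention
#'
#' Returns the band whose lowest channel ratio is smaller -- ERD is spatially
#' focal, so the band minimum over channels is compared. Exact ties resolve
#' to alpha.
#'
#' @param map An [erd_ratio_map()].
#' @return The selected band name (a column of `map`).
#' @export
select_band <- function(map) {
  stopifnot(inherits(map, "erd_ratio_map"))
  bands <- ratio_bands(map)
  mins <- vapply(bands, function(b) min(map[[b]]), numeric(1))
  if ("alpha" %in% bands && mins["alpha"] <= min(mins)) {
    return("alpha")
  }
  bands[which.min(mins)]
}

## contralateral primary-sensorimotor neighborhood (C3/C4 plus immediate
## neighbors), mirrored by paretic side
sm1_neighborhood <- function(paretic_side) {
  switch(contralateral_hemisphere(paretic_side),
    left = c("C3", "C1", "C5", "FC3", "CP3"),
    right = c("C4", "C2", "C6", "FC4", "CP4")
  )
}

#' Classify an ERD topography into the five observed patterns
#'
#' Operationalizes the visual grouping of paretic-hand ERD topographies:
#' channels with a selected-band ratio below `theta_active` count as active;
#' no active channel means ERD-blind (if the unaffected hand also shows no
#' ERD) or ERD-disappearance; six or more active channels spanning both
#' hemispheres or lying predominantly ipsilateral mean ERD-proliferation;
#' activity confined to the contralateral sensorimotor neighborhood means
#' ERD-SM1; anything else falls into "others".
#'
#' @param map An [erd_ratio_map()] from paretic-hand attempt trials.
#' @param paretic_side `"left"` or `"right"`.
#' @param unaffected_has_erd Logical: did the unaffected-hand map show ERD?
#' @param theta_active Activity threshold on the ratio (default 0.8).
#' @param band Band to threshold; defaults to [select_band()].
#' @return A list of class `topography_pattern` with elements `group`,
#'   `metrics` (min ratio, active-channel count, laterality index) and
#'   `active_channels`.
#' @export
classify_pattern <- function(map, paretic_side,
                             unaffected_has_erd = TRUE,
                             theta_active = 0.8, band = NULL) {
  stopifnot(inherits(map, "erd_ratio_map"))
  contra <- contralateral_hemisphere(paretic_side)
  ipsi <- setdiff(c("left", "right"), contra)
  band <- band %||% select_band(map)
  ratios <- map[[band]]
  active <- map$channel[ratios < theta_active]
  hemi <- hemisphere_of(active)
  n_contra <- sum(hemi == contra)
  n_ipsi <- sum(hemi == ipsi)
  laterality <- if (n_contra + n_ipsi == 0) 0 else {
    (n_contra - n_ipsi) / (n_contra + n_ipsi)
  }
  group <- if (length(active) == 0L) {
    if (!isTRUE(unaffected_has_erd)) "ERD-blind" else "ERD-disappearance"
  } else if (length(active) >= 6L &&
             ((n_contra > 0 && n_ipsi > 0) || laterality <= 0)) {
    "ERD-proliferation"
  } else if (all(active %in% sm1_neighborhood(paretic_side))) {
    "ERD-SM1"
  } else {
    "others"
  }
  structure(
    list(
      group = group,
      metrics = list(
        min_ratio = min(ratios),
        n_active_channels = length(active),
        laterality_index = laterality
      ),
      active_channels = active,
      band = band,
      theta_active = theta_active
    ),
    class = "topography_pattern"
  )
}

#' @export
print.topography_pattern <- function(x, ...) {
  cat(sprintf(
    "<topography_pattern> %s (%s band): %d active channel(s), min ratio %.3f, laterality %.2f\n",
    x$group, x$band, x$metrics$n_active_channels, x$metrics$min_ratio,
    x$metrics$laterality_index
  ))
  invisible(x)
}

#' Tidy an ERD ratio map into long format
#'
#' @param x An [erd_ratio_map()].
#' @param ... Unused.
#' @return A tibble with columns `channel`, `band`, `ratio`.
#' @exportS3Method generics::tidy
#' @export
tidy.erd_ratio_map <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), -"channel",
                      names_to = "band", values_to = "ratio")
}
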