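#' Fixed sensorimotor channel-selection strategies
#'
#' The two classical montages over the contralateral primary sensorimotor
#' cortex (SM1): `sm1_4()` selects Cz plus three central electrodes and
#' `sm1_5()` five electrodes around C3 (or C4), mirrored according to the
#' paretic side. Both are data-independent.
#'
#' @param paretic_side `"left"` or `"right"` (the paretic hand).
#' @return Character vector of channel labels.
#' @examples
#' sm1_4("right")
#' sm1_5("left")
#' @export
sm1_4 <- function(paretic_side) {
  switch(contralateral_hemisphere(paretic_side),
    left = c("Cz", "C1", "C3", "C5"),
    right = c("Cz", "C2", "C4", "C6")
  )
}

#' @rdname sm1_4
#' @export
sm1_5 <- function(paretic_side) {
  switch(contralateral_hemisphere(paretic_side),
    left = c("C1", "C3", "C5", "FC3", "CP3"),
    right = c("C2", "C4", "C6", "FC4", "CP4")
  )
}

#' Individualized lowest-ERD-ratio channel selection
#'
#' Selects the `k` channels with the smallest ERD ratio in the representative
#' band (the band chosen by [select_band()] unless given). Ties are broken
#' deterministically by montage label order.
#'
#' @param map An [erd_ratio_map()].
#' @param k Number of channels to select (default 4).
#' @param band Ratio column to rank; defaults to [select_band()].
#' @return Character vector of `k` channel labels, ordered by increasing
#'   ratio.
#' @export
erd_lowest_k <- function(map, k = 4L, band = NULL) {
  stopifnot(inherits(map, "erd_ratio_map"))
  k <- as.integer(k)
  if (k < 1L) abort("`k` must be at least 1.")
  if (k > nrow(map)) {
    abort(sprintf("cannot select %d channels from a %d-channel map.",
                  k, nrow(map)))
  }
  band <- band %||% select_band(map)
  canonical <- attr(map, "montage_labels") %||% map$channel
  tie_rank <- match(map$channel, canonical)
  ord <- order(map[[band]], tie_rank)
  map$channel[ord][seq_len(k)]
}
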