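#' Standard 64-channel 10/20-extended electrode montage
#'
#' The montage used throughout the package: 64 recorded channels positioned
#' according to the international 10/20 extended layout, with the EOG channel
#' at position 32, CPz as the (unrecorded) online reference and AFz as ground.
#' After EOG removal 63 scalp channels remain for analysis.
#'
#' @param eog_index 1-based position of the EOG channel (default 32).
#' @return An object of class `eeg_montage`: a list with `labels` (64 channel
#'   names), `eog_index`, `reference_label` (`"CPz"`) and `ground_label`
#'   (`"AFz"`).
#' @examples
#' m <- standard_montage()
#' m$labels[m$eog_index]
#' @export
standard_montage <- function(eog_index = 32L) {
  labels <- c(
    "Fp1", "Fpz", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6", "M1", "T7", "C3", "Cz",
    "C4", "T8", "M2", "CP5", "CP1", "CP2", "CP6", "P7",
    "P3", "Pz", "P4", "P8", "POz", "O1", "Oz", "EOG",
    "O2", "AF7", "AF3", "AF4", "AF8", "F5", "F1", "F2",
    "F6", "FC3", "FCz", "FC4", "C5", "C1", "C2", "C6",
    "CP3", "CP4", "P5", "P1", "P2", "P6", "PO5", "PO3",
    "PO4", "PO6", "FT7", "FT8", "TP7", "TP8", "PO7", "PO8"
  )
  eog_index <- as.integer(eog_index)
  if (length(eog_index) != 1L || is.na(eog_index) ||
      eog_index < 1L || eog_index > length(labels)) {
    abort("`eog_index` must be a single integer in [1, 64].")
  }
  ## keep the EOG label at the requested slot
  if (eog_index != 32L) {
    labels <- labels[labels != "EOG"]
    labels <- append(labels, "EOG", after = eog_index - 1L)
  }
  stopifnot(!anyDuplicated(labels))
  structure(
    list(
      labels = labels,
      eog_index = eog_index,
      reference_label = "CPz",
      ground_label = "AFz"
    ),
    class = "eeg_montage"
  )
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> ", length(x$labels), " channels, EOG at #", x$eog_index,
      ", reference ", x$reference_label, ", ground ", x$ground_label, "\n",
      sep = "")
  invisible(x)
}

#' Approximate 2-D scalp positions for montage labels
#'
#' Schematic top-view coordinates derived from the 10/20 label grammar
#' (row letters give the anterior-posterior position, digits the lateral
#' position; odd = left, even = right, z = midline). Intended for plotting
#' and for hemisphere bookkeeping, not for source analysis.
#'
#' @param labels Character vector of 10/20 channel labels.
#' @return A tibble with columns `channel`, `x`, `y`, `hemisphere`
#'   (`"left"`, `"right"` or `"midline"`).
#' @export
montage_positions <- function(labels) {
  row_y <- c(
    Fp = 3.5, AF = 3, F = 2.2, FT = 1.1, FC = 1.1, T = 0, C = 0,
    M = 0, TP = -1.1, CP = -1.1, P = -2.2, PO = -2.9, O = -3.5, I = -4
  )
  parse_one <- function(lab) {
    if (lab == "EOG") {
      return(c(x = 0, y = 4.3))
    }
    m <- regmatches(lab, regexec("^([A-Za-z]+?)(z|[0-9]+)$", lab))[[1]]
    if (length(m) == 0L) {
      return(c(x = NA_real_, y = NA_real_))
    }
    row <- m[2]
    if (row %in% c("Fpz", "Fp")) row <- "Fp"
    y <- unname(row_y[row])
    if (m[3] == "z") {
      return(c(x = 0, y = y))
    }
    d <- as.integer(m[3])
    mag <- if (row %in% c("M")) 2 else 0.4 * ceiling(d / 2)
    x <- if (d %% 2 == 1) -mag else mag
    c(x = x, y = y)
  }
  xy <- t(vapply(labels, parse_one, c(x = 0, y = 0)))
  tibble(
    channel = labels,
    x = xy[, "x"],
    y = xy[, "y"],
    hemisphere = hemisphere_of(labels)
  )
}

#' Hemisphere of a 10/20 channel label
#'
#' Odd trailing digits are on the left hemisphere, even digits on the right,
#' `z`-suffixed labels on the midline.
#'
#' @param labels Character vector of channel labels.
#' @return Character vector: `"left"`, `"right"` or `"midline"`.
#' @export
hemisphere_of <- function(labels) {
  vapply(labels, function(lab) {
    if (grepl("z$", lab)) {
      return("midline")
    }
    m <- regmatches(lab, regexec("([0-9]+)$", lab))[[1]]
    if (length(m) == 0L) {
      return("midline")
    }
    if (as.integer(m[2]) %% 2 == 1) "left" else "right"
  }, character(1), USE.NAMES = FALSE)
}

## hemisphere opposite the paretic hand, i.e. the side expected to generate
## movement-related activity in an intact brain
contralateral_hemisphere <- function(paretic_side) {
  switch(paretic_side,
    right = "left",
    left = "right",
    abort(sprintf("Unknown paretic side '%s'; use \"left\" or \"right\".",
                  paretic_side))
  )
}
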