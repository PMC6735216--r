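## plain-text session container
##
##   #eegsession v1
##   #header {json: sampling_rate, channel_labels, montage fields, seed}
##   #events <n>
##   <n tab-separated event rows: sample  code  kind>
##   #signal <n_channels> <n_samples>
##   <n_samples rows x n_channels tab-separated columns, %.17g>
##
## doubles are written with 17 significant digits so read(write(x)) is
## bit-exact

#' Write a session to the plain-text container format
#'
#' @param session A [raw_session()].
#' @param path Output file path.
#' @param seed Optional creation seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, seed = NULL) {
  stopifnot(inherits(session, "raw_session"))
  header <- list(
    sampling_rate = session$sampling_rate,
    channel_labels = session$channel_labels
  )
  if (!is.null(session$montage)) {
    header$montage <- list(
      eog_index = session$montage$eog_index,
      reference_label = session$montage$reference_label,
      ground_label = session$montage$ground_label
    )
  }
  if (!is.null(seed)) header$seed <- seed
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("#eegsession v1", con)
  writeLines(paste0("#header ", jsonlite::toJSON(header, auto_unbox = TRUE)),
             con)
  ev <- session$events
  writeLines(sprintf("#events %d", nrow(ev)), con)
  if (nrow(ev) > 0) {
    writeLines(paste(ev$sample, ev$code, ev$kind, sep = "\t"), con)
  }
  writeLines(sprintf("#signal %d %d", nrow(session$signal),
                     ncol(session$signal)), con)
  ## one text row per sample, channels as columns
  txt <- matrix(sprintf("%.17g", t(session$signal)),
                ncol(session$signal), nrow(session$signal))
  writeLines(do.call(paste, c(asplit(txt, 2), list(sep = "\t"))), con)
  invisible(path)
}

#' Read a session from the plain-text container format
#'
#' @param path File written by [write_session()].
#' @return A [raw_session()]. The montage header, if present, is restored.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such session file: %s", path))
  lines <- readLines(path)
  if (length(lines) < 3L || lines[1] != "#eegsession v1") {
    abort("malformed session file: missing '#eegsession v1' magic line.")
  }
  if (!startsWith(lines[2], "#header ")) {
    abort("malformed session file: missing '#header' line.")
  }
  header <- jsonlite::fromJSON(sub("^#header ", "", lines[2]))
  if (is.null(header$sampling_rate)) {
    abort("malformed session header: field 'sampling_rate' missing.")
  }
  if (is.null(header$channel_labels)) {
    abort("malformed session header: field 'channel_labels' missing.")
  }
  ev_head <- strsplit(lines[3], " ")[[1]]
  if (ev_head[1] != "#events") {
    abort("malformed session file: missing '#events' line.")
  }
  n_events <- as.integer(ev_head[2])
  ev_lines <- if (n_events > 0) lines[3L + seq_len(n_events)] else character()
  sig_at <- 4L + n_events
  if (sig_at > length(lines) || !startsWith(lines[sig_at], "#signal")) {
    abort("malformed session file: missing '#signal' line.")
  }
  sig_head <- strsplit(lines[sig_at], " ")[[1]]
  n_ch <- as.integer(sig_head[2])
  n_samp <- as.integer(sig_head[3])
  if (n_ch != length(header$channel_labels)) {
    abort("malformed session header: field 'channel_labels' does not match the signal channel count.")
  }
  sig_lines <- lines[seq.int(sig_at + 1L, length.out = length(lines) - sig_at)]
  sig_lines <- sig_lines[nzchar(sig_lines)]
  if (length(sig_lines) != n_samp) {
    abort(sprintf(
      "truncated signal payload: expected %d sample rows, found %d.",
      n_samp, length(sig_lines)
    ))
  }
  vals <- scan(text = sig_lines, what = numeric(), sep = "\t", quiet = TRUE)
  if (length(vals) != n_ch * n_samp) {
    abort("truncated signal payload: sample row width does not match the channel count.")
  }
  signal <- matrix(vals, n_ch, n_samp)
  events <- if (n_events > 0) {
    parts <- strsplit(ev_lines, "\t")
    tibble(
      sample = as.integer(vapply(parts, `[[`, "", 1L)),
      code = vapply(parts, `[[`, "", 2L),
      kind = vapply(parts, `[[`, "", 3L)
    )
  } else {
    empty_events()
  }
  montage <- NULL
  if (!is.null(header$montage)) {
    montage <- standard_montage(eog_index = header$montage$eog_index)
    if (!identical(montage$labels, as.character(header$channel_labels))) {
      ## labels differ from the package montage (e.g. EOG already dropped);
      ## keep the montage for its metadata but do not enforce its label order
      montage$labels <- as.character(header$channel_labels)
    }
  }
  raw_session(signal, header$sampling_rate,
              as.character(header$channel_labels), events, montage)
}
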