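# Minimal European Data Format (EDF) writer/reader for continuous EEG.
# Covers the subset this package produces: uninterrupted signals, one-second
# data records, identical sampling rate on every channel, 16-bit samples.
# Header date/time fields are fixed so regeneration is byte-identical.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too wide: ", x)
  formatC(x, width = -width)
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16 bits over a per-channel symmetric physical
#' range covering the data, which bounds the round-trip error by
#' `range/32767` microvolts. The session duration must be a whole number of
#' seconds (one-second data records).
#'
#' @param recording An `eeg_recording`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_edf <- function(recording, file) {
  fs <- recording$sampling_rate
  sig <- recording$signal
  nch <- nrow(sig)
  n <- ncol(sig)
  if (fs != round(fs)) stop("write_edf needs an integer sampling rate")
  n_rec <- n / fs
  if (n_rec != round(n_rec))
    stop("recording length must be a whole number of seconds")
  phys_max <- pmax(1, ceiling(apply(abs(sig), 1, max)))
  dig_max <- 32767L

  con <- file(file, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_field(x, width), con, width, eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)                       # local patient id (anonymous)
  wr("Startdate 01-JAN-2000 X X X", 80)   # local recording id
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 * (1 + nch), 8)
  wr("", 44)
  wr(n_rec, 8)
  wr(1, 8)
  wr(nch, 4)
  for (ch in recording$channel_labels) wr(paste("EEG", ch), 16)
  for (i in seq_len(nch)) wr("AgAgCl electrode", 80)
  for (i in seq_len(nch)) wr("uV", 8)
  for (i in seq_len(nch)) wr(-phys_max[i], 8)
  for (i in seq_len(nch)) wr(phys_max[i], 8)
  for (i in seq_len(nch)) wr(-dig_max, 8)
  for (i in seq_len(nch)) wr(dig_max, 8)
  for (i in seq_len(nch)) wr("", 80)
  for (i in seq_len(nch)) wr(fs, 8)
  for (i in seq_len(nch)) wr("", 32)

  scale <- dig_max / phys_max
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    block <- round(sig[, cols, drop = FALSE] * scale)
    block <- pmin(pmax(block, -dig_max), dig_max)
    writeBin(as.integer(t(block)), con, size = 2L, endian = "little")
  }
  invisible(file)
}

#' Read an EDF file written by this package (or any single-rate EDF)
#'
#' @param file Path to an EDF file.
#' @return An `eeg_recording`.
#' @export
read_edf <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                    # version
  rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.numeric(rd(8))
  rd(44)
  n_rec <- as.numeric(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  if (!is.finite(nch) || nch < 1) stop("malformed EDF header")
  labels <- vapply(seq_len(nch), function(i) rd(16), "")
  for (i in seq_len(nch)) rd(80)
  for (i in seq_len(nch)) rd(8)
  phys_min <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  phys_max <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  dig_min <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  dig_max <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(nch)) rd(80)
  spr <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(nch)) rd(32)
  if (length(unique(spr)) != 1)
    stop("read_edf supports a single sampling rate across channels")
  if (header_bytes != 256 * (1 + nch)) stop("malformed EDF header size")
  fs <- spr[1] / rec_dur

  n_per_rec <- sum(spr)
  sig <- matrix(0, nch, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = n_per_rec, size = 2L,
                   endian = "little")
    if (length(raw) < n_per_rec) stop("EDF data truncated at record ", r)
    block <- matrix(raw, nrow = spr[1], ncol = nch)
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    sig[, cols] <- t(block)
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  sig <- sig * gain + (phys_min - dig_min * gain)
  labels <- sub("^EEG ", "", labels)
  new_recording(sig, fs, labels)
}

#' Write / read a simulated dataset (signal + events sidecar)
#'
#' `write_dataset()` stores the continuous signal as `recording.edf` (or
#' `recording.tsv`, a plain-text samples-by-channels matrix) plus a
#' BIDS-style `events.tsv` sidecar with columns `onset`, `kind`,
#' `condition`, `value`, and a small `meta.json`. `read_dataset()` restores
#' both; the signal round-trips to within the format quantization.
#'
#' @param recording An `eeg_recording`.
#' @param events An event stream data.frame.
#' @param path Directory to create/use.
#' @param format `"edf"` or `"tsv"`.
#' @param sort_events On read: sort unsorted event onsets (`TRUE`) or fail.
#' @return `write_dataset()`: `path` invisibly. `read_dataset()`:
#'   `list(recording=, events=)`.
#' @export
write_dataset <- function(recording, events, path, format = c("edf", "tsv")) {
  format <- match.arg(format)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (format == "edf") {
    write_edf(recording, file.path(path, "recording.edf"))
  } else {
    df <- as.data.frame(t(recording$signal))
    names(df) <- recording$channel_labels
    write.table(format(df, digits = 8, trim = TRUE, scientific = FALSE),
                file.path(path, "recording.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  ev <- as.data.frame(events)
  ev$onset <- sprintf("%.6f", ev$onset)
  write.table(ev, file.path(path, "events.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "n/a")
  jsonlite::write_json(
    list(sampling_rate = recording$sampling_rate,
         channels = recording$channel_labels,
         units = "uV", format = format),
    file.path(path, "meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path, sort_events = TRUE) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  if (identical(meta$format, "edf")) {
    rec <- read_edf(file.path(path, "recording.edf"))
    if (!isTRUE(all.equal(rec$sampling_rate, meta$sampling_rate)))
      stop("sampling rate in meta.json does not match the EDF header")
  } else {
    df <- read.delim(file.path(path, "recording.tsv"), check.names = FALSE)
    rec <- new_recording(t(as.matrix(df)), meta$sampling_rate, names(df))
  }
  ev_path <- file.path(path, "events.tsv")
  if (!file.exists(ev_path)) stop("events sidecar missing: ", ev_path)
  ev <- read.delim(ev_path, na.strings = "n/a", stringsAsFactors = FALSE)
  required <- c("onset", "kind", "condition")
  if (!all(required %in% names(ev)))
    stop("malformed events sidecar; needs columns ",
         paste(required, collapse = ", "))
  if (!is.numeric(ev$onset) || anyNA(ev$onset))
    stop("malformed events sidecar: non-numeric onset")
  if (is.unsorted(ev$onset)) {
    if (sort_events) ev <- ev[order(ev$onset), , drop = FALSE]
    else stop("event onsets are not sorted")
  }
  dur <- ncol(rec$signal) / rec$sampling_rate
  if (any(ev$onset < 0 | ev$onset > dur))
    stop("event onsets fall outside the recording")
  rownames(ev) <- NULL
  class(ev) <- c("event_stream", "data.frame")
  list(recording = rec, events = ev)
}
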