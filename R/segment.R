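# Response-locked epoch segmentation and artifact rejection.
#
# Conventions: an event at time t (seconds) maps to 0-based sample
# round(t * fs); an epoch spans the half-open sample interval
# [demarcation - pre*fs, demarcation + post*fs), i.e. exactly
# (pre + post) * fs samples, so boundary counting is unambiguous.

new_epoch_set <- function(data, time_ms, sampling_rate, channel_labels,
                          demarcation, condition, onsets) {
  es <- list(data = data, time = time_ms, sampling_rate = sampling_rate,
             channel_labels = channel_labels, demarcation = demarcation,
             condition = condition, onsets = onsets,
             rejected = rep(FALSE, dim(data)[3]),
             reject_reason = rep(NA_character_, dim(data)[3]))
  class(es) <- "epoch_set"
  es
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials (%d rejected), %d channels, %d samples [%g..%g ms], locked to %s\n",
              n_epochs(x), sum(x$rejected), dim(x$data)[1], dim(x$data)[2],
              min(x$time), max(x$time) + 1000 / x$sampling_rate, x$demarcation))
  invisible(x)
}

#' Number of epochs in an epoch set
#' @param x An `epoch_set`.
#' @param surviving Count only trials not flagged as rejected.
#' @return Integer count.
#' @export
n_epochs <- function(x, surviving = FALSE) {
  if (surviving) sum(!x$rejected) else dim(x$data)[3]
}

#' Keep a subset of trials of an epoch set
#' @param x An `epoch_set`.
#' @param idx Trial indices to keep.
#' @return The subset `epoch_set`.
#' @export
subset_epochs <- function(x, idx) {
  x$data <- x$data[, , idx, drop = FALSE]
  x$onsets <- x$onsets[idx]
  x$rejected <- x$rejected[idx]
  x$reject_reason <- x$reject_reason[idx]
  x
}

epoch_span_samples <- function(onsets, fs, pre, post) {
  i0 <- round(onsets * fs)
  cbind(lo = i0 - round(pre * fs), hi = i0 + round(post * fs)) # half-open
}

cut_epochs <- function(recording, onsets, pre, post, demarcation, condition) {
  fs <- recording$sampling_rate
  n <- ncol(recording$signal)
  span <- epoch_span_samples(onsets, fs, pre, post)
  inside <- span[, "lo"] >= 0 & span[, "hi"] <= n
  onsets <- onsets[inside]
  span <- span[inside, , drop = FALSE]
  len <- round((pre + post) * fs)
  data <- array(0, c(nrow(recording$signal), len, length(onsets)))
  for (k in seq_along(onsets))
    data[, , k] <- recording$signal[, (span[k, "lo"] + 1L):span[k, "hi"], drop = FALSE]
  time_ms <- (seq_len(len) - 1 - round(pre * fs)) / fs * 1000
  new_epoch_set(data, time_ms, fs, recording$channel_labels,
                demarcation, condition, onsets)
}

#' Extract response-locked reversal epochs
#'
#' Cuts one epoch per button press, spanning 3,000 ms before to 2,000 ms
#' after the press (half-open on the right). Epochs whose window contains
#' any other button press are excluded, to avoid post-motor contamination;
#' epochs truncated by the recording edges are dropped.
#'
#' @param recording An `eeg_recording`.
#' @param events Event stream containing `button_press` rows.
#' @param condition Optional condition label filter.
#' @param pre,post Window extent before/after the press, seconds.
#' @return An `epoch_set` locked to the button press. Empty (with a warning)
#'   when there are no presses.
#' @export
extract_reversal_epochs <- function(recording, events, condition = NULL,
                                    pre = 3, post = 2) {
  ev <- as.data.frame(events)
  if (!is.null(condition)) ev <- ev[ev$condition == condition, , drop = FALSE]
  presses <- ev$onset[ev$kind == "button_press"]
  cond <- condition %||% (if (nrow(ev)) ev$condition[1] else NA_character_)
  if (length(presses) == 0) {
    warning("no button presses; returning an empty epoch set")
    return(cut_epochs(recording, numeric(0), pre, post, "button_press", cond))
  }
  fs <- recording$sampling_rate
  i_press <- round(presses * fs)
  span <- epoch_span_samples(presses, fs, pre, post)
  solitary <- vapply(seq_along(presses), function(k) {
    sum(i_press >= span[k, "lo"] & i_press < span[k, "hi"]) == 1L
  }, TRUE)
  cut_epochs(recording, presses[solitary], pre, post, "button_press", cond)
}

#' Extract non-reversal (perceptual stability) epochs
#'
#' Candidate epochs are anchored on the artificial stimulus markers placed
#' every 250 ms (synthesized at that cadence when the event stream carries
#' none) and use the same -3,000..+2,000 ms layout as reversal epochs, with
#' the anchoring marker at 0 ms. Scanning markers left to right, a candidate
#' is kept if it contains no button press, does not overlap any reversal
#' epoch, and does not overlap a previously accepted non-reversal epoch.
#' The greedy earliest-first scan is deterministic and maximal for the fixed
#' marker grid.
#'
#' @param recording An `eeg_recording`.
#' @param events Event stream.
#' @param reversal_epochs The retained reversal `epoch_set` to avoid.
#' @param pre,post Window extent around the anchoring marker, seconds.
#' @return An `epoch_set` locked to the artificial marker.
#' @export
extract_nonreversal_epochs <- function(recording, events, reversal_epochs,
                                       pre = 3, post = 2) {
  fs <- recording$sampling_rate
  n <- ncol(recording$signal)
  ev <- as.data.frame(events)
  markers <- sort(ev$onset[ev$kind == "stimulus_frame"])
  if (length(markers) == 0)
    markers <- seq(0.25, n / fs - 0.25, by = 0.25)
  i_press <- round(ev$onset[ev$kind == "button_press"] * fs)
  rev_span <- epoch_span_samples(reversal_epochs$onsets, fs, 3, 2)

  span <- epoch_span_samples(markers, fs, pre, post)
  keep <- logical(length(markers))
  last_hi <- -Inf
  for (k in seq_along(markers)) {
    lo <- span[k, "lo"]; hi <- span[k, "hi"]
    if (lo < 0 || hi > n) next
    if (lo < last_hi) next
    if (any(i_press >= lo & i_press < hi)) next
    if (nrow(rev_span) &&
        any(rev_span[, "lo"] < hi & rev_span[, "hi"] > lo)) next
    keep[k] <- TRUE
    last_hi <- hi
  }
  cond <- if (nrow(ev)) ev$condition[1] else NA_character_
  cut_epochs(recording, markers[keep], pre, post, "artificial_marker", cond)
}

#' Flag artifact-contaminated epochs
#'
#' A trial is rejected when any analyzed channel exceeds the +/-`threshold`
#' amplitude bound inside the inspection window (-1,500 to +200 ms around
#' the demarcation by default), catching spikes, large drifts and blink
#' deflections. Optionally, a blink-template correlation on an EOG channel
#' adds a second rejection route. Flags carry reasons; data are kept so the
#' decision is auditable.
#'
#' @param epochs An `epoch_set`.
#' @param window Inspection window, ms relative to demarcation, half-open.
#' @param threshold Amplitude bound in microvolts (> 0).
#' @param eog_channel Optional channel label used for blink detection.
#' @param eog_cutoff Correlation cutoff for the blink template.
#' @return The `epoch_set` with updated `rejected` / `reject_reason`.
#' @export
reject_artifacts <- function(epochs, window = c(-1500, 200), threshold = 100,
                             eog_channel = NULL, eog_cutoff = 0.7) {
  if (threshold <= 0) stop("threshold must be positive")
  if (window[1] < min(epochs$time) ||
      window[2] > max(epochs$time) + 1000 / epochs$sampling_rate)
    stop("inspection window exceeds the epoch span")
  idx <- window_index(epochs$time, window)
  chans <- seq_along(epochs$channel_labels)
  if (!is.null(eog_channel))
    chans <- setdiff(chans, match(eog_channel, epochs$channel_labels))
  for (k in seq_len(n_epochs(epochs))) {
    seg <- epochs$data[chans, idx, k, drop = FALSE]
    if (any(abs(seg) > threshold)) {
      epochs$rejected[k] <- TRUE
      epochs$reject_reason[k] <- "amplitude"
      next
    }
    if (!is.null(eog_channel)) {
      ei <- match(eog_channel, epochs$channel_labels)
      x <- epochs$data[ei, idx, k]
      tmpl <- blink_template(length(idx), epochs$sampling_rate)
      cc <- suppressWarnings(max(abs(stats::ccf(x, tmpl, plot = FALSE,
                                                lag.max = length(idx) %/% 4)$acf)))
      if (is.finite(cc) && cc > eog_cutoff) {
        epochs$rejected[k] <- TRUE
        epochs$reject_reason[k] <- "blink"
      }
    }
  }
  epochs
}

blink_template <- function(n, fs) {
  tt <- (seq_len(n) - n / 2) / fs
  exp(-tt^2 / (2 * 0.08^2))
}

#' Equalize epoch counts across subjects by seeded random exclusion
#'
#' Randomly subsamples each subject's surviving epochs down to a common
#' target so that epoch counts cannot confound group comparisons. The
#' default policy takes the minimum surviving count over subjects; a fixed
#' target may be supplied instead. Subjects with no surviving epochs are
#' excluded and reported in the `"dropped"` attribute. Reproducible from
#' the seed.
#'
#' @param epoch_sets Named list of `epoch_set` objects, one per subject.
#' @param policy `"min"` or `"target"`.
#' @param target Target count when `policy = "target"`.
#' @param seed Integer seed.
#' @return Named list of subsampled epoch sets (rejected trials removed),
#'   with attribute `"dropped"` naming excluded subjects.
#' @export
equalize_epoch_counts <- function(epoch_sets, policy = c("min", "target"),
                                  target = NULL, seed = 1L) {
  policy <- match.arg(policy)
  counts <- vapply(epoch_sets, n_epochs, 0L, surviving = TRUE)
  dropped <- names(counts)[counts == 0]
  if (length(dropped))
    warning("subjects with no surviving epochs excluded: ",
            paste(dropped, collapse = ", "))
  keep_subj <- counts > 0
  counts <- counts[keep_subj]
  if (!length(counts)) stop("no subject has surviving epochs")
  tgt <- switch(policy, min = min(counts),
                target = {
                  stopifnot(!is.null(target), target >= 1)
                  target
                })
  idx_list <- equalize_indices(counts, tgt, seed)
  out <- Map(function(es, idx) {
    surv <- which(!es$rejected)
    subset_epochs(es, surv[idx])
  }, epoch_sets[keep_subj], idx_list)
  attr(out, "dropped") <- dropped
  attr(out, "target") <- tgt
  out
}

#' Serialize an epoch set to a flat binary container plus JSON metadata
#'
#' Writes `epochs.bin` (little-endian doubles in channel-fastest order) and
#' `epochs.json` (dimensions, time axis, labels, rejection flags) into a
#' directory; `read_epochs()` restores the object exactly.
#'
#' @param epochs An `epoch_set`.
#' @param path Directory to create/use.
#' @return `path` (write) or the restored `epoch_set` (read).
#' @export
write_epochs <- function(epochs, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(path, "epochs.bin"), "wb")
  writeBin(as.vector(epochs$data), con, size = 8L, endian = "little")
  close(con)
  meta <- epochs[setdiff(names(epochs), "data")]
  meta$dim <- dim(epochs$data)
  jsonlite::write_json(meta, file.path(path, "epochs.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "epochs.json"),
                              simplifyVector = TRUE)
  n <- prod(meta$dim)
  con <- file(file.path(path, "epochs.bin"), "rb")
  data <- readBin(con, "numeric", n = n, size = 8L, endian = "little")
  close(con)
  if (length(data) != n) stop("epoch container truncated")
  es <- list(data = array(data, meta$dim), time = meta$time,
             sampling_rate = meta$sampling_rate,
             channel_labels = meta$channel_labels,
             demarcation = meta$demarcation, condition = meta$condition,
             onsets = as.numeric(meta$onsets),
             rejected = as.logical(meta$rejected),
             reject_reason = as.character(meta$reject_reason))
  class(es) <- "epoch_set"
  es
}

# Seeded choice of retained (sorted) indices per subject; shared by the
# epoch-set route above and the pipeline's aggregate route, so both make
# identical draws.
equalize_indices <- function(counts, target, seed) {
  out <- vector("list", length(counts))
  names(out) <- names(counts)
  for (i in seq_along(counts)) {
    set.seed(derive_seed(seed, "equalize", names(counts)[i] %||% i, i))
    k <- min(counts[i], target)
    out[[i]] <- sort(sample.int(counts[i], k))
  }
  out
}
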