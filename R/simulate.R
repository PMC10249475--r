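# Synthetic continuous EEG with event-locked alpha desynchronization.
#
# The generator emulates one recording session of the two stroboscopic
# alternative motion (SAM) tasks: an endogenous condition in which the
# observer reports spontaneous perceptual reversals at stochastic dwell
# times, and an exogenous control condition in which the stimulus itself
# reverses at a fixed rate and the observer responds with a lagged button
# press. Each channel carries 1/f background noise plus a narrow-band alpha
# oscillation whose envelope is suppressed around each button press
# (event-related desynchronization, ERD).

#' Group behavioral and spectral profiles
#'
#' Default parameters for the two age groups: mean endogenous reversal rate
#' (per minute) and its between-subject SD, exogenous reaction time mean/SD
#' (seconds, between subjects), within-subject reaction-time SD, response
#' accuracy (percent of exogenous motion changes answered), and per-ROI
#' alpha-suppression depths (dB) for each condition. Young adults show
#' posterior-dominant suppression during endogenous reversals; older adults
#' show an anteriorized pattern; both groups show posterior suppression in
#' the exogenous condition.
#'
#' @param group `"young"` or `"older"`.
#' @return Named list of profile parameters.
#' @export
group_profile <- function(group = c("young", "older")) {
  group <- match.arg(group)
  if (group == "young") {
    list(group = "young",
         reversal_rate = 7.18, reversal_rate_sd = 1.97,
         rt_mean = 0.58, rt_between_sd = 0.09, rt_within_sd = 0.09,
         accuracy = 98.55,
         erd_roi = list(
           endogenous = c(F = 0, C = -0.3, P = -1.2, O = -2.0),
           # the stimulus-driven posterior response is shared across groups
           exogenous  = c(F = 0, C = -0.2, P = -0.8, O = -1.3)))
  } else {
    list(group = "older",
         reversal_rate = 4.83, reversal_rate_sd = 2.26,
         rt_mean = 0.78, rt_between_sd = 0.22, rt_within_sd = 0.12,
         accuracy = 93.46,
         erd_roi = list(
           endogenous = c(F = -1.5, C = -1.5, P = -1.2, O = -0.3),
           exogenous  = c(F = 0, C = -0.2, P = -0.8, O = -1.3)))
  }
}

# Expand a per-ROI named vector (F/C/P/O) to per-channel values.
expand_roi <- function(x, channels) {
  pairs <- roi_pairs()
  out <- setNames(numeric(length(channels)), channels)
  for (roi in names(pairs)) {
    hit <- channels %in% pairs[[roi]]
    if (any(hit) && roi %in% names(x)) out[hit] <- x[[roi]]
  }
  out
}

#' Build a simulation configuration
#'
#' Collects every tunable of the synthetic-session generator. Defaults
#' reproduce the study conditions: 10-minute sessions sampled at 500 Hz on
#' eight 10-20 channels, an 11 Hz alpha rhythm with a posterior > frontal
#' amplitude gradient, gamma-distributed endogenous dwell times, eight
#' exogenous reversals per minute, and an ERD whose ramp begins 1 s before
#' the button press with recovery complete 0.5 s after it.
#'
#' @param condition `"endogenous"` (spontaneous reversals) or `"exogenous"`
#'   (stimulus-driven reversals).
#' @param group `"young"` or `"older"`; fills behavioral and topography
#'   defaults from [group_profile()].
#' @param sampling_rate Sampling rate, Hz.
#' @param session_duration Session length, seconds (whole seconds).
#' @param channels Ordered channel labels (no duplicates).
#' @param dwell_shape Gamma shape of endogenous inter-reversal intervals.
#'   Dwell times of multistable perception are positively skewed; a gamma
#'   with shape 3 is a standard choice. Scale is set from `reversal_rate`.
#' @param reversal_rate Endogenous reversal rate, per minute.
#' @param exogenous_rate Exogenous motion-change rate, per minute.
#' @param rt_mean,rt_sd Mean and SD (s) of the press latency after an
#'   exogenous motion change (within-session variability).
#' @param accuracy Percent of exogenous motion changes answered with the
#'   correct direction; unanswered changes are omissions.
#' @param alpha_center Alpha center frequency, Hz.
#' @param alpha_rms Per-channel alpha RMS amplitude, microvolts. A named
#'   vector over `channels`, or a per-ROI vector named F/C/P/O.
#' @param erd_depth Per-channel ERD depth in dB (values must be <= 0); a
#'   named vector over `channels` or per-ROI (F/C/P/O). `NULL` uses the
#'   group/condition default from [group_profile()].
#' @param erd_onset Seconds before the press at which the suppression ramp
#'   begins.
#' @param erd_plateau Length-2 vector, seconds relative to the press, over
#'   which suppression sits at full depth.
#' @param erd_offset Seconds after the press at which recovery is complete.
#' @param noise_rms 1/f background-noise RMS amplitude, microvolts.
#' @param artifact_rates Named numeric `c(blink=, spike=, drift=)`, events
#'   per minute.
#' @param seed Integer seed controlling all stochastic draws.
#' @return Object of class `"simulation_config"` (a named list).
#' @examples
#' cfg <- simulation_config(condition = "endogenous", group = "young", seed = 1)
#' cfg$reversal_rate
#' @export
simulation_config <- function(condition = c("endogenous", "exogenous"),
                              group = c("young", "older"),
                              sampling_rate = 500,
                              session_duration = 600,
                              channels = default_channels(),
                              dwell_shape = 3,
                              reversal_rate = NULL,
                              exogenous_rate = 8,
                              rt_mean = NULL,
                              rt_sd = NULL,
                              accuracy = NULL,
                              alpha_center = 11,
                              alpha_rms = c(F = 6, C = 7, P = 10, O = 10),
                              erd_depth = NULL,
                              erd_onset = NULL,
                              erd_plateau = NULL,
                              erd_offset = NULL,
                              noise_rms = 4,
                              artifact_rates = c(blink = 0, spike = 0, drift = 0),
                              seed = 1L) {
  condition <- match.arg(condition)
  group <- match.arg(group)
  prof <- group_profile(group)
  stopifnot(sampling_rate > 0, session_duration > 0,
            session_duration == round(session_duration),
            length(channels) >= 1, !anyDuplicated(channels),
            dwell_shape > 0, exogenous_rate >= 0, alpha_center > 0,
            noise_rms >= 0, all(artifact_rates >= 0))
  # the exogenous alpha response is steeper and shorter than the endogenous one
  if (is.null(erd_onset))   erd_onset   <- if (condition == "endogenous") 1.0 else 0.6
  if (is.null(erd_plateau)) erd_plateau <- if (condition == "endogenous") c(-0.6, 0.1) else c(-0.35, 0.1)
  if (is.null(erd_offset))  erd_offset  <- if (condition == "endogenous") 0.5 else 0.4
  stopifnot(erd_onset > 0, erd_offset > 0,
            -erd_onset < erd_plateau[1], erd_plateau[1] <= erd_plateau[2],
            erd_plateau[2] < erd_offset)

  to_channels <- function(x) {
    if (is.null(names(x)) || any(names(x) == ""))
      stop("per-channel parameters must be fully named ",
           "(channel labels or ROI labels F/C/P/O)")
    if (all(names(x) %in% names(roi_pairs()))) {
      stopifnot(all(names(roi_pairs()) %in% names(x)))
      expand_roi(x, channels)
    } else {
      stopifnot(all(channels %in% names(x)))
      x[channels]
    }
  }
  erd_depth <- to_channels(erd_depth %||% prof$erd_roi[[condition]])
  if (any(erd_depth > 0))
    stop("erd_depth must be <= 0 dB (a suppression) on every channel")
  alpha_rms <- to_channels(alpha_rms)

  cfg <- list(condition = condition, group = group,
              sampling_rate = sampling_rate,
              session_duration = session_duration,
              channels = channels,
              dwell_shape = dwell_shape,
              reversal_rate = reversal_rate %||% prof$reversal_rate,
              exogenous_rate = exogenous_rate,
              rt_mean = rt_mean %||% prof$rt_mean,
              rt_sd = rt_sd %||% prof$rt_within_sd,
              accuracy = accuracy %||% prof$accuracy,
              alpha_center = alpha_center,
              alpha_rms = alpha_rms,
              erd_depth = erd_depth,
              erd_onset = erd_onset,
              erd_plateau = erd_plateau,
              erd_offset = erd_offset,
              noise_rms = noise_rms,
              artifact_rates = artifact_rates,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

#' Build an EEG recording object from a signal matrix
#'
#' @param signal Channels x samples numeric matrix, microvolts.
#' @param sampling_rate Sampling rate, Hz.
#' @param channel_labels Channel names (defaults to rownames or Ch1..ChN).
#' @return An `eeg_recording`.
#' @export
as_recording <- function(signal, sampling_rate,
                         channel_labels = rownames(signal)) {
  if (is.null(channel_labels))
    channel_labels <- paste0("Ch", seq_len(nrow(signal)))
  stopifnot(all(is.finite(signal)))
  new_recording(signal, sampling_rate, channel_labels)
}

new_recording <- function(signal, sampling_rate, channel_labels,
                          start_time = 0, alpha_component = NULL) {
  stopifnot(is.matrix(signal), nrow(signal) == length(channel_labels))
  rec <- list(signal = signal, sampling_rate = sampling_rate,
              channel_labels = channel_labels, start_time = start_time)
  attr(rec, "alpha_component") <- alpha_component
  class(rec) <- "eeg_recording"
  rec
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$signal), ncol(x$signal), x$sampling_rate,
              ncol(x$signal) / x$sampling_rate))
  cat(" channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

new_event_stream <- function(onset, kind, condition, value = NA_character_) {
  ev <- data.frame(onset = onset, kind = kind, condition = condition,
                   value = value, stringsAsFactors = FALSE)
  ev <- ev[order(ev$onset), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("event_stream", "data.frame")
  ev
}

# Smooth ERD gain profile h(tau) in [0, 1]: half-Gaussian ramp from
# -onset to the plateau, full depth over the plateau, half-Gaussian
# recovery finishing at +offset. tau in seconds relative to the press.
erd_profile <- function(tau, onset, plateau, offset) {
  s_on <- (plateau[1] + onset) / 3
  s_off <- (offset - plateau[2]) / 3
  h <- numeric(length(tau))
  pre <- tau < plateau[1]
  mid <- tau >= plateau[1] & tau <= plateau[2]
  post <- tau > plateau[2]
  h[pre] <- exp(-(tau[pre] - plateau[1])^2 / (2 * s_on^2))
  h[mid] <- 1
  h[post] <- exp(-(tau[post] - plateau[2])^2 / (2 * s_off^2))
  h[tau < -onset | tau > offset] <- 0
  h
}

#' Suppress the alpha envelope around button presses
#'
#' Multiplies the oscillatory (alpha) component of a synthetic recording,
#' around each button press, by a smooth gain window whose floor equals
#' `10^(depth/20)` so that an injected depth of d dB produces a d dB drop in
#' alpha power at full suppression. Overlapping windows multiply. The signal
#' outside ERD windows is unchanged. Only recordings produced by
#' [generate_session()] (which track their alpha component) can be modified.
#'
#' @param recording An `eeg_recording` carrying an alpha component.
#' @param events An event stream with at least one `button_press`.
#' @param depth_db Per-channel depth in dB (<= 0), named over the recording's
#'   channels or per-ROI (F/C/P/O).
#' @param onset,plateau,offset ERD time profile, seconds relative to the
#'   press (see [simulation_config()]).
#' @return The modified `eeg_recording`.
#' @export
inject_erd <- function(recording, events, depth_db,
                       onset = 1.0, plateau = c(-0.6, 0.1), offset = 0.5) {
  alpha <- attr(recording, "alpha_component")
  if (is.null(alpha))
    stop("recording does not track an alpha component; ",
         "ERD injection applies to simulator output")
  presses <- events$onset[events$kind == "button_press"]
  if (length(presses) == 0) stop("events contain no button press")
  if (all(names(depth_db) %in% names(roi_pairs())))
    depth_db <- expand_roi(depth_db, recording$channel_labels)
  depth_db <- depth_db[recording$channel_labels]
  stopifnot(all(depth_db <= 0))
  fs <- recording$sampling_rate
  n <- ncol(recording$signal)
  g0 <- 10^(depth_db / 20)
  log_gain <- matrix(0, nrow(alpha), n)
  sup <- seq(floor(-onset * fs), ceiling(offset * fs))
  h_sup <- erd_profile(sup / fs, onset, plateau, offset)
  for (tp in presses) {
    i0 <- round(tp * fs)
    idx <- i0 + sup
    keep <- idx >= 0 & idx < n
    w <- outer(g0 - 1, h_sup[keep]) + 1 # channels x window
    log_gain[, idx[keep] + 1L] <- log_gain[, idx[keep] + 1L] + log(w)
  }
  gain <- exp(log_gain)
  new_alpha <- alpha * gain
  recording$signal <- recording$signal - alpha + new_alpha
  attr(recording, "alpha_component") <- new_alpha
  recording
}

#' Add blink, spike and drift artifacts to a recording
#'
#' Adds, at Poisson-distributed times: blink-shaped frontal transients
#' (Gaussian bump, ~150 microvolt at frontal leads, attenuating towards
#' occipital), brief spikes exceeding +/-100 microvolts on a single channel,
#' and slow half-sine drifts reaching beyond +/-100 microvolts. Returns the
#' ground-truth log so downstream rejection recall is testable.
#'
#' @param recording An `eeg_recording`.
#' @param rates Named numeric `c(blink=, spike=, drift=)`, events/minute.
#' @param seed Integer seed.
#' @return `list(recording=, log=)`; the log is a data.frame with columns
#'   `time` (s), `kind`, `channel`, `amplitude` (microvolts).
#' @export
inject_artifacts <- function(recording, rates = c(blink = 2, spike = 0.3, drift = 0.2),
                             seed = 1L) {
  stopifnot(all(rates >= 0))
  fs <- recording$sampling_rate
  n <- ncol(recording$signal)
  minutes <- n / fs / 60
  chans <- recording$channel_labels
  set.seed(seed)
  log <- list()
  add <- function(kind) {
    k <- rpois(1, rates[[kind]] * minutes)
    if (k == 0) return(numeric(0))
    sort(runif(k, 0.5, n / fs - 0.5))
  }

  # blinks: frontal-weighted Gaussian bump, sigma 80 ms
  blink_gain <- expand_roi(c(F = 1, C = 0.5, P = 0.2, O = 0.1), chans)
  for (tb in add("blink")) {
    amp <- 150 * runif(1, 0.8, 1.3)
    idx <- round(tb * fs) + seq(-200L, 200L)
    idx <- idx[idx >= 0 & idx < n]
    bump <- amp * exp(-((idx / fs - tb)^2) / (2 * 0.08^2))
    recording$signal[, idx + 1L] <- recording$signal[, idx + 1L] +
      outer(blink_gain, bump)
    log[[length(log) + 1L]] <- data.frame(time = tb, kind = "blink",
                                          channel = "frontal", amplitude = amp)
  }
  # spikes: 1-3 samples, one channel, beyond the +/-100 uV rejection bound
  for (ts in add("spike")) {
    ch <- sample(length(chans), 1)
    amp <- sample(c(-1, 1), 1) * runif(1, 120, 200)
    idx <- round(ts * fs) + seq_len(sample(1:3, 1)) - 1L
    idx <- idx[idx < n]
    recording$signal[ch, idx + 1L] <- recording$signal[ch, idx + 1L] + amp
    log[[length(log) + 1L]] <- data.frame(time = ts, kind = "spike",
                                          channel = chans[ch], amplitude = amp)
  }
  # drifts: slow half-sine excursion over 2-5 s on one channel
  for (td in add("drift")) {
    ch <- sample(length(chans), 1)
    dur <- runif(1, 2, 5)
    amp <- sample(c(-1, 1), 1) * runif(1, 110, 160)
    idx <- round(td * fs) + seq_len(round(dur * fs)) - 1L
    idx <- idx[idx < n]
    recording$signal[ch, idx + 1L] <- recording$signal[ch, idx + 1L] +
      amp * sin(pi * seq_along(idx) / length(idx))
    log[[length(log) + 1L]] <- data.frame(time = td, kind = "drift",
                                          channel = chans[ch], amplitude = amp)
  }
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(time = numeric(0), kind = character(0),
               channel = character(0), amplitude = numeric(0))
  log <- log[order(log$time), , drop = FALSE]
  rownames(log) <- NULL
  list(recording = recording, log = log)
}

#' Generate one synthetic EEG session
#'
#' Builds a continuous multichannel recording (1/f background noise plus a
#' narrow-band alpha oscillation with small frequency jitter and slow
#' amplitude modulation) together with its event stream: stimulus-frame
#' markers every 250 ms, endogenous button presses at gamma-distributed
#' dwell times or exogenous motion changes at a fixed rate with lagged
#' presses, and event-locked alpha suppression around every press per the
#' config's ERD depth and time profile. Fully reproducible from the seed.
#'
#' @param config A [simulation_config()].
#' @return `list(recording=, events=, artifact_log=)`.
#' @examples
#' cfg <- simulation_config(condition = "exogenous", group = "young",
#'                          session_duration = 60, seed = 7)
#' ses <- generate_session(cfg)
#' nrow(ses$events[ses$events$kind == "motion_change", ])
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  fs <- config$sampling_rate
  dur <- config$session_duration
  n <- round(dur * fs)
  if (dur < 5 + 1 / fs)
    stop("session too short to contain a complete 5 s epoch")
  nch <- length(config$channels)
  ev <- generate_events(config)

  ## ---- continuous signal ----
  noise <- t(pink_noise(n, nch, fs, config$noise_rms))
  alpha <- matrix(0, nch, n)
  for (ch in seq_len(nch)) {
    f_inst <- config$alpha_center + 0.15 * slow_noise(n, fs, dt_knot = 0.5)
    phase <- 2 * pi * cumsum(f_inst) / fs + runif(1, 0, 2 * pi)
    # gentle waxing/waning (10% envelope CV on a 0.5 s scale): keeps the
    # rhythm realistic while leaving ~0.15 dB precision on 300 ms window
    # estimates at ~30 epochs
    m <- pmax(0.1, 1 + 0.10 * slow_noise(n, fs, dt_knot = 0.5))
    x <- m * cos(phase)
    alpha[ch, ] <- x / rms(x) * config$alpha_rms[[ch]]
  }
  rec <- new_recording(noise + alpha, fs, config$channels,
                       alpha_component = alpha)

  if (any(config$erd_depth < 0) && any(ev$kind == "button_press"))
    rec <- inject_erd(rec, ev, config$erd_depth, config$erd_onset,
                      config$erd_plateau, config$erd_offset)

  art_log <- NULL
  if (any(config$artifact_rates > 0)) {
    art <- inject_artifacts(rec, config$artifact_rates,
                            seed = derive_seed(config$seed, "artifacts"))
    rec <- art$recording
    art_log <- art$log
  }
  list(recording = rec, events = ev, artifact_log = art_log)
}

#' Generate only the event stream of a session
#'
#' The event-level part of [generate_session()]: stimulus-frame markers
#' every 250 ms plus endogenous button presses (gamma dwell times) or
#' exogenous motion changes with lagged presses. Sets the seed from the
#' config, so [generate_session()] (which draws events first, then the
#' signal) produces exactly this stream.
#'
#' @param config A [simulation_config()].
#' @return An event stream data.frame.
#' @export
generate_events <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  dur <- config$session_duration
  set.seed(config$seed)
  frame_times <- seq(0.25, dur - 0.25, by = 0.25)
  if (config$condition == "endogenous") {
    scale <- (60 / config$reversal_rate) / config$dwell_shape
    # draw comfortably more intervals than expected, then truncate
    k <- ceiling(dur / 60 * config$reversal_rate * 2 + 20)
    presses <- cumsum(rgamma(k, shape = config$dwell_shape, scale = scale))
    presses <- presses[presses < dur - 0.05]
    ev <- new_event_stream(
      onset = c(frame_times, presses),
      kind = c(rep("stimulus_frame", length(frame_times)),
               rep("button_press", length(presses))),
      condition = config$condition)
  } else {
    # exactly exogenous_rate changes per minute, at an unpredictable moment
    # within each cycle (stratified jitter); variable gaps also leave room
    # for 5-s stable epochs between reversal epochs
    interval <- 60 / config$exogenous_rate
    slots <- (seq_len(floor(dur / interval)) - 1) * interval
    changes <- slots + runif(length(slots), 0.5, interval - 0.5)
    answered <- runif(length(changes)) < config$accuracy / 100
    rt <- pmax(0.15, rnorm(length(changes), config$rt_mean, config$rt_sd))
    press_t <- (changes + rt)[answered]
    # a press landing after the next change is an omission
    nxt <- c(changes[-1], Inf)[answered]
    press_t <- press_t[press_t < nxt]
    press_t <- press_t[press_t < dur - 0.05]
    ev <- new_event_stream(
      onset = c(frame_times, changes, press_t),
      kind = c(rep("stimulus_frame", length(frame_times)),
               rep("motion_change", length(changes)),
               rep("button_press", length(press_t))),
      condition = config$condition,
      value = c(rep(NA_character_, length(frame_times) + length(changes)),
                rep("correct", length(press_t))))
  }
  ev
}
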