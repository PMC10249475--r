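# Shared fixtures, built once per test run.

# A quiet recording with known content: pure 11 Hz alpha on every channel,
# no noise, no ERD. Cheap to segment and transform.
flat_recording <- function(duration = 60, fs = 500,
                           channels = c("O1", "O2"), amp = 10) {
  tt <- (seq_len(duration * fs) - 1) / fs
  sig <- matrix(rep(amp * sqrt(2) * cos(2 * pi * 11 * tt),
                    each = length(channels)),
                nrow = length(channels))
  as_recording(sig, fs, channels)
}

# Event stream helper: presses plus the 250 ms marker grid.
events_with_presses <- function(presses, duration = 60,
                                condition = "endogenous") {
  frames <- seq(0.25, duration - 0.25, by = 0.25)
  ev <- data.frame(
    onset = c(frames, presses),
    kind = c(rep("stimulus_frame", length(frames)),
             rep("button_press", length(presses))),
    condition = condition, value = NA_character_)
  ev[order(ev$onset), ]
}

# Brute-force direct (time-domain) complex convolution, center-aligned:
# the independent oracle for convolve_fft.
direct_convolve <- function(x, wavelet) {
  k <- wavelet$values
  nk <- length(k)
  nx <- length(x)
  ic <- (nk + 1L) %/% 2L
  out <- complex(nx)
  xp <- c(rep(0, nk), x, rep(0, nk)) # xp[i] = x[i - nk]
  for (t in seq_len(nx)) {
    # linear convolution re-centered on the kernel peak:
    # out[t] = sum_s x[t + ic - s] * k[s]
    out[t] <- sum(k * xp[t + ic + nk - seq_len(nk)])
  }
  out
}

# Mann-Whitney U by exhaustive pair counting (ties count one half).
brute_force_u <- function(x, y) {
  u <- 0
  for (xi in x) u <- u + sum(xi > y) + 0.5 * sum(xi == y)
  u
}

# One mid-size session shared by several segmentation/timefreq tests.
shared <- new.env()
shared_session <- function() {
  if (is.null(shared$ses)) {
    cfg <- simulation_config("endogenous", "young",
                             erd_depth = c(F = 0, C = 0, P = 0, O = -3),
                             seed = 42)
    shared$cfg <- cfg
    shared$ses <- generate_session(cfg)
  }
  shared$ses
}
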