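# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed and a tag
#'
#' Deterministically maps a master seed plus an arbitrary character tag to an
#' integer in `[0, 2^31 - 2]`. Used to split independent random streams per
#' subject and per stage, so that adding subjects to a study never perturbs the
#' streams of existing ones.
#'
#' @param master Integer master seed.
#' @param ... Character or numeric tags identifying the sub-stream.
#' @return A single integer seed.
#' @examples
#' derive_seed(1, "subj01", "endogenous")
#' @export
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- 2147483647 # 2^31 - 1, prime
  tag <- paste(vapply(list(...), paste, "", collapse = "|"), collapse = "|")
  h <- (abs(master) %% m) * 7919 %% m
  for (code in utf8ToInt(tag)) h <- (h * 31 + code) %% m
  as.integer(h)
}

rms <- function(x) sqrt(mean(x^2))

# Half-open window [lo, hi) on a time axis, values in the axis' own units.
window_index <- function(time, window) {
  which(time >= window[1] & time < window[2])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gaussian-shaped low-frequency noise: unit-SD smooth signal built by linear
# interpolation of coarse knots (knot spacing `dt_knot` seconds).
slow_noise <- function(n, fs, dt_knot = 0.5) {
  kn <- max(3L, ceiling(n / fs / dt_knot) + 2L)
  knots <- rnorm(kn)
  x <- approx(seq(0, by = dt_knot, length.out = kn), knots,
              xout = (seq_len(n) - 1) / fs, rule = 2)$y
  s <- sd(x)
  if (s > 0) x / s else x
}

# 1/f ("pink") noise, flat below f_floor Hz, target RMS in signal units.
# One column per channel, generated with a single matrix FFT.
pink_noise <- function(n, n_channels, fs, rms_target, f_floor = 1) {
  nfft <- nextn(n, c(2L, 3L, 5L))
  freqs <- seq(0, fs - fs / nfft, by = fs / nfft)
  half <- seq_len(floor(nfft / 2) + 1L)
  shape <- 1 / sqrt(pmax(freqs[half], f_floor))
  shape[1] <- 0 # no DC
  re <- matrix(rnorm(length(half) * n_channels), ncol = n_channels)
  im <- matrix(rnorm(length(half) * n_channels), ncol = n_channels)
  spec <- complex(real = re, imaginary = im) * shape
  dim(spec) <- dim(re)
  full <- matrix(0 + 0i, nfft, n_channels)
  full[half, ] <- spec
  idx_conj <- seq(2L, length(half) - if (nfft %% 2L == 0L) 1L else 0L)
  full[nfft + 2L - idx_conj, ] <- Conj(spec[idx_conj, ])
  x <- Re(mvfft(full, inverse = TRUE)) / nfft
  x <- x[seq_len(n), , drop = FALSE]
  x <- sweep(x, 2L, apply(x, 2L, rms), "/")
  sweep(x, 2L, rep_len(rms_target, n_channels), "*")
}
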