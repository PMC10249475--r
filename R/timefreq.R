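# Complex Morlet wavelet time-frequency decomposition.
#
# A wavelet at center frequency f with n cycles is
#   psi(t) = exp(2*pi*i*f*t) * exp(-t^2 / (2*sigma^2)),  sigma = n/(2*pi*f),
# sampled on a symmetric support (default +/- 5 sigma) and rescaled to unit
# energy (sum |psi|^2 * dt = 1). Convolution is done in the frequency domain
# (FFT -> pointwise product -> inverse FFT) as zero-padded linear
# convolution, center-aligned so Z(t) corresponds to the kernel centered at
# t. Epochs are concatenated per channel before transformation and re-cut
# afterwards; results are exact except within one kernel half-width of the
# joins, which lie far outside the analysis windows.

#' Construct a complex Morlet wavelet kernel
#'
#' @param freq Center frequency, Hz (> 0).
#' @param n_cycles Number of cycles (>= 1); trades temporal for spectral
#'   resolution. `sigma = n_cycles / (2*pi*freq)` seconds.
#' @param sampling_rate Sampling rate, Hz.
#' @param support_sigma Half-support in units of sigma (>= 4).
#' @return Object of class `"morlet_wavelet"`: list with `values` (complex),
#'   `time` (s, symmetric about 0), `freq`, `n_cycles`, `sigma`,
#'   `sampling_rate`.
#' @examples
#' w <- make_wavelet(11, 7, 500)
#' sum(Mod(w$values)^2) / 500 # unit energy
#' @export
make_wavelet <- function(freq, n_cycles = 7, sampling_rate = 500,
                         support_sigma = 5) {
  stopifnot(freq > 0, n_cycles >= 1, sampling_rate > 0)
  if (support_sigma < 4)
    stop("support must cover at least 4 sigma for a faithful kernel")
  sigma <- n_cycles / (2 * pi * freq)
  half <- ceiling(support_sigma * sigma * sampling_rate)
  tt <- (-half:half) / sampling_rate
  psi <- exp(2i * pi * freq * tt) * exp(-tt^2 / (2 * sigma^2))
  psi <- psi / sqrt(sum(Mod(psi)^2) / sampling_rate) # unit energy
  # response magnitude to a matched unit-amplitude complex exponential;
  # |Z|^2 / (gain^2 / 2) restores mean-square (power) units of the input,
  # so a matched sinusoid of RMS r microvolts reads r^2 microvolt^2
  gain <- Re(sum(psi * exp(-2i * pi * freq * tt)))
  structure(list(values = psi, time = tt, freq = freq, n_cycles = n_cycles,
                 sigma = sigma, sampling_rate = sampling_rate, gain = gain),
            class = "morlet_wavelet")
}

#' Convolve a signal with a wavelet via the FFT
#'
#' Zero-padded linear convolution realized in the frequency domain, with the
#' output center-aligned: `Z[t]` is the inner product of the signal with the
#' kernel centered at sample `t`. Output length equals input length.
#'
#' @param x Numeric (or complex) signal vector, longer than the kernel.
#' @param wavelet A [make_wavelet()] kernel (matching sampling rate).
#' @return Complex vector of `length(x)`.
#' @export
convolve_fft <- function(x, wavelet) {
  if (length(x) == 0) stop("empty signal")
  k <- wavelet$values
  nk <- length(k)
  nx <- length(x)
  if (nx <= nk) stop("signal must be longer than the wavelet kernel")
  nfull <- nx + nk - 1L
  nfft <- nextn(nfull, c(2L, 3L, 5L))
  y <- fft(fft(c(x, rep(0, nfft - nx))) *
           fft(c(k, rep(0, nfft - nk))), inverse = TRUE) / nfft
  ic <- (nk + 1L) %/% 2L
  y[ic:(ic + nx - 1L)]
}

#' Time-frequency power of an epoch set
#'
#' Concatenates trials per channel, convolves with one Morlet kernel per
#' frequency, re-cuts trials, and averages single-trial power `|Z|^2`
#' across trials (see [compute_power()]).
#'
#' @param epochs An `epoch_set` (rejected trials are dropped).
#' @param freqs Frequency grid, Hz (default 8--14 in 0.25 steps).
#' @param n_cycles Wavelet cycles.
#' @return Object of class `"tfr_power"`: list with `power` (channels x
#'   frequencies x time, microvolt^2), `freqs`, `time` (ms), `n_trials`,
#'   `channel_labels`, `sampling_rate`, `normalized = FALSE`.
#' @export
tfr_epochs <- function(epochs, freqs = seq(8, 14, by = 0.25), n_cycles = 7) {
  keep <- which(!epochs$rejected)
  if (!length(keep)) stop("no surviving epochs to transform")
  data <- epochs$data[, , keep, drop = FALSE]
  nch <- dim(data)[1]; nt <- dim(data)[2]; ntr <- dim(data)[3]
  stopifnot(all(diff(freqs) > 0))
  pow <- array(0, c(nch, length(freqs), nt))
  kernels <- lapply(freqs, make_wavelet, n_cycles = n_cycles,
                    sampling_rate = epochs$sampling_rate)
  # one zero-padded FFT of the concatenated signal per channel, reused for
  # every frequency (linear convolution needs nfft >= ncat + max nk - 1)
  ncat <- nt * ntr
  nk <- vapply(kernels, function(k) length(k$values), 0L)
  nfft <- nextn(ncat + max(nk) - 1L, c(2L, 3L, 5L))
  Kf <- lapply(kernels, function(k)
    fft(c(k$values, rep(0, nfft - length(k$values)))))
  for (ch in seq_len(nch)) {
    xcat <- as.vector(data[ch, , ]) # trials appended in order
    Xf <- fft(c(xcat, rep(0, nfft - ncat)))
    for (fi in seq_along(freqs)) {
      y <- fft(Xf * Kf[[fi]], inverse = TRUE) / nfft
      ic <- (nk[fi] + 1L) %/% 2L
      z <- y[ic:(ic + ncat - 1L)]
      cal <- kernels[[fi]]$gain^2 / 2 # calibrate to microvolt^2 band power
      pow[ch, fi, ] <- rowMeans(matrix(Mod(z)^2, nt, ntr)) / cal
    }
  }
  structure(list(power = pow, freqs = freqs, time = epochs$time,
                 n_trials = ntr, channel_labels = epochs$channel_labels,
                 sampling_rate = epochs$sampling_rate, normalized = FALSE,
                 condition = epochs$condition),
            class = "tfr_power")
}

#' @export
print.tfr_power <- function(x, ...) {
  cat(sprintf("<tfr_power%s> %d channels x %d freqs [%g..%g Hz] x %d times, n = %d trials\n",
              if (x$normalized) " (dB)" else "", dim(x$power)[1],
              dim(x$power)[2], min(x$freqs), max(x$freqs), dim(x$power)[3],
              x$n_trials))
  invisible(x)
}

#' Trial-averaged power from single-trial complex coefficients
#'
#' `A(t) = mean_k |Z_k(t)|^2` over trials (the last array dimension).
#' The mean (not the sum) is used so that power is comparable across
#' differing trial counts, e.g. after epoch-count equalization.
#'
#' @param z Complex matrix (time x trials) or array with trials last.
#' @return Numeric array with the trial dimension dropped.
#' @export
compute_power <- function(z) {
  d <- dim(z)
  if (is.null(d) || d[length(d)] == 0) stop("need at least one trial")
  p <- Mod(z)^2
  if (length(d) == 2) rowMeans(p)
  else apply(p, seq_len(length(d) - 1L), mean)
}

#' Baseline power per channel and frequency
#'
#' Time-mean of (trial-averaged) power over the baseline window, by default
#' the 500 ms preceding the demarcation marker. Applied to the non-reversal
#' epoch transform, this yields the perceptual-stability baseline used for
#' decibel normalization.
#'
#' @param tfr A raw `tfr_power`.
#' @param window Baseline window, ms, half-open.
#' @return Matrix channels x frequencies (microvolt^2).
#' @export
baseline_power <- function(tfr, window = baseline_window()) {
  stopifnot(!tfr$normalized)
  idx <- window_index(tfr$time, window)
  if (!length(idx)) stop("baseline window outside the epoch span")
  apply(tfr$power[, , idx, drop = FALSE], c(1, 2), mean)
}

#' Decibel baseline normalization
#'
#' `dB(t) = 10 * (log10 A(t) - log10 B)` per channel and frequency, with
#' `B` the baseline power (typically from [baseline_power()] on the
#' non-reversal epochs of the same subject, task and channel).
#'
#' @param tfr A raw `tfr_power`.
#' @param baseline Matrix channels x frequencies, strictly positive.
#' @return A `tfr_power` with `normalized = TRUE` and values in dB.
#' @export
baseline_normalize <- function(tfr, baseline) {
  stopifnot(!tfr$normalized,
            identical(dim(baseline), dim(tfr$power)[1:2]))
  bad <- which(!(baseline > 0), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-positive baseline at channel %s, %g Hz",
                 tfr$channel_labels[bad[1, 1]], tfr$freqs[bad[1, 2]]))
  db <- 10 * (log10(tfr$power) - rep(log10(baseline), dim(tfr$power)[3]))
  dim(db) <- dim(tfr$power)
  tfr$power <- db
  tfr$normalized <- TRUE
  tfr
}

#' Window-averaged ROI summaries at the analysis frequency
#'
#' Averages normalized power over each analysis window's time samples at
#' the stated frequency bin, then over each ROI's electrode pair. The
#' unnormalized baseline summary (alpha power in microvolt^2 during
#' perceptual stability) is produced by passing the raw non-reversal
#' transform as `baseline_tfr`.
#'
#' @param tfr_db A normalized (`dB`) `tfr_power` of reversal epochs.
#' @param condition `"endogenous"` or `"exogenous"` (selects window bounds).
#' @param baseline_tfr Optional raw `tfr_power` of non-reversal epochs.
#' @param freq Analysis frequency bin, Hz (must be on the grid).
#' @return data.frame with columns `roi`, `window`, `value` (dB for
#'   pre-reversal/reversal rows, microvolt^2 for baseline rows).
#' @export
average_windows <- function(tfr_db, condition, baseline_tfr = NULL, freq = 11) {
  stopifnot(tfr_db$normalized)
  fi <- match(freq, tfr_db$freqs)
  if (is.na(fi)) stop("frequency ", freq, " Hz not on the transform grid")
  wins <- analysis_windows(condition)
  rois <- roi_pairs()
  rows <- list()
  for (wn in c("pre_reversal", "reversal")) {
    idx <- window_index(tfr_db$time, wins[[wn]])
    if (!length(idx)) stop("window ", wn, " outside the epoch span")
    chan_mean <- rowMeans(tfr_db$power[, fi, idx, drop = FALSE][, 1, ])
    for (rn in names(rois)) {
      ci <- match(rois[[rn]], tfr_db$channel_labels)
      rows[[length(rows) + 1L]] <-
        data.frame(roi = rn, window = wn, value = mean(chan_mean[ci]))
    }
  }
  if (!is.null(baseline_tfr)) {
    stopifnot(!baseline_tfr$normalized)
    fb <- match(freq, baseline_tfr$freqs)
    idx <- window_index(baseline_tfr$time, wins$baseline)
    chan_mean <- rowMeans(baseline_tfr$power[, fb, idx, drop = FALSE][, 1, ])
    for (rn in names(rois)) {
      ci <- match(rois[[rn]], baseline_tfr$channel_labels)
      rows[[length(rows) + 1L]] <-
        data.frame(roi = rn, window = "baseline", value = mean(chan_mean[ci]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spectral and temporal resolution of a wavelet kernel
#'
#' Measures, from the sampled kernel itself: the standard deviation of its
#' Gaussian magnitude spectrum (via amplitude-weighted moments of a finely
#' zero-padded FFT), reported as the `center +/- 2 SD` frequency band, and
#' its temporal width, defined as twice the time at which the squared
#' (power) envelope has fallen to `exp(-2)` of its peak.
#'
#' @param wavelet A [make_wavelet()] kernel.
#' @return List with `freq_sd` (Hz), `freq_band_2sd` (length-2 Hz vector)
#'   and `temporal_width` (ms).
#' @examples
#' wavelet_diagnostics(make_wavelet(11, 7, 500))
#' @export
wavelet_diagnostics <- function(wavelet) {
  fs <- wavelet$sampling_rate
  nk <- length(wavelet$values)
  nfft <- nextn(max(2^16, 4L * nk), c(2L, 3L, 5L))
  spec <- Mod(fft(c(wavelet$values, rep(0, nfft - nk))))
  freqs <- (seq_len(nfft) - 1) * fs / nfft
  half <- freqs <= fs / 2
  w <- spec[half]; f <- freqs[half]
  # the magnitude spectrum is Gaussian: fit log|H| over its main lobe
  # (amplitude-weighted quadratic), which is robust to truncation tails
  lobe <- w > 1e-3 * max(w)
  fit <- lm(log(w[lobe]) ~ f[lobe] + I(f[lobe]^2), weights = w[lobe])
  curv <- coef(fit)[[3]]                  # = -1 / (2 sigma_f^2)
  mu <- -coef(fit)[[2]] / (2 * curv)      # vertex = center frequency
  sdv <- sqrt(-1 / (2 * curv))

  env2 <- Mod(wavelet$values)^2
  env2 <- env2 / max(env2)
  pos <- wavelet$time >= 0
  cross <- approx(env2[pos], wavelet$time[pos], xout = exp(-2))$y
  list(freq_sd = sdv,
       freq_band_2sd = c(mu - 2 * sdv, mu + 2 * sdv),
       temporal_width = 2 * cross * 1000)
}
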