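# Morlet wavelet construction, FFT convolution, power, dB normalization,
# window averaging and kernel diagnostics.

test_that("wavelet kernels have the stated sigma, unit energy and symmetry", {
  w <- make_wavelet(11, 7, 500)
  expect_equal(w$sigma, 7 / (2 * pi * 11), tolerance = 1e-12)
  expect_equal(sum(Mod(w$values)^2) / 500, 1, tolerance = 1e-9)
  expect_equal(which.max(Mod(w$values)), (length(w$values) + 1) %/% 2)
  # analytic form: real part even, imaginary part odd about t = 0
  expect_equal(Re(w$values), rev(Re(w$values)))
  expect_equal(Im(w$values), -rev(Im(w$values)))
  expect_error(make_wavelet(11, 7, 500, support_sigma = 3), "support")
  expect_error(make_wavelet(-1, 7, 500))
})

test_that("an impulse reproduces the centered kernel", {
  w <- make_wavelet(11, 7, 500)
  x <- numeric(2001)
  x[1001] <- 1
  z <- convolve_fft(x, w)
  half <- length(w$values) %/% 2
  expect_equal(z[(1001 - half):(1001 + half)], w$values, tolerance = 1e-12)
})

test_that("FFT convolution equals the direct time-domain oracle", {
  set.seed(7)
  for (rep in 1:12) {
    n <- sample(200:3000, 1)
    f <- runif(1, 8, 14)
    x <- rnorm(n)
    w <- make_wavelet(f, 7, 500)
    z_fft <- convolve_fft(x, w)
    z_dir <- direct_convolve(x, w)
    expect_lt(max(Mod(z_fft - z_dir)) / max(Mod(z_dir)), 1e-8)
  }
  expect_error(convolve_fft(numeric(0), make_wavelet(11, 7, 500)), "empty")
})

test_that("a matched sinusoid yields a stationary modulus", {
  tt <- (0:9999) / 500
  z <- convolve_fft(sin(2 * pi * 11 * tt), make_wavelet(11, 7, 500))
  mid <- Mod(z[1000:9000])
  expect_lt(sd(mid) / mean(mid), 0.01)
})

test_that("convolution energy obeys Parseval within the kernel band", {
  set.seed(3)
  x <- rnorm(4096)
  w <- make_wavelet(11, 7, 512)
  nk <- length(w$values)
  # zero margins so the center-aligned output holds the full convolution
  xm <- c(rep(0, nk), x, rep(0, nk))
  e_time <- sum(Mod(convolve_fft(xm, w))^2)
  # frequency-domain account: energy of x filtered by the kernel transfer
  # function
  nfft <- stats::nextn(length(xm) + nk - 1L, c(2, 3, 5))
  H <- fft(c(w$values, rep(0, nfft - nk)))
  X <- fft(c(xm, rep(0, nfft - length(xm))))
  e_freq <- sum(Mod(X * H)^2) / nfft
  expect_lt(abs(e_time - e_freq) / e_freq, 1e-6)
})

test_that("trial power averages, scales quadratically, and rejects n = 0", {
  set.seed(5)
  z <- matrix(complex(real = rnorm(300), imaginary = rnorm(300)), 100, 3)
  p <- compute_power(z)
  expect_equal(compute_power(2 * z), 4 * p)
  expect_equal(compute_power(cbind(z[, 1], z[, 1])), Mod(z[, 1])^2)
  # two trials with power p and 3p -> 2p
  z2 <- cbind(z[, 1], sqrt(3) * z[, 1])
  expect_equal(compute_power(z2), 2 * Mod(z[, 1])^2)
  expect_error(compute_power(z[, 0, drop = FALSE]), "trial")
})

test_that("decibel normalization has its closed forms and scale invariance", {
  ses <- shared_session()
  rev <- extract_reversal_epochs(ses$recording, ses$events)
  rev <- subset_epochs(rev, 1:10)
  tfr <- tfr_epochs(rev, freqs = c(10, 11, 12))
  expect_true(all(tfr$power >= 0))
  B <- apply(tfr$power, c(1, 2), mean)
  db <- baseline_normalize(tfr, B)
  expect_true(db$normalized)
  # closed forms on constant power: A = B -> 0 dB; A = 2B -> +3.0103 dB
  const <- tfr
  const$power <- array(5, dim(tfr$power))
  expect_true(all(baseline_normalize(const, array(5, dim(B)))$power == 0))
  expect_equal(
    unique(as.vector(baseline_normalize(const, array(2.5, dim(B)))$power)),
    10 * log10(2), tolerance = 1e-12)
  tfr2 <- tfr
  tfr2$power <- 2 * tfr$power
  db2 <- baseline_normalize(tfr2, B)
  expect_equal(db2$power - db$power,
               array(10 * log10(2), dim(db$power)), tolerance = 1e-10)
  # global amplitude scaling of the recording leaves dB untouched
  scaled <- rev
  scaled$data <- scaled$data * 3
  tfr3 <- tfr_epochs(scaled, freqs = c(10, 11, 12))
  db3 <- baseline_normalize(tfr3, apply(tfr3$power, c(1, 2), mean))
  expect_equal(db3$power, db$power, tolerance = 1e-8)
  bad <- B
  bad[1, 1] <- 0
  expect_error(baseline_normalize(tfr, bad), "non-positive baseline")
})

test_that("window averaging picks 150 samples and means electrode pairs", {
  wins <- analysis_windows("endogenous")
  time_ms <- seq(-3000, by = 2, length.out = 2500)
  in_win <- which(time_ms >= wins$reversal[1] & time_ms < wins$reversal[2])
  expect_length(in_win, 150) # 300 ms at 500 Hz
  # constant dB everywhere -> every summary equals that constant
  fake <- structure(list(
    power = array(-2, c(8, 1, 2500)), freqs = 11, time = time_ms,
    n_trials = 5, channel_labels = default_channels(),
    sampling_rate = 500, normalized = TRUE), class = "tfr_power")
  s <- average_windows(fake, "endogenous")
  expect_true(all(s$value == -2))
  expect_setequal(s$roi, c("F", "C", "P", "O"))
  # O pair mean: O1 = -4, O2 = -2 -> -3
  fake2 <- fake
  fake2$power[7, 1, ] <- -4
  s2 <- average_windows(fake2, "endogenous")
  expect_equal(s2$value[s2$roi == "O" & s2$window == "reversal"], -3)
  expect_error(average_windows(fake, "endogenous", freq = 9.9), "grid")
})

test_that("exogenous windows slide 100 ms towards the press", {
  we <- analysis_windows("exogenous")
  wn <- analysis_windows("endogenous")
  expect_equal(we$pre_reversal, wn$pre_reversal + 100)
  expect_equal(we$reversal, wn$reversal + 100)
  expect_equal(we$baseline, wn$baseline)
})

test_that("kernel diagnostics match the analytic band and width", {
  d <- wavelet_diagnostics(make_wavelet(11, 7, 500))
  expect_equal(d$freq_sd, 11 / 7, tolerance = 0.01)
  expect_equal(d$freq_band_2sd, c(11 - 22 / 7, 11 + 22 / 7), tolerance = 0.02)
  # power envelope folds to exp(-2) at sigma * sqrt(2)
  expect_equal(d$temporal_width, 2000 * sqrt(2) * 7 / (2 * pi * 11),
               tolerance = 1)
  # more cycles: narrower band, wider in time
  d12 <- wavelet_diagnostics(make_wavelet(11, 12, 500))
  expect_lt(d12$freq_sd, d$freq_sd)
  expect_gt(d12$temporal_width, d$temporal_width)
})

test_that("concatenated transform equals per-epoch transform away from joins", {
  ses <- shared_session()
  rev <- subset_epochs(extract_reversal_epochs(ses$recording, ses$events), 1:6)
  tfr <- tfr_epochs(rev, freqs = 11)
  w <- make_wavelet(11, 7, 500)
  half <- length(w$values) %/% 2
  interior <- (half + 1):(2500 - half)
  cal <- w$gain^2 / 2
  per_trial <- sapply(1:6, function(k)
    Mod(convolve_fft(rev$data[1, , k], w))^2 / cal)
  expect_equal(tfr$power[1, 1, interior],
               rowMeans(per_trial)[interior], tolerance = 1e-8)
})

test_that("the end-to-end pipeline recovers injected ERD depth", {
  ses <- shared_session() # -3 dB at O1/O2
  rev <- reject_artifacts(extract_reversal_epochs(ses$recording, ses$events))
  non <- reject_artifacts(extract_nonreversal_epochs(ses$recording,
                                                     ses$events, rev))
  expect_gte(n_epochs(rev, surviving = TRUE), 30)
  tfr <- tfr_epochs(rev, freqs = 11)
  bl <- baseline_power(tfr_epochs(non, freqs = 11))
  s <- average_windows(baseline_normalize(tfr, bl), "endogenous")
  o_rev <- s$value[s$roi == "O" & s$window == "reversal"]
  f_rev <- s$value[s$roi == "F" & s$window == "reversal"]
  expect_lt(abs(o_rev - (-3)), 0.5)
  expect_lt(abs(f_rev), 0.5)
  # suppression deepens from pre-reversal to reversal at the injected site
  expect_lt(o_rev, s$value[s$roi == "O" & s$window == "pre_reversal"])
})
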