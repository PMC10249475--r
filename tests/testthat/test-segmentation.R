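# Epoch extraction, artifact rejection and epoch-count equalization.

test_that("isolated presses yield full-length epochs", {
  rec <- flat_recording(600, channels = c("O1", "O2"))
  ev <- events_with_presses(c(100, 200), duration = 600)
  ep <- extract_reversal_epochs(rec, ev)
  expect_equal(n_epochs(ep), 2)
  expect_equal(dim(ep$data), c(2, 2500, 2))
  expect_equal(range(ep$time), c(-3000, 2000 - 2))
})

test_that("epochs containing a second press are excluded", {
  rec <- flat_recording(600)
  ep <- extract_reversal_epochs(rec, events_with_presses(c(100, 101.5), 600))
  expect_equal(n_epochs(ep), 0)
  # asymmetric window [-3, 2): a press 2 s later is outside the first
  # epoch's window, but the first press sits inside the second's
  ep2 <- extract_reversal_epochs(rec, events_with_presses(c(100, 102.0), 600))
  expect_equal(n_epochs(ep2), 1)
  expect_equal(ep2$onsets, 100)
  # separation beyond 3 s clears both windows
  ep3 <- extract_reversal_epochs(rec, events_with_presses(c(100, 104.0), 600))
  expect_equal(n_epochs(ep3), 2)
})

test_that("edge-truncated epochs are dropped and empty streams warn", {
  rec <- flat_recording(60)
  ep <- extract_reversal_epochs(rec, events_with_presses(c(2, 30, 58.5), 60))
  expect_equal(n_epochs(ep), 1) # 2 s and 58.5 s run off the edges
  expect_warning(
    empty <- extract_reversal_epochs(rec, events_with_presses(numeric(0), 60)),
    "no button presses")
  expect_equal(n_epochs(empty), 0)
})

test_that("reversal epoch counts match brute-force enumeration", {
  fs <- 50
  rec <- as_recording(matrix(0, 1, 600 * fs), fs, "O1")
  set.seed(123)
  for (rep in 1:500) {
    presses <- sort(runif(sample(2:40, 1), 0, 600))
    ep <- extract_reversal_epochs(rec, events_with_presses(presses, 600))
    # oracle: no neighbour press within the epoch span, sample-rounded,
    # and the epoch fully inside the recording
    i_press <- round(presses * fs)
    expected <- sum(vapply(seq_along(presses), function(k) {
      lo <- i_press[k] - 3 * fs; hi <- i_press[k] + 2 * fs
      lo >= 0 && hi <= 600 * fs &&
        sum(i_press >= lo & i_press < hi) == 1
    }, TRUE))
    expect_equal(n_epochs(ep), expected)
  }
})

test_that("a press-free minute yields 12 tiled non-reversal epochs", {
  rec <- flat_recording(60)
  ev <- events_with_presses(numeric(0), 60)
  ep <- suppressWarnings(extract_reversal_epochs(rec, ev))
  non <- extract_nonreversal_epochs(rec, ev, ep)
  # greedy earliest-first: anchors at 3, 8, ..., 58 s (3 s lead-in needed)
  expect_equal(n_epochs(non), 12)
  expect_equal(non$onsets[1], 3)
  expect_true(all(diff(non$onsets) == 5))
})

test_that("presses everywhere leave no non-reversal epochs", {
  rec <- flat_recording(60)
  ev <- events_with_presses(seq(2, 58, by = 2), 60)
  ep <- extract_reversal_epochs(rec, ev)
  non <- extract_nonreversal_epochs(rec, ev, ep)
  expect_equal(n_epochs(non), 0)
})

test_that("non-reversal epochs never overlap presses or reversal epochs", {
  ses <- shared_session()
  rev <- extract_reversal_epochs(ses$recording, ses$events)
  non <- extract_nonreversal_epochs(ses$recording, ses$events, rev)
  expect_gt(n_epochs(non), 0)
  non_spans <- cbind(non$onsets - 3, non$onsets + 2)
  rev_spans <- cbind(rev$onsets - 3, rev$onsets + 2)
  presses <- ses$events$onset[ses$events$kind == "button_press"]
  for (k in seq_len(nrow(non_spans))) {
    expect_false(any(presses >= non_spans[k, 1] & presses < non_spans[k, 2]))
    expect_false(any(rev_spans[, 1] < non_spans[k, 2] &
                       rev_spans[, 2] > non_spans[k, 1]))
  }
  # mutual non-overlap
  expect_true(all(diff(non$onsets) >= 5))
})

test_that("epoch extraction is translation-equivariant", {
  fs <- 100
  dur <- 30
  set.seed(1)
  sig <- matrix(rnorm(2 * dur * fs), 2)
  rec1 <- as_recording(sig, fs, c("A", "B"))
  presses <- c(5, 12.5, 20)
  delta <- 3
  rec2 <- as_recording(cbind(matrix(0, 2, delta * fs), sig), fs, c("A", "B"))
  ep1 <- extract_reversal_epochs(rec1, events_with_presses(presses, dur))
  ep2 <- extract_reversal_epochs(rec2, events_with_presses(presses + delta,
                                                           dur + delta))
  expect_equal(ep2$onsets, ep1$onsets + delta)
  expect_equal(ep2$data, ep1$data)
  expect_equal(ep2$time, ep1$time)
})

test_that("amplitude rejection honours the inspection window", {
  rec <- flat_recording(60)
  ev <- events_with_presses(c(20, 30, 40), 60)
  ep <- extract_reversal_epochs(rec, ev)
  # 150 uV spike at -500 ms of the second epoch: inside -1500..200
  hit <- which(ep$time >= -500)[1]
  ep$data[1, hit, 2] <- 150
  # spike at +1000 ms of the third epoch: outside the inspection window
  out <- which(ep$time >= 1000)[1]
  ep$data[1, out, 3] <- 150
  res <- reject_artifacts(ep)
  expect_equal(which(res$rejected), 2L)
  expect_equal(res$reject_reason[2], "amplitude")
  expect_error(reject_artifacts(ep, threshold = 0), "positive")
})

test_that("every injected supra-threshold spike inside the window rejects", {
  cfg <- simulation_config("endogenous", "young",
                           artifact_rates = c(blink = 0, spike = 2, drift = 0),
                           seed = 77)
  ses <- generate_session(cfg)
  rev <- extract_reversal_epochs(ses$recording, ses$events)
  res <- reject_artifacts(rev)
  spikes <- ses$artifact_log$time[abs(ses$artifact_log$amplitude) > 100]
  for (k in seq_len(n_epochs(res))) {
    t0 <- res$onsets[k]
    inside <- any(spikes >= t0 - 1.5 & spikes < t0 + 0.2)
    if (inside) expect_true(res$rejected[k])
  }
})

test_that("equalization subsamples to the minimum and is reproducible", {
  make_set <- function(n) {
    rec <- flat_recording(600)
    on <- seq(20, by = 6, length.out = n)
    extract_reversal_epochs(rec, events_with_presses(on, 600))
  }
  sets <- list(a = make_set(35), b = make_set(31), c = make_set(29))
  eq1 <- equalize_epoch_counts(sets, seed = 4)
  expect_true(all(vapply(eq1, n_epochs, 0L) == 29))
  eq2 <- equalize_epoch_counts(sets, seed = 4)
  expect_identical(lapply(eq1, `[[`, "onsets"), lapply(eq2, `[[`, "onsets"))
  eq3 <- equalize_epoch_counts(sets, policy = "target", target = 10, seed = 4)
  expect_true(all(vapply(eq3, n_epochs, 0L) == 10))
})

test_that("equalization draws retained sets uniformly over combinations", {
  counts <- c(s1 = 5L)
  combos <- combn(5, 3)
  keys <- apply(combos, 2, paste, collapse = ",")
  tab <- setNames(numeric(length(keys)), keys)
  for (i in 1:1000) {
    idx <- revalpha:::equalize_indices(counts, 3, seed = i)$s1
    tab[paste(idx, collapse = ",")] <- tab[paste(idx, collapse = ",")] + 1
  }
  chi <- sum((tab - 100)^2 / 100)
  expect_gt(pchisq(chi, df = 9, lower.tail = FALSE), 0.001)
})
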