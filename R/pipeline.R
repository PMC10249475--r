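# End-to-end simulated study: simulate -> segment -> time-frequency -> stats.
#
# Window statistics need only the analysis frequency bin, so the pipeline
# stores, per subject and condition, single-trial power over the analysis
# windows at that bin. Epoch-count equalization is then a seeded selection
# of trial indices applied to those aggregates; because the wavelet
# transform is computed per trial, selecting trials after the transform is
# identical to transforming the selected trials.

#' Single-trial window power at one frequency
#'
#' Convolves each channel's concatenated surviving trials with one Morlet
#' kernel and returns, for each requested window, the single-trial power
#' time courses restricted to that window.
#'
#' @param epochs An `epoch_set`.
#' @param windows Named list of `c(start, end)` ms windows (half-open).
#' @param freq Analysis frequency, Hz.
#' @param n_cycles Wavelet cycles.
#' @return Named list of arrays `trials x samples_in_window x channels`
#'   (microvolt^2), with attribute `"onsets"` carrying trial onsets.
#' @export
trial_window_power <- function(epochs, windows, freq = 11, n_cycles = 7) {
  keep <- which(!epochs$rejected)
  if (!length(keep)) stop("no surviving epochs")
  data <- epochs$data[, , keep, drop = FALSE]
  nch <- dim(data)[1]; nt <- dim(data)[2]; ntr <- dim(data)[3]
  w <- make_wavelet(freq, n_cycles, epochs$sampling_rate)
  idxs <- lapply(windows, function(win) window_index(epochs$time, win))
  out <- lapply(idxs, function(idx) array(0, c(ntr, length(idx), nch)))
  cal <- w$gain^2 / 2 # microvolt^2 band-power calibration
  for (ch in seq_len(nch)) {
    z <- convolve_fft(as.vector(data[ch, , ]), w)
    p <- matrix(Mod(z)^2, nt, ntr) / cal
    for (wn in names(windows))
      out[[wn]][, , ch] <- t(p[idxs[[wn]], , drop = FALSE])
  }
  for (wn in names(windows)) attr(out[[wn]], "onsets") <- epochs$onsets[keep]
  out
}

#' Configuration of a simulated group study
#'
#' @param n_young,n_older Subjects per group.
#' @param session_duration Session length per condition, seconds.
#' @param sampling_rate Hz.
#' @param channels Channel montage.
#' @param stat_freq Frequency bin feeding the statistics, Hz.
#' @param n_cycles Wavelet cycles.
#' @param reject_threshold Artifact amplitude bound, microvolts.
#' @param inspection_window Artifact inspection window, ms.
#' @param artifact_rates Artifact rates per minute (named blink/spike/drift).
#' @param erd_sd Between-subject SD of per-ROI ERD depth, dB.
#' @param spectrograms Also compute and (when `out_dir` is set) export
#'   per-subject ROI spectrograms over the full 8--14 Hz grid.
#' @param freqs Spectrogram frequency grid, Hz.
#' @param seed Master seed; per-subject and per-stage sub-seeds are derived
#'   deterministically, so adding subjects never perturbs existing ones.
#' @return Object of class `"study_config"`.
#' @export
study_config <- function(n_young = 12, n_older = 12,
                         session_duration = 600, sampling_rate = 500,
                         channels = default_channels(),
                         stat_freq = 11, n_cycles = 7,
                         reject_threshold = 100,
                         inspection_window = c(-1500, 200),
                         artifact_rates = c(blink = 2, spike = 0.3, drift = 0.2),
                         erd_sd = 0.3, spectrograms = FALSE,
                         freqs = seq(8, 14, by = 0.25), seed = 1L) {
  stopifnot(n_young >= 0, n_older >= 0, n_young + n_older > 0)
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  class(cfg) <- "study_config"
  cfg
}

rtrunc_norm <- function(n, mean, sd, lower) pmax(lower, rnorm(n, mean, sd))

# Simulate and reduce one subject-condition session to its window
# aggregates at the analysis frequency.
process_session <- function(cfg, group, subject_id, condition, subj_par) {
  sim <- simulation_config(
    condition = condition, group = group,
    sampling_rate = cfg$sampling_rate,
    session_duration = cfg$session_duration,
    channels = cfg$channels,
    reversal_rate = subj_par$reversal_rate,
    rt_mean = subj_par$rt_mean,
    accuracy = subj_par$accuracy,
    erd_depth = subj_par$erd_roi[[condition]],
    artifact_rates = cfg$artifact_rates,
    seed = derive_seed(cfg$seed, "session", subject_id, condition))
  ses <- generate_session(sim)
  rev_ep <- extract_reversal_epochs(ses$recording, ses$events, condition)
  rev_ep <- reject_artifacts(rev_ep, cfg$inspection_window, cfg$reject_threshold)
  non_ep <- extract_nonreversal_epochs(ses$recording, ses$events, rev_ep)
  non_ep <- reject_artifacts(non_ep, cfg$inspection_window, cfg$reject_threshold)
  wins <- analysis_windows(condition)
  out <- list(
    behavioral = behavioral_metrics(ses$events, condition, cfg$session_duration),
    n_rev = n_epochs(rev_ep, surviving = TRUE),
    n_non = n_epochs(non_ep, surviving = TRUE))
  if (out$n_rev > 0)
    out$rev_pow <- trial_window_power(
      rev_ep, wins[c("pre_reversal", "reversal")], cfg$stat_freq, cfg$n_cycles)
  if (out$n_non > 0)
    out$non_pow <- trial_window_power(
      non_ep, wins["baseline"], cfg$stat_freq, cfg$n_cycles)
  if (isTRUE(cfg$spectrograms) && out$n_rev > 0 && out$n_non > 0) {
    tfr <- tfr_epochs(rev_ep, cfg$freqs, cfg$n_cycles)
    bl <- baseline_power(tfr_epochs(non_ep, cfg$freqs, cfg$n_cycles))
    out$spectrogram <- baseline_normalize(tfr, bl)
  }
  out
}

roi_means <- function(values_by_channel, channels) {
  vapply(roi_pairs(), function(pair)
    mean(values_by_channel[match(pair, channels)]), 0)
}

#' Run a full simulated study
#'
#' Simulates every subject's endogenous and exogenous session, segments and
#' cleans epochs, equalizes epoch counts across subjects by seeded random
#' exclusion (separately for reversal and non-reversal sets within each
#' condition), computes decibel-normalized window summaries at the analysis
#' frequency, and runs the statistical battery: the 2x4x2 mixed ANOVA with
#' Greenhouse-Geisser correction, the linear ROI-by-time trend-contrast
#' group test, Bonferroni-corrected post-hocs, planned paired pre-to-
#' reversal comparisons with Hedges g_av per group and ROI, the baseline
#' (group x ROI) ANOVA on raw alpha power, behavioral group comparisons,
#' and the dwell-time-on-alpha regressions. Group-level statistics are
#' skipped, with an explicit notice, when either group has no subjects.
#' Re-running with the same config reproduces every table exactly.
#'
#' @param config A [study_config()].
#' @param out_dir Optional directory for CSV tables and a JSON manifest.
#' @return Object of class `"study_result"`: list with `summaries`,
#'   `behavioral`, `epoch_counts`, `stats` (per condition), `notices`,
#'   `manifest`.
#' @export
run_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  groups <- rep(c("young", "older"), c(config$n_young, config$n_older))
  ids <- sprintf("%s%02d", substr(groups, 1, 1),
                 c(seq_len(config$n_young), seq_len(config$n_older)))
  conditions <- c("endogenous", "exogenous")
  notices <- character(0)

  sessions <- list()
  for (i in seq_along(ids)) {
    prof <- group_profile(groups[i])
    set.seed(derive_seed(config$seed, "subject_params", ids[i]))
    subj_par <- list(
      reversal_rate = rtrunc_norm(1, prof$reversal_rate,
                                  prof$reversal_rate_sd, 1.5),
      rt_mean = rtrunc_norm(1, prof$rt_mean, prof$rt_between_sd, 0.25),
      accuracy = min(100, rtrunc_norm(1, prof$accuracy, 2, 50)),
      erd_roi = lapply(prof$erd_roi, function(d) {
        jit <- d + rnorm(length(d), 0, config$erd_sd)
        jit[jit > 0] <- 0
        jit
      }))
    for (cond in conditions)
      sessions[[paste(ids[i], cond, sep = ".")]] <-
        process_session(config, groups[i], ids[i], cond, subj_par)
  }

  summaries <- list(); behavioral <- list(); counts <- list()
  for (cond in conditions) {
    keys <- paste(ids, cond, sep = ".")
    n_rev <- vapply(sessions[keys], `[[`, 0L, "n_rev")
    n_non <- vapply(sessions[keys], `[[`, 0L, "n_non")
    names(n_rev) <- names(n_non) <- ids
    usable <- n_rev > 0 & n_non > 0
    if (any(!usable)) {
      notices <- c(notices, paste0("subjects without usable epochs in ",
                                   cond, ": ",
                                   paste(ids[!usable], collapse = ", ")))
    }
    counts[[cond]] <- data.frame(subject = ids, group = groups,
                                 condition = cond, n_reversal = n_rev,
                                 n_nonreversal = n_non,
                                 n_retained = if (any(usable))
                                   ifelse(usable, min(n_rev[usable]), 0) else 0)
    if (!any(usable)) next
    idx_rev <- equalize_indices(n_rev[usable], min(n_rev[usable]),
                                derive_seed(config$seed, "equalize", cond, "rev"))
    idx_non <- equalize_indices(n_non[usable], min(n_non[usable]),
                                derive_seed(config$seed, "equalize", cond, "non"))
    for (s in ids[usable]) {
      ses <- sessions[[paste(s, cond, sep = ".")]]
      gi <- groups[match(s, ids)]
      # baseline: time-mean of trial-mean power, per channel (uV^2)
      bsel <- ses$non_pow$baseline[idx_non[[s]], , , drop = FALSE]
      B <- apply(bsel, 3, mean)
      vals <- list(baseline = roi_means(B, config$channels))
      for (wn in c("pre_reversal", "reversal")) {
        sel <- ses$rev_pow[[wn]][idx_rev[[s]], , , drop = FALSE]
        A <- apply(sel, c(2, 3), mean)            # samples x channels
        db <- sweep(10 * log10(A), 2, 10 * log10(B))
        vals[[wn]] <- roi_means(colMeans(db), config$channels)
      }
      for (wn in names(vals))
        summaries[[length(summaries) + 1L]] <- data.frame(
          subject = s, group = gi, condition = cond,
          roi = names(vals[[wn]]), window = wn, value = unname(vals[[wn]]))
      beh <- ses$behavioral
      behavioral[[length(behavioral) + 1L]] <- data.frame(
        subject = s, group = gi, condition = cond,
        reversal_rate = beh$reversal_rate,
        mean_dwell_time = beh$mean_dwell_time %||% NA_real_,
        mean_rt = beh$mean_rt %||% NA_real_,
        rt_variability = beh$rt_variability %||% NA_real_,
        accuracy = beh$accuracy %||% NA_real_)
    }
  }
  summaries <- do.call(rbind, summaries)
  behavioral <- do.call(rbind, behavioral)
  rownames(summaries) <- rownames(behavioral) <- NULL

  both_groups <- config$n_young > 0 && config$n_older > 0
  stats_out <- list()
  for (cond in conditions) {
    sc <- summaries[summaries$condition == cond, ]
    bc <- behavioral[behavioral$condition == cond, ]
    res <- list()
    if (!both_groups) {
      notices <- c(notices, paste0(
        "group statistics skipped for ", cond,
        ": both groups need at least one subject"))
    } else {
      res$alpha <- mixed_anova_2x4x2(sc)
      base <- sc[sc$window == "baseline", ]
      res$baseline_anova <-
        mixed_anova(transform(base, roi = factor(roi, c("F", "C", "P", "O"))),
                    "value", "subject", "group", "roi")
      if (cond == "endogenous") {
        if (min(table(bc$group)) >= 2)
          res$reversal_rate <- group_compare(
            bc$reversal_rate[bc$group == "young"],
            bc$reversal_rate[bc$group == "older"], "t_cohen_d")
        if (min(table(bc$group)) >= 3) {
          res$dwell_regression <- regress_dwell_on_alpha(sc, bc)
        } else {
          notices <- c(notices,
                       "dwell regression skipped: needs >= 3 subjects per group")
        }
      } else if (min(table(bc$group)) >= 2) {
        res$rt <- group_compare(bc$mean_rt[bc$group == "young"],
                                bc$mean_rt[bc$group == "older"],
                                "mann_whitney_u")
        res$accuracy <- group_compare(bc$accuracy[bc$group == "young"],
                                      bc$accuracy[bc$group == "older"],
                                      "mann_whitney_u")
      } else {
        notices <- c(notices, paste0(
          "behavioral group comparisons skipped for ", cond,
          ": fewer than 2 usable subjects in a group"))
      }
    }
    # planned pre-to-reversal paired comparisons per group and ROI
    planned <- list()
    for (gname in unique(sc$group)) for (rname in unique(sc$roi)) {
      pre <- sc[sc$group == gname & sc$roi == rname &
                  sc$window == "pre_reversal", ]
      rev <- sc[sc$group == gname & sc$roi == rname &
                  sc$window == "reversal", ]
      rev <- rev[match(pre$subject, rev$subject), ]
      if (nrow(pre) >= 2) {
        tt <- paired_t_gav(pre$value, rev$value)
        planned[[length(planned) + 1L]] <- data.frame(
          group = gname, roi = rname, t = tt$statistic, df = tt$df,
          p = tt$p, g_av = tt$g_av)
      }
    }
    res$planned <- if (length(planned)) do.call(rbind, planned) else NULL
    stats_out[[cond]] <- res
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("revalpha")),
    r_version = R.version.string,
    seed = config$seed,
    config = config[setdiff(names(config), "channels")],
    channels = config$channels)
  result <- list(summaries = summaries, behavioral = behavioral,
                 epoch_counts = do.call(rbind, counts),
                 stats = stats_out, notices = notices, manifest = manifest)
  class(result) <- "study_result"

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wcsv <- function(df, nm) utils::write.csv(
      df, file.path(out_dir, nm), row.names = FALSE)
    wcsv(summaries, "window_summaries.csv")
    wcsv(behavioral, "behavioral.csv")
    wcsv(result$epoch_counts, "epoch_counts.csv")
    for (cond in conditions) {
      st <- stats_out[[cond]]
      if (!is.null(st$alpha)) {
        wcsv(st$alpha$anova, paste0("anova_", cond, ".csv"))
        wcsv(st$alpha$trend, paste0("trend_", cond, ".csv"))
        if (!is.null(st$alpha$posthoc))
          wcsv(st$alpha$posthoc, paste0("posthoc_", cond, ".csv"))
        wcsv(st$baseline_anova, paste0("baseline_anova_", cond, ".csv"))
      }
      if (!is.null(st$planned)) wcsv(st$planned, paste0("planned_", cond, ".csv"))
      if (!is.null(st$dwell_regression))
        wcsv(st$dwell_regression, paste0("dwell_regression_", cond, ".csv"))
    }
    if (isTRUE(config$spectrograms)) {
      for (key in names(sessions)) {
        sp <- sessions[[key]]$spectrogram
        if (is.null(sp)) next
        for (ch in seq_along(sp$channel_labels)) {
          mat <- t(sp$power[ch, , ]) # time x freq
          colnames(mat) <- sp$freqs
          utils::write.table(
            cbind(time_ms = sp$time, mat),
            file.path(out_dir, sprintf("spectrogram_%s_%s.tsv", key,
                                       sp$channel_labels[ch])),
            sep = "\t", quote = FALSE, row.names = FALSE)
        }
      }
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result>\n")
  cat(sprintf("  %d window summaries over %d subjects\n",
              nrow(x$summaries), length(unique(x$summaries$subject))))
  for (n in x$notices) cat("  notice:", n, "\n")
  invisible(x)
}

#' Write a small deterministic simulated dataset
#'
#' `"tiny"` writes 2 subjects (one per group) x 2 conditions x 2 minutes,
#' used by the test suite; `"paper"` writes the full 12 + 12 subjects x
#' 10 minutes. Datasets are EDF + events.tsv per session; regeneration with
#' the same seed is byte-identical.
#'
#' @param scale `"tiny"` or `"paper"`.
#' @param path Output directory.
#' @param seed Master seed.
#' @return Invisibly, a data.frame listing the written sessions.
#' @export
make_fixtures <- function(scale = c("tiny", "paper"), path, seed = 2026L) {
  scale <- match.arg(scale)
  n_per_group <- if (scale == "tiny") 1 else 12
  dur <- if (scale == "tiny") 120 else 600
  rows <- list()
  for (grp in c("young", "older")) for (i in seq_len(n_per_group)) {
    id <- sprintf("%s%02d", substr(grp, 1, 1), i)
    for (cond in c("endogenous", "exogenous")) {
      cfg <- simulation_config(
        condition = cond, group = grp, session_duration = dur,
        artifact_rates = c(blink = 2, spike = 0.3, drift = 0.2),
        seed = derive_seed(seed, "fixture", id, cond))
      ses <- generate_session(cfg)
      dir <- file.path(path, id, cond)
      write_dataset(ses$recording, ses$events, dir)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = id, group = grp, condition = cond, path = dir,
        n_presses = sum(ses$events$kind == "button_press"))
    }
  }
  invisible(do.call(rbind, rows))
}
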