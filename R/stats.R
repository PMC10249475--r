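# Behavioral metrics and two-sample / paired statistics.

#' Behavioral summary of one session's event stream
#'
#' Endogenous sessions yield the reversal rate (presses per minute) and
#' dwell times (inter-press intervals). Exogenous sessions additionally
#' yield reaction time (press minus motion-change onset, each press scored
#' to the most recent motion change without an intervening press), its SD,
#' and accuracy: the percentage of motion changes answered with the correct
#' direction before the next change (unanswered changes count as
#' omissions; when the events carry no correctness labels every matched
#' press counts as correct).
#'
#' @param events Event stream data.frame.
#' @param condition `"endogenous"` or `"exogenous"`.
#' @param duration Session duration in seconds.
#' @return List with `reversal_rate` (per min), `mean_dwell_time`,
#'   `dwell_times` (s) and, for exogenous sessions, `mean_rt`,
#'   `rt_variability` (s) and `accuracy` (percent).
#' @export
behavioral_metrics <- function(events, condition = c("endogenous", "exogenous"),
                               duration) {
  condition <- match.arg(condition)
  ev <- as.data.frame(events)
  stopifnot(duration > 0)
  presses <- sort(ev$onset[ev$kind == "button_press"])
  out <- list(
    condition = condition,
    n_reversals = length(presses),
    reversal_rate = length(presses) / (duration / 60),
    dwell_times = diff(presses),
    mean_dwell_time = if (length(presses) > 1) mean(diff(presses)) else NA_real_)
  if (condition == "exogenous") {
    changes <- sort(ev$onset[ev$kind == "motion_change"])
    if (!length(changes))
      stop("exogenous metrics requested but events contain no motion_change")
    has_value <- "value" %in% names(ev)
    rt <- rep(NA_real_, length(changes))
    correct <- rep(FALSE, length(changes))
    nxt <- c(changes[-1], Inf)
    for (i in seq_along(changes)) {
      cand <- presses[presses > changes[i] & presses < nxt[i]]
      if (length(cand)) {
        rt[i] <- cand[1] - changes[i]
        val <- if (has_value)
          ev$value[ev$kind == "button_press" & ev$onset == cand[1]][1]
        else NA
        correct[i] <- is.na(val) || identical(val, "correct")
      }
    }
    out$mean_rt <- mean(rt, na.rm = TRUE)
    out$rt_variability <- sd(rt, na.rm = TRUE)
    out$accuracy <- 100 * mean(correct)
    out$n_changes <- length(changes)
  }
  out
}

#' Paired t test with Hedges g_av effect size
#'
#' The paired-design standardized mean difference divides the mean
#' difference by the average of the two condition SDs and applies the
#' small-sample bias correction `1 - 3 / (4*(n-1) - 1)`.
#'
#' @param a,b Equal-length paired numeric vectors (n >= 2).
#' @return List: `statistic` (t), `df`, `p`, `mean_diff`, `g_av`,
#'   `degenerate` (TRUE when the differences have zero variance, in which
#'   case t is signed infinity and p is 0 or, for a = b, t = 0 / p = 1).
#' @export
paired_t_gav <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  n <- length(a)
  d <- a - b
  corr <- 1 - 3 / (4 * (n - 1) - 1)
  sd_av <- (sd(a) + sd(b)) / 2
  g_av <- if (sd_av > 0) mean(d) / sd_av * corr else 0
  if (sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
    tv <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(list(statistic = tv, df = n - 1,
                p = if (mean(d) == 0) 1 else 0,
                mean_diff = mean(d), g_av = g_av, degenerate = TRUE))
  }
  tt <- t.test(a, b, paired = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(d), g_av = g_av, degenerate = FALSE)
}

# Levene's variance-homogeneity test, centered on group means:
# one-way ANOVA on absolute deviations.
levene_test <- function(x, y) {
  z <- c(abs(x - mean(x)), abs(y - mean(y)))
  g <- factor(rep(1:2, c(length(x), length(y))))
  tab <- summary(stats::aov(z ~ g))[[1]]
  list(F = tab$`F value`[1], df1 = tab$Df[1], df2 = tab$Df[2],
       p = tab$`Pr(>F)`[1])
}

#' Compare two independent groups
#'
#' Either an independent-samples t test (pooled SD) with Cohen's d, or a
#' Mann-Whitney U test (the U statistic is the number of young-over-older
#' pairwise wins, counting ties as half; equal to the `wilcox.test` W).
#' A Levene variance-homogeneity check (centered on means) is reported
#' alongside either method.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @param method `"t_cohen_d"` or `"mann_whitney_u"`.
#' @return List: `method`, `statistic` (t or U), `df` (t only), `p`,
#'   `effect_size` (Cohen's d, t only), `levene`.
#' @export
group_compare <- function(x, y, method = c("t_cohen_d", "mann_whitney_u")) {
  method <- match.arg(method)
  if (length(x) < 2 || length(y) < 2) stop("each group needs n >= 2")
  lev <- levene_test(x, y)
  if (method == "t_cohen_d") {
    tt <- t.test(x, y, var.equal = TRUE)
    sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
                 (length(x) + length(y) - 2))
    d <- if (sp > 0) (mean(x) - mean(y)) / sp else 0
    list(method = method, statistic = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value, effect_size = d,
         levene = lev)
  } else {
    wt <- suppressWarnings(wilcox.test(x, y))
    list(method = method, statistic = unname(wt$statistic), df = NA,
         p = wt$p.value, effect_size = NA, levene = lev)
  }
}

#' Regress mean dwell time on reversal-window alpha change
#'
#' Per group and ROI, ordinary least squares of each subject's mean dwell
#' time on their reversal-window baseline-normalized alpha power.
#'
#' @param summaries WindowSummary data.frame (`subject`, `group`, `roi`,
#'   `window`, `value`).
#' @param behavioral data.frame with columns `subject`, `mean_dwell_time`.
#' @param window Window whose values serve as predictor.
#' @return data.frame: `group`, `roi`, `n`, `slope`, `r_squared`, `p`.
#' @export
regress_dwell_on_alpha <- function(summaries, behavioral,
                                   window = "reversal") {
  s <- summaries[summaries$window == window, ]
  m <- merge(s, behavioral[c("subject", "mean_dwell_time")], by = "subject")
  rows <- list()
  for (gname in unique(m$group)) {
    for (rname in unique(m$roi)) {
      mi <- m[m$group == gname & m$roi == rname, ]
      mi <- mi[complete.cases(mi[c("value", "mean_dwell_time")]), ]
      if (nrow(mi) < 3)
        stop("need at least 3 subjects per group/ROI for regression")
      fit <- lm(mean_dwell_time ~ value, data = mi)
      sm <- summary(fit)
      rows[[length(rows) + 1L]] <- data.frame(
        group = gname, roi = rname, n = nrow(mi),
        slope = unname(coef(fit)[2]), r_squared = sm$r.squared,
        p = sm$coefficients[2, 4])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate null window summaries for calibration studies
#'
#' Generates WindowSummary tables under the null hypothesis of no group
#' difference and full exchangeability across cells: each subject's cell
#' value is a subject intercept plus the mean of `n_epochs` independent
#' epoch-level draws. Used to measure the empirical type-I error of the
#' three-way interaction test.
#'
#' @param n_per_group Subjects per group.
#' @param n_epochs Epoch-level draws averaged per cell.
#' @param sd_subject Between-subject SD of the intercept (dB).
#' @param sd_epoch Epoch-level SD (dB).
#' @param seed Integer seed.
#' @return WindowSummary data.frame.
#' @export
simulate_null_summaries <- function(n_per_group = 12, n_epochs = 10,
                                    sd_subject = 0.8, sd_epoch = 1.5,
                                    seed = 1L) {
  set.seed(seed)
  rois <- c("F", "C", "P", "O")
  wins <- c("pre_reversal", "reversal")
  rows <- expand.grid(roi = rois, window = wins,
                      subject = sprintf("s%02d", seq_len(2 * n_per_group)),
                      stringsAsFactors = FALSE)
  rows$group <- ifelse(match(rows$subject, unique(rows$subject)) <= n_per_group,
                       "young", "older")
  intercepts <- rnorm(2 * n_per_group, 0, sd_subject)
  names(intercepts) <- unique(rows$subject)
  rows$value <- intercepts[rows$subject] +
    rnorm(nrow(rows), 0, sd_epoch / sqrt(n_epochs))
  rows[c("subject", "group", "roi", "window", "value")]
}
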