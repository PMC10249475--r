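# Mixed-design (split-plot) ANOVA: one between-subjects factor, one or two
# fully-crossed within-subjects factors, balanced within-subject design
# (every subject measured in every cell). Implemented from the multivariate
# linear model Y ~ group (sum-to-zero coding, Type III hypotheses, matching
# SPSS conventions): each within effect is tested by projecting the
# hypothesis and error cross-product matrices onto an orthonormal contrast
# basis; the Greenhouse-Geisser epsilon of an effect with d contrast columns
# is (sum lambda)^2 / (d * sum lambda^2) over the eigenvalues lambda of the
# projected error covariance (epsilon = 1 exactly when d = 1).

orthonormal_contrasts <- function(k) {
  cm <- stats::contr.helmert(k)
  cm %*% diag(1 / sqrt(colSums(cm^2)), ncol(cm))
}

#' Mixed-design ANOVA with Greenhouse-Geisser correction
#'
#' Fits the split-plot decomposition for a design with one between-subjects
#' factor and one or two within-subjects factors, reporting for every
#' effect: F, degrees of freedom, p, partial eta squared, and for within
#' effects the Greenhouse-Geisser epsilon with corrected degrees of freedom
#' and p value.
#'
#' @param data Long-format data.frame.
#' @param dv Name of the numeric response column.
#' @param subject Name of the subject identifier column.
#' @param between Name of the between-subjects factor column.
#' @param within Character vector (length 1 or 2) of within-subjects factor
#'   columns.
#' @return data.frame of class `"mixed_anova"`: one row per effect with
#'   columns `effect`, `df1`, `df2`, `F`, `p` (uncorrected), `pes` (partial
#'   eta squared), `gg_epsilon`, `df1_gg`, `df2_gg`, `p_gg` (Greenhouse-
#'   Geisser corrected), `mauchly_p` (Mauchly's sphericity test, `NA` for
#'   1-df effects), and `p_inference`: the corrected p when Mauchly
#'   indicates a sphericity violation (p < 0.05), the uncorrected p
#'   otherwise. Missing design cells are an error (listed).
#' @examples
#' d <- expand.grid(subject = paste0("s", 1:6), roi = c("F", "O"),
#'                  time = c("pre", "rev"))
#' d$group <- ifelse(d$subject %in% paste0("s", 1:3), "young", "older")
#' set.seed(1); d$value <- rnorm(nrow(d))
#' mixed_anova(d, "value", "subject", "group", c("roi", "time"))
#' @export
mixed_anova <- function(data, dv, subject, between, within) {
  stopifnot(length(within) %in% 1:2, all(c(dv, subject, between, within)
                                         %in% names(data)))
  data <- as.data.frame(data)
  for (v in c(subject, between, within)) data[[v]] <- factor(data[[v]])
  lv <- lapply(within, function(v) levels(data[[v]]))
  cells <- rev(expand.grid(rev(lv), stringsAsFactors = FALSE)) # within[1] slow
  names(cells) <- within
  p <- nrow(cells)
  cell_key <- do.call(paste, c(cells, sep = "\r"))
  data_key <- do.call(paste, c(data[within], sep = "\r"))

  subjects <- levels(data[[subject]])
  Y <- matrix(NA_real_, length(subjects), p,
              dimnames = list(subjects, cell_key))
  grp <- rep(NA_character_, length(subjects))
  for (i in seq_len(nrow(data))) {
    s <- as.character(data[[subject]][i])
    Y[s, match(data_key[i], cell_key)] <- data[[dv]][i]
    grp[match(s, subjects)] <- as.character(data[[between]][i])
  }
  if (anyNA(Y)) {
    miss <- which(is.na(Y), arr.ind = TRUE)
    lab <- apply(miss, 1, function(r)
      paste0(subjects[r[1]], ":", gsub("\r", "/", cell_key[r[2]])))
    stop("missing design cells: ", paste(head(lab, 10), collapse = ", "))
  }
  gf <- factor(grp)
  g <- nlevels(gf)
  n <- nrow(Y)
  if (g < 2) stop("between factor needs at least 2 levels")

  X <- stats::model.matrix(~gf, contrasts.arg = list(gf = "contr.sum"))
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Y)
  E <- crossprod(Y - X %*% B)
  dfe <- n - g
  hyp_ssp <- function(rows) {
    L <- diag(ncol(X))[rows, , drop = FALSE]
    LB <- L %*% B
    crossprod(LB, solve(L %*% XtXi %*% t(L), LB))
  }
  H_int <- hyp_ssp(1L)
  H_grp <- hyp_ssp(seq(2L, g))

  # orthonormal bases over the cell axis
  Ms <- list()
  if (length(within) == 1L) {
    Ms[[within[1]]] <- orthonormal_contrasts(length(lv[[1]]))
  } else {
    a <- length(lv[[1]]); b <- length(lv[[2]])
    C1 <- orthonormal_contrasts(a); C2 <- orthonormal_contrasts(b)
    j1 <- matrix(1 / sqrt(a), a, 1); j2 <- matrix(1 / sqrt(b), b, 1)
    Ms[[within[1]]] <- kronecker(C1, j2)
    Ms[[within[2]]] <- kronecker(j1, C2)
    Ms[[paste(within, collapse = ":")]] <- kronecker(C1, C2)
  }

  rows <- list()
  ss_floor <- 1e-12 * (sum(Y * Y) / length(Y) + 1) # numerically-zero SS
  add_row <- function(effect, ss, df1, sse, df2, eps = NA_real_,
                      mauchly_p = NA_real_) {
    # a zero hypothesis SS is "no effect" even when the error SS is also zero
    Fv <- if (ss <= ss_floor) 0 else (ss / df1) / (sse / df2)
    p_un <- pf(Fv, df1, df2, lower.tail = FALSE)
    p_gg <- pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE)
    r <- data.frame(effect = effect, df1 = df1, df2 = df2, F = Fv,
                    p = p_un,
                    pes = if (ss <= ss_floor) 0 else ss / (ss + sse),
                    gg_epsilon = eps,
                    df1_gg = df1 * eps, df2_gg = df2 * eps,
                    p_gg = p_gg,
                    mauchly_p = mauchly_p,
                    # correct only when Mauchly indicates non-sphericity
                    p_inference = if (!is.na(mauchly_p) && mauchly_p < 0.05)
                      p_gg else p_un)
    rows[[length(rows) + 1L]] <<- r
  }

  # Mauchly's sphericity statistic on the projected error covariance
  mauchly_p_value <- function(V, d, dfe) {
    if (d < 2) return(NA_real_)
    lam <- eigen(V / dfe, symmetric = TRUE, only.values = TRUE)$values
    if (any(lam <= 0)) return(NA_real_)
    W <- prod(lam) / (mean(lam))^d
    f <- (2 * d^2 + d + 2) / (6 * d * dfe)
    x2 <- -(1 - f) * dfe * log(W)
    pchisq(x2, d * (d + 1) / 2 - 1, lower.tail = FALSE)
  }

  M0 <- matrix(1 / sqrt(p), p, 1)
  add_row(between, drop(crossprod(M0, H_grp %*% M0)), g - 1,
          drop(crossprod(M0, E %*% M0)), dfe, eps = 1)

  for (eff in names(Ms)) {
    M <- Ms[[eff]]
    d <- ncol(M)
    V <- crossprod(M, E %*% M)
    lam <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
    eps <- if (sum(lam^2) <= 0) 1 else sum(lam)^2 / (d * sum(lam^2))
    mp <- mauchly_p_value(V, d, dfe)
    add_row(eff, sum(diag(crossprod(M, H_int %*% M))), d,
            sum(diag(V)), d * dfe, eps, mp)
    add_row(paste(eff, between, sep = ":"),
            sum(diag(crossprod(M, H_grp %*% M))), d * (g - 1),
            sum(diag(V)), d * dfe, eps, mp)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mixed_anova", "data.frame")
  out
}

#' Between-group test of the linear ROI-by-time trend
#'
#' Scores each subject on the linear-over-ROI trend of the time effect
#' (reversal minus pre-reversal change weighted by equally spaced linear
#' coefficients over the anterior-to-posterior ROI ordering) and tests the
#' group difference of that score with a one-way ANOVA, yielding the
#' 1-df trend-contrast F test for the group-by-ROI-by-time linear pattern.
#'
#' @param summaries WindowSummary data.frame with columns `subject`,
#'   `group`, `roi`, `window`, `value` (windows `pre_reversal`, `reversal`).
#' @param roi_order ROI ordering used for the linear weights.
#' @return One-row data.frame: `F`, `df1`, `df2`, `p`, `pes`.
#' @export
linear_trend_contrast <- function(summaries,
                                  roi_order = c("F", "C", "P", "O")) {
  s <- summaries[summaries$window %in% c("pre_reversal", "reversal"), ]
  w <- seq_along(roi_order) - mean(seq_along(roi_order))
  w <- w / sqrt(sum(w^2))
  subjects <- unique(s[c("subject", "group")])
  score <- vapply(seq_len(nrow(subjects)), function(i) {
    si <- s[s$subject == subjects$subject[i], ]
    dif <- vapply(roi_order, function(r) {
      si$value[si$roi == r & si$window == "reversal"] -
        si$value[si$roi == r & si$window == "pre_reversal"]
    }, 0)
    sum(w * dif) / sqrt(2)
  }, 0)
  fit <- stats::aov(score ~ factor(subjects$group))
  tab <- summary(fit)[[1]]
  data.frame(F = tab$`F value`[1], df1 = tab$Df[1], df2 = tab$Df[2],
             p = tab$`Pr(>F)`[1],
             pes = tab$`Sum Sq`[1] / sum(tab$`Sum Sq`))
}

#' Full 2 (group) x 4 (ROI) x 2 (time) analysis of window summaries
#'
#' Runs the mixed ANOVA over the pre-reversal/reversal window values,
#' the linear ROI-by-time trend-contrast group test, and Bonferroni-corrected
#' post-hoc pairwise ROI comparisons of the reversal-related change within
#' each group (paired t with Hedges g_av; family size defaults to the
#' number of tests performed).
#'
#' @param summaries WindowSummary data.frame (`subject`, `group`, `roi`,
#'   `window`, `value`) for one condition; baseline rows are ignored.
#' @param bonferroni_m Family size for the post-hoc correction; `NULL` uses
#'   the number of post-hoc tests.
#' @return List with `anova` ([mixed_anova] table), `trend`
#'   ([linear_trend_contrast] row) and `posthoc` (data.frame).
#' @export
mixed_anova_2x4x2 <- function(summaries, bonferroni_m = NULL) {
  s <- summaries[summaries$window %in% c("pre_reversal", "reversal"), ]
  s$roi <- factor(s$roi, levels = c("F", "C", "P", "O"))
  s$window <- factor(s$window, levels = c("pre_reversal", "reversal"))
  an <- mixed_anova(s, "value", "subject", "group", c("roi", "window"))
  trend <- linear_trend_contrast(s)

  ph <- list()
  for (gname in unique(s$group)) {
    sg <- s[s$group == gname, ]
    subj <- sort(unique(sg$subject))
    chg <- vapply(levels(s$roi), function(r) {
      wide <- sg[sg$roi == r, ]
      rev <- wide$value[wide$window == "reversal"][
        match(subj, wide$subject[wide$window == "reversal"])]
      pre <- wide$value[wide$window == "pre_reversal"][
        match(subj, wide$subject[wide$window == "pre_reversal"])]
      rev - pre
    }, numeric(length(subj)))
    chg <- matrix(chg, nrow = length(subj),
                  dimnames = list(NULL, levels(s$roi)))
    if (nrow(chg) < 2) next
    prs <- utils::combn(levels(s$roi), 2)
    for (j in seq_len(ncol(prs))) {
      tt <- paired_t_gav(chg[, prs[1, j]], chg[, prs[2, j]])
      ph[[length(ph) + 1L]] <- data.frame(
        group = gname, roi_a = prs[1, j], roi_b = prs[2, j],
        t = tt$statistic, df = tt$df, p = tt$p, g_av = tt$g_av)
    }
  }
  if (!length(ph))
    return(list(anova = an, trend = trend, posthoc = NULL))
  posthoc <- do.call(rbind, ph)
  m <- bonferroni_m %||% nrow(posthoc)
  posthoc$p_bonferroni <- pmin(1, posthoc$p * m)
  list(anova = an, trend = trend, posthoc = posthoc)
}
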