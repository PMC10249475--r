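# Mixed-design ANOVA engine against the car reference implementation and
# its analytic special cases.

library(car)

make_design <- function(n_per_group, seed, effect = NULL) {
  set.seed(seed)
  d <- expand.grid(roi = c("F", "C", "P", "O"),
                   window = c("pre_reversal", "reversal"),
                   subject = sprintf("s%02d", 1:(2 * n_per_group)),
                   stringsAsFactors = TRUE)
  d$group <- factor(ifelse(as.integer(sub("s", "", d$subject)) <= n_per_group,
                           "young", "older"))
  d$value <- rnorm(nrow(d))
  if (!is.null(effect)) d$value <- d$value + effect(d)
  d
}

car_reference <- function(d) {
  cells <- expand.grid(window = levels(d$window), roi = levels(d$roi))[, 2:1]
  subj <- levels(d$subject)
  Y <- matrix(NA, length(subj), nrow(cells))
  for (i in seq_len(nrow(d))) {
    r <- match(as.character(d$subject[i]), subj)
    cl <- which(cells$roi == d$roi[i] & cells$window == d$window[i])
    Y[r, cl] <- d$value[i]
  }
  grp <- factor(d$group[match(subj, d$subject)])
  idata <- data.frame(roi = factor(cells$roi, levels(d$roi)),
                      window = factor(cells$window, levels(d$window)))
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  mod <- lm(Y ~ grp)
  suppressWarnings(summary(Anova(mod, idata = idata, idesign = ~roi * window,
                                 type = 3), multivariate = FALSE))
}

test_that("mixed ANOVA matches car::Anova to near machine precision", {
  for (seed in c(101, 202, 303, 404, 505)) {
    d <- make_design(12, seed)
    mine <- mixed_anova(d, "value", "subject", "group", c("roi", "window"))
    ref <- car_reference(d)
    uni <- ref$univariate.tests
    map <- c(group = "grp", roi = "roi", "roi:group" = "grp:roi",
             window = "window", "window:group" = "grp:window",
             "roi:window" = "roi:window",
             "roi:window:group" = "grp:roi:window")
    for (eff in names(map)) {
      i <- match(eff, mine$effect)
      expect_equal(mine$F[i], unname(uni[map[[eff]], "F value"]),
                   tolerance = 1e-6)
      expect_equal(mine$p[i], unname(uni[map[[eff]], "Pr(>F)"]),
                   tolerance = 1e-6)
      expect_equal(mine$df1[i], unname(uni[map[[eff]], "num Df"]))
      expect_equal(mine$df2[i], unname(uni[map[[eff]], "den Df"]))
    }
    gg <- ref$pval.adjustments
    for (eff in c("roi", "roi:window")) {
      i <- match(eff, mine$effect)
      expect_equal(mine$gg_epsilon[i], unname(gg[map[[eff]], "GG eps"]),
                   tolerance = 1e-6)
    }
    expect_equal(mine$p_gg[mine$effect == "roi:window:group"],
                 unname(gg["grp:roi:window", "Pr(>F[GG])"]), tolerance = 1e-6)
  }
})

test_that("unbalanced group sizes still reproduce the reference", {
  d <- make_design(12, 42)
  d <- d[!(d$subject %in% c("s01", "s02", "s03")), ]
  d$subject <- droplevels(d$subject)
  mine <- mixed_anova(d, "value", "subject", "group", c("roi", "window"))
  uni <- car_reference(d)$univariate.tests
  expect_equal(mine$F[mine$effect == "roi:window:group"],
               unname(uni["grp:roi:window", "F value"]), tolerance = 1e-6)
  expect_equal(mine$F[mine$effect == "group"],
               unname(uni["grp", "F value"]), tolerance = 1e-6)
})

test_that("identical cell values give zero F everywhere", {
  d <- make_design(6, 1)
  d$value <- 3.7
  res <- mixed_anova(d, "value", "subject", "group", c("roi", "window"))
  expect_true(all(res$F == 0))
  expect_true(all(res$pes == 0))
})

test_that("two-level within factors have epsilon exactly 1", {
  d <- make_design(8, 2)
  res <- mixed_anova(d, "value", "subject", "group", c("roi", "window"))
  expect_equal(res$gg_epsilon[res$effect == "window"], 1)
  expect_equal(res$gg_epsilon[res$effect == "window:group"], 1)
  # and epsilon for a 4-level factor lies in (1/3, 1]
  eps <- res$gg_epsilon[res$effect == "roi"]
  expect_gt(eps, 1 / 3)
  expect_lte(eps, 1)
})

test_that("missing cells are reported by name", {
  d <- make_design(4, 3)
  d <- d[-5, ]
  expect_error(mixed_anova(d, "value", "subject", "group",
                           c("roi", "window")),
               "missing design cells")
})

test_that("single within-factor designs work (baseline ANOVA layout)", {
  set.seed(77)
  d <- expand.grid(roi = c("F", "C", "P", "O"),
                   subject = sprintf("s%02d", 1:16), stringsAsFactors = TRUE)
  d$group <- factor(rep(c("young", "older"), each = 4 * 8))
  d$value <- rnorm(nrow(d)) + ifelse(d$roi == "F", -1.2, 0)
  res <- mixed_anova(d, "value", "subject", "group", "roi")
  expect_setequal(res$effect, c("group", "roi", "roi:group"))
  expect_lt(res$p[res$effect == "roi"], 0.05)
})

test_that("the linear trend contrast flags opposed anterior/posterior slopes", {
  grad <- function(d) {
    lin <- c(F = -1.5, C = -0.5, P = 0.5, O = 1.5)[as.character(d$roi)]
    sign <- ifelse(d$group == "young", -1, 1)
    ifelse(d$window == "reversal", sign * lin * 0.8, 0)
  }
  d <- make_design(12, 11, effect = grad)
  tr <- linear_trend_contrast(d)
  expect_equal(tr$df1, 1)
  expect_equal(tr$df2, 22)
  expect_lt(tr$p, 0.01)
  # no group difference in the trend -> large p on average
  d0 <- make_design(12, 12)
  expect_gt(linear_trend_contrast(d0)$p, 0.001)
})

test_that("the full 2x4x2 wrapper returns ANOVA, trend and post-hocs", {
  d <- make_design(10, 21)
  out <- mixed_anova_2x4x2(d)
  expect_s3_class(out$anova, "mixed_anova")
  expect_equal(nrow(out$posthoc), 12) # 6 ROI pairs x 2 groups
  expect_true(all(out$posthoc$p_bonferroni >= out$posthoc$p))
  expect_true(all(out$posthoc$p_bonferroni <= 1))
})
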