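# Statistics battery: closed-form and cross-implementation oracles.

test_that("summary_ci reports mean, SD and the t confidence interval", {
  s <- summary_ci(c(1, 2, 3))
  expect_equal(s$estimate, 2)
  expect_equal(s$statistic, 1)
  half <- qt(0.975, 2) / sqrt(3)       # 2.48414
  expect_equal(s$ci_low, 2 - half, tolerance = 1e-9)
  expect_equal(s$ci_high, 2 + half, tolerance = 1e-9)
  cst <- summary_ci(rep(4.2, 5))
  expect_equal(cst$statistic, 0)
  expect_equal(cst$ci_low, 4.2)
  expect_equal(cst$ci_high, 4.2)
  expect_error(summary_ci(3), "at least 2")
})

test_that("one-sample t matches the closed-form df = 2 CDF", {
  r <- t_test(c(1, 2, 3), mu0 = 0, mode = "one_sample_two_tailed")
  expect_equal(r$statistic, 2 * sqrt(3), tolerance = 1e-9)
  # P(T2 <= t) = 1/2 + t / (2 sqrt(2 + t^2))
  tstat <- 2 * sqrt(3)
  p_oracle <- 2 * (1 - (0.5 + tstat / (2 * sqrt(2 + tstat^2))))
  expect_equal(r$p_value, p_oracle, tolerance = 1e-9)
  expect_equal(r$p_value, 0.0742, tolerance = 1e-3)
})

test_that("one-tailed t halves the two-tailed p on the favored side", {
  x <- c(0.4, 1.3, 0.9, 1.8, 0.2)
  two <- t_test(x, mode = "one_sample_two_tailed")
  one <- t_test(x, mode = "one_sample_one_tailed")
  expect_identical(one$tail, "greater")    # direction from the sample mean
  expect_equal(one$p_value, two$p_value / 2, tolerance = 1e-12)
  oneless <- t_test(-x, mode = "one_sample_one_tailed")
  expect_identical(oneless$tail, "less")
})

test_that("paired t aligns by specimen id and degrades gracefully", {
  x <- setNames(c(5, 7, 6, 9), paste0("S", 1:4))
  self <- t_test(x, x, mode = "paired")
  expect_equal(self$statistic, 0)
  expect_equal(self$p_value, 1)
  # alignment by name, not order
  y <- x[c(3, 1, 4, 2)] + c(1, 1, 1, 1)
  r <- t_test(x, y, mode = "paired")
  expect_equal(r$estimate, -1)
  expect_error(t_test(x, setNames(y, paste0("Q", 1:4)), mode = "paired"),
               "unmatched")
})

test_that("Shapiro-Wilk matches an independent reference implementation", {
  # W and p frozen from scipy.stats.shapiro on this fixed 12-point sample
  x <- c(2.31, 4.77, 1.05, 3.62, 5.90, 2.18, 4.04, 3.33, 6.21, 0.87, 3.95, 2.60)
  r <- shapiro_wilk(x)
  expect_equal(r$statistic, 0.9624759307, tolerance = 1e-6)
  expect_equal(r$p_value, 0.8185077727, tolerance = 1e-6)
  expect_lte(r$statistic, 1)
  expect_error(shapiro_wilk(rep(1, 10)), "zero variance")
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
})

test_that("three-way ANOVA matches brute-force sums of squares on a balanced design", {
  set.seed(11)
  d <- expand.grid(region = c("a", "b"), specimen = c("s1", "s2", "s3"),
                   side = c("left", "right"))
  d <- rbind(d, d)
  d$y <- rnorm(nrow(d)) + ifelse(d$region == "a", 0, 1.5)
  res <- three_way_anova(d, "y", c("region", "specimen", "side"))
  # brute force: balanced main-effects SS per factor + residual from the fit
  gm <- mean(d$y)
  ss_factor <- function(f) {
    ag <- tapply(d$y, d[[f]], mean)
    cnt <- table(d[[f]])
    sum(cnt * (ag - gm)^2)
  }
  for (f in c("region", "specimen", "side")) {
    expect_equal(res$sumsq[res$term == f], ss_factor(f), tolerance = 1e-9)
  }
  fit <- lm(y ~ region + specimen + side, data = d)
  expect_equal(res$sumsq[res$term == "Residuals"], sum(resid(fit)^2),
               tolerance = 1e-9)
  # F ratio arithmetic
  ms_res <- res$sumsq[res$term == "Residuals"] / res$df[res$term == "Residuals"]
  expect_equal(res$statistic[res$term == "region"],
               (ss_factor("region") / 1) / ms_res, tolerance = 1e-9)
  expect_error(three_way_anova(d[d$side == "left", ], "y",
                               c("region", "specimen", "side")),
               "single level")
})

test_that("Games-Howell matches the pingouin reference on unequal variances", {
  g <- list(a = c(10.1, 12.3, 9.8, 11.5, 10.9, 12.0, 11.1, 10.4),
            b = c(14.2, 19.9, 12.1, 17.6, 15.3, 21.4),
            c = c(9.1, 9.4, 9.0, 9.7, 9.2, 9.5, 9.3, 9.6, 9.35, 9.45))
  r <- games_howell(g)
  # frozen from pingouin.pairwise_gameshowell
  expect_equal(r$statistic, c(-3.883602, 5.119053, 5.114299), tolerance = 1e-5)
  expect_equal(r$df, c(5.479834, 7.673449, 5.022893), tolerance = 1e-5)
  expect_equal(r$p_value, c(0.022339, 0.002605, 0.008481), tolerance = 1e-4)
  # identical groups: p ~ 1, CI straddles zero
  same <- games_howell(list(x = c(1, 2, 3, 4), y = c(1, 2, 3, 4)))
  expect_gt(same$p_value, 0.999)
  expect_lt(same$ci_low, 0)
  expect_gt(same$ci_high, 0)
  expect_error(games_howell(list(a = 1, b = c(1, 2))), "n >= 2")
})

test_that("Games-Howell reduces to Tukey HSD for equal variances and sizes", {
  # groups share the identical centered residual vector, so sample variances
  # and sizes match exactly; only the Welch vs pooled df remain to differ
  set.seed(33)
  base <- scale(rnorm(60))[, 1]
  y <- c(base, base + 0.25, base + 0.5)
  g <- factor(rep(c("a", "b", "c"), each = 60))
  gh <- games_howell(split(y, g))
  tk <- TukeyHSD(aov(y ~ g))$g
  # same pairs: group1-group2 a-b, a-c, b-c vs Tukey b-a, c-a, c-b
  expect_equal(gh$p_value, tk[, "p adj"], tolerance = 0.05,
               ignore_attr = TRUE)
  expect_equal(-gh$diff, tk[, "diff"], tolerance = 1e-9, ignore_attr = TRUE)
})
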