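# Cohort statistics battery: summary with 95% CI, one-sample and paired
# t-tests, Shapiro-Wilk normality, main-effects three-way ANOVA with Type II
# sums of squares, and Games-Howell post-hoc comparisons.

stat_result <- function(test, estimate, statistic, df, p_value,
                        ci_low = NA_real_, ci_high = NA_real_,
                        tail = "two-sided", n = NA_integer_) {
  data.frame(test = test, estimate = estimate, statistic = statistic,
             df = df, p_value = p_value, ci_low = ci_low, ci_high = ci_high,
             tail = tail, n = n, stringsAsFactors = FALSE)
}

#' Mean, SD and 95% confidence interval of a sample
#'
#' The CI is the usual t-interval `mean +/- t(0.975, n-1) * SD / sqrt(n)`
#' with the sample (n-1) standard deviation.
#' @param values numeric sample, `n >= 2`.
#' @return one-row data.frame with `estimate` (mean), `statistic` (SD), `df`,
#'   `ci_low`, `ci_high`, `n`.
#' @export
summary_ci <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) stop("need at least 2 values")
  m <- mean(values)
  s <- sd(values)
  half <- qt(0.975, n - 1L) * s / sqrt(n)
  stat_result("summary", m, s, n - 1L, NA_real_, m - half, m + half,
              tail = NA_character_, n = n)
}

#' One-sample and paired t-tests
#'
#' One-sample tests compare a sample mean to `mu0`; the one-tailed variant
#' chooses its direction from the sign of `mean - mu0` unless `direction` is
#' given.  Paired tests match two samples by specimen: when both `x` and `y`
#' carry names, observations are aligned by name and unmatched specimens are
#' an error.
#'
#' @param x numeric sample (named by specimen for paired mode).
#' @param y second sample for `mode = "paired"`.
#' @param mu0 null value (default 0).
#' @param mode one of `"one_sample_two_tailed"`, `"one_sample_one_tailed"`,
#'   `"paired"`.
#' @param direction optional `"greater"` or `"less"` for the one-tailed test.
#' @return one-row data.frame (see [summary_ci()] for the column layout).
#' @export
t_test <- function(x, y = NULL, mu0 = 0,
                   mode = c("one_sample_two_tailed", "one_sample_one_tailed",
                            "paired"),
                   direction = NULL) {
  mode <- match.arg(mode)
  if (mode == "paired") {
    if (is.null(y)) stop("paired mode needs two samples")
    if (!is.null(names(x)) && !is.null(names(y))) {
      if (!setequal(names(x), names(y)))
        stop("paired samples have unmatched specimen ids")
      y <- y[names(x)]
    } else if (length(x) != length(y)) {
      stop("paired samples have unmatched lengths")
    }
    d <- x - y
    res <- safe_one_sample(d, 0, "two.sided")
    return(stat_result("paired_t", res$estimate, res$statistic, res$df,
                       res$p, res$ci[1L], res$ci[2L], "two-sided",
                       length(d)))
  }
  x <- x[!is.na(x)]
  if (length(x) < 2L) stop("need at least 2 values")
  if (mode == "one_sample_two_tailed") {
    res <- safe_one_sample(x, mu0, "two.sided")
    return(stat_result("one_sample_t", res$estimate, res$statistic, res$df,
                       res$p, res$ci[1L], res$ci[2L], "two-sided",
                       length(x)))
  }
  if (is.null(direction))
    direction <- if (mean(x) >= mu0) "greater" else "less"
  res <- safe_one_sample(x, mu0, direction)
  stat_result("one_sample_t", res$estimate, res$statistic, res$df, res$p,
              res$ci[1L], res$ci[2L], direction, length(x))
}

# t.test that tolerates zero-variance samples
safe_one_sample <- function(x, mu0, alternative) {
  if (sd(x) < 1e-300) {
    m <- mean(x)
    p <- if (isTRUE(all.equal(m, mu0))) 1 else 0
    tstat <- if (p == 1) 0 else sign(m - mu0) * Inf
    return(list(estimate = m, statistic = tstat, df = length(x) - 1L,
                p = p, ci = c(m, m)))
  }
  tt <- t.test(x, mu = mu0, alternative = alternative)
  list(estimate = unname(tt$estimate), statistic = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value, ci = as.numeric(tt$conf.int))
}

#' Shapiro-Wilk normality test
#'
#' Royston's approximation as implemented in base R.
#' @param values numeric sample, `3 <= n <= 5000`.
#' @return one-row data.frame with the W statistic and p-value.
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3L || length(values) > 5000L)
    stop("Shapiro-Wilk needs 3 <= n <= 5000")
  if (sd(values) < 1e-300) stop("zero variance")
  sw <- shapiro.test(values)
  stat_result("shapiro_wilk", NA_real_, unname(sw$statistic), NA_real_,
              sw$p.value, n = length(values))
}

#' Main-effects three-way ANOVA with Type II sums of squares
#'
#' Fits `response ~ factor1 + factor2 + factor3` (no interactions) and
#' reports Type II sums of squares, F and p per factor; Type II is robust to
#' the mild imbalance left by missing regions.
#'
#' @param table data.frame of measurements.
#' @param response name of the response column.
#' @param factors character vector of three factor column names (e.g.
#'   region/bone, specimen, side).
#' @return data.frame with one row per factor plus residuals: `term`,
#'   `sumsq`, `df`, `statistic`, `p_value`.
#' @export
three_way_anova <- function(table, response, factors) {
  if (length(factors) != 3L) stop("exactly three factors required")
  dat <- table[, c(response, factors)]
  dat <- dat[complete.cases(dat), ]
  for (f in factors) {
    dat[[f]] <- factor(dat[[f]])
    if (nlevels(dat[[f]]) < 2L)
      stop("factor has a single level: ", f)
  }
  fml <- stats::reformulate(factors, response)
  fit <- lm(fml, data = dat)
  a <- car::Anova(fit, type = 2)
  data.frame(term = rownames(a), sumsq = a[["Sum Sq"]], df = a[["Df"]],
             statistic = a[["F value"]], p_value = a[["Pr(>F)"]],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Games-Howell post-hoc pairwise comparisons
#'
#' For each pair of groups the Welch-type statistic
#' `t = (m_i - m_j) / sqrt(s_i^2/n_i + s_j^2/n_j)` with Welch-Satterthwaite
#' degrees of freedom is referred to the studentized-range distribution with
#' `k` groups at `q = |t| * sqrt(2)`; confidence intervals use the same
#' quantile.  Robust to unequal variances and sizes.
#'
#' @param groups named list of numeric samples (each `n >= 2`).
#' @param conf confidence level (default 0.95).
#' @return data.frame with one row per pair: `group1`, `group2`, `diff`,
#'   `se`, `statistic`, `df`, `p_value`, `ci_low`, `ci_high`.
#' @export
games_howell <- function(groups, conf = 0.95) {
  k <- length(groups)
  if (k < 2L) stop("need at least 2 groups")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  groups <- lapply(groups, function(g) g[!is.na(g)])
  ns <- vapply(groups, length, 0L)
  if (any(ns < 2L)) stop("every group needs n >= 2")
  ms <- vapply(groups, mean, 0)
  vs <- vapply(groups, var, 0)
  pairs <- utils::combn(k, 2L)
  out <- lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    se2 <- vs[i] / ns[i] + vs[j] / ns[j]
    se <- sqrt(se2)
    df <- se2^2 / (vs[i]^2 / (ns[i]^2 * (ns[i] - 1L)) +
                     vs[j]^2 / (ns[j]^2 * (ns[j] - 1L)))
    diff <- ms[i] - ms[j]
    tstat <- diff / se
    # ptukey/qtukey warn about reduced precision at very small fractional
    # df (groups of 2-3 observations); the values remain usable there
    p_val <- suppressWarnings(ptukey(abs(tstat) * sqrt(2), nmeans = k,
                                     df = df, lower.tail = FALSE))
    hw <- suppressWarnings(qtukey(conf, nmeans = k, df = df)) / sqrt(2) * se
    data.frame(group1 = names(groups)[i], group2 = names(groups)[j],
               diff = unname(diff), se = unname(se), statistic = unname(tstat),
               df = unname(df), p_value = unname(p_val),
               ci_low = unname(diff - hw), ci_high = unname(diff + hw),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
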