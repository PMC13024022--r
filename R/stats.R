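# Statistical battery: normality-dispatched parametric/nonparametric
# tests, their effect-size conventions, BH-FDR, post hoc power, the
# composite performance index, and univariate regression with BCa
# bootstrap confidence intervals.
#
# Effect-size conventions used throughout:
#   cohen_d_independent: (m1 - m2) / pooled SD
#   cohen_d_paired:      mean(diff) / sd(diff)  (= t / sqrt(n))
#   cliffs_delta:        |2U/(n1 n2) - 1|       (dominance probability gap)
#   rank_ratio:          W / (n'(n'+1)/2)       (signed-rank sum over its max,
#                        zero differences dropped)

stat_result <- function(test, statistic, df = NA_real_, p, effect,
                        effect_convention, extra = list()) {
  out <- c(list(test = test, statistic = unname(statistic), df = unname(df),
                p = unname(p), effect = unname(effect),
                effect_convention = effect_convention), extra)
  class(out) <- "stat_result"
  out
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: stat = %.4f%s, p = %.4g, %s = %.4f\n",
              x$test, x$statistic,
              if (is.na(x$df)) "" else sprintf(" (df = %g)", x$df),
              x$p, x$effect_convention, x$effect))
  invisible(x)
}

#' Shapiro-Wilk normality check
#'
#' @param x Numeric sample, 3 <= n <= 5000.
#' @return List with `W`, `p` and `normal` (p >= 0.05). A constant sample
#'   is flagged (`normal = NA`, `degenerate = TRUE`) rather than an error.
#' @export
shapiro_wilk <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L || n > 5000L) stop("Shapiro-Wilk requires 3 <= n <= 5000",
                                call. = FALSE)
  if (diff(range(x)) == 0) {
    return(list(W = NA_real_, p = NA_real_, normal = NA, degenerate = TRUE))
  }
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value, normal = sw$p.value >= 0.05,
       degenerate = FALSE)
}

#' Independent-samples t-test from summary statistics
#'
#' Pooled-variance t with df = n1 + n2 - 2, as used for group comparisons
#' of demographic and behavioral summaries; `t = (mean1 - mean2)/SE`.
#' Cohen's d uses the pooled SD. [t_independent()] on raw samples routes
#' through this function, so raw and summary inputs agree exactly.
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @return A `stat_result` (test `"t_independent"`).
#' @export
t_independent_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 > 0 || sd2 > 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 <= 0) stop("zero pooled variance", call. = FALSE)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (mean1 - mean2) / se
  stat_result("t_independent", t, df,
              2 * stats::pt(-abs(t), df),
              (mean1 - mean2) / sqrt(sp2), "cohen_d_independent")
}

#' Independent-samples t-test from raw samples
#'
#' @param x,y Numeric samples.
#' @return A `stat_result`, identical to the summary-statistic route.
#' @export
t_independent <- function(x, y) {
  t_independent_from_summary(mean(x), stats::sd(x), length(x),
                             mean(y), stats::sd(y), length(y))
}

#' Mann-Whitney U test with Cliff's delta
#'
#' U counts pairs where `x` exceeds `y` (ties counted half); p-value from
#' the normal approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric samples.
#' @return A `stat_result` (test `"mann_whitney_u"`, effect Cliff's delta).
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  )
  stat_result("mann_whitney_u", U, NA_real_, p,
              cliffs_delta_from_u(U, n1, n2), "cliffs_delta",
              extra = list(n1 = n1, n2 = n2))
}

#' Cliff's delta from a Mann-Whitney U statistic
#'
#' `|2U/(n1 n2) - 1|`: the absolute gap between the probability that a
#' value from the first sample exceeds one from the second and vice versa.
#'
#' @param U Mann-Whitney U for the first sample.
#' @param n1,n2 Sample sizes.
#' @return Effect size in \[0, 1\].
#' @export
cliffs_delta_from_u <- function(U, n1, n2) {
  if (U < 0 || U > n1 * n2) stop("U must lie in [0, n1*n2]", call. = FALSE)
  abs(2 * U / (n1 * n2) - 1)
}

#' Normality-dispatched paired test
#'
#' Computes differences `post - pre`, checks them with Shapiro-Wilk at
#' alpha = 0.05, and runs a paired t-test when normal (effect: paired
#' Cohen's d = t/sqrt(n)) or a Wilcoxon signed-rank test otherwise
#' (statistic W = sum of positive ranks after dropping zero differences,
#' midranks for ties; effect: rank ratio W / (n'(n'+1)/2); exact p for
#' n' <= 25 without ties, else normal approximation with continuity
#' correction).
#'
#' @param pre,post Paired numeric vectors, length >= 3.
#' @return A `stat_result` with test `"t_paired"` or `"wilcoxon_signed_rank"`.
#' @export
paired_tests <- function(pre, post) {
  n <- length(pre)
  if (n < 3L || length(post) != n) {
    stop("need paired samples of equal length >= 3", call. = FALSE)
  }
  d <- post - pre
  if (all(d == 0)) stop("all paired differences are zero", call. = FALSE)
  sw <- shapiro_wilk(d)
  if (isTRUE(sw$normal)) {
    t <- mean(d) / (stats::sd(d) / sqrt(n))
    return(stat_result("t_paired", t, n - 1, 2 * stats::pt(-abs(t), n - 1),
                       t / sqrt(n), "cohen_d_paired",
                       extra = list(n = n, shapiro_p = sw$p)))
  }
  dz <- d[d != 0]
  np <- length(dz)
  rk <- rank(abs(dz))
  W <- sum(rk[dz > 0])
  wmax <- np * (np + 1) / 2
  has_ties <- anyDuplicated(abs(dz)) > 0
  p <- if (np <= 25 && !has_ties) {
    # exact two-sided signed-rank p
    2 * min(stats::psignrank(W, np), stats::psignrank(wmax - W, np))
  } else {
    suppressWarnings(
      stats::wilcox.test(dz, exact = FALSE, correct = TRUE)$p.value
    )
  }
  stat_result("wilcoxon_signed_rank", W, NA_real_, min(p, 1), W / wmax,
              "rank_ratio", extra = list(n = n, n_nonzero = np,
                                         shapiro_p = sw$p))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param pvals Numeric p-values in \[0, 1\].
#' @return Adjusted p-values (step-up, monotone, capped at 1).
#' @export
bh_fdr <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Composite dual-task performance index
#'
#' `Perf = N_c / T`: correct responses per second of mean reaction time, a
#' speed-accuracy composite that avoids accuracy ceiling effects.
#'
#' @param n_c Number of correct responses (>= 0).
#' @param t Mean reaction time in seconds (> 0).
#' @return Perf value(s).
#' @export
perf_index <- function(n_c, t) {
  if (any(t <= 0)) stop("mean reaction time must be positive", call. = FALSE)
  if (any(n_c < 0)) stop("correct count must be non-negative", call. = FALSE)
  n_c / t
}

#' Post hoc power for an observed effect size
#'
#' For the t family the exact noncentral-t computation is used (ncp =
#' d*sqrt(n) for paired designs, d*sqrt(n1 n2/(n1+n2)) for independent).
#' For nonparametric effects, power is estimated by Monte-Carlo under a
#' normal shift alternative matched to the observed effect: Cliff's delta
#' maps to a shift via delta = 2*Phi(m/sqrt(2)) - 1, and the paired rank
#' ratio via its dominant pair term, p-hat ~ Phi(m*sqrt(2)).
#'
#' @param effect Observed effect size (convention per `family`).
#' @param n,n2 Sample size(s); `n2` only for independent designs.
#' @param family `"paired_t"`, `"independent_t"`, `"wilcoxon"` (paired,
#'   effect = rank ratio) or `"mann_whitney"` (effect = Cliff's delta).
#' @param alpha Two-sided significance level.
#' @param n_sim Monte-Carlo replicates for nonparametric families.
#' @param seed Seed for the Monte-Carlo families.
#' @return Estimated power in \[alpha, 1\]; attribute `method` records how.
#' @export
posthoc_power <- function(effect, n, n2 = NULL,
                          family = c("paired_t", "independent_t",
                                     "wilcoxon", "mann_whitney"),
                          alpha = 0.05, n_sim = 2000, seed = 1L) {
  family <- match.arg(family)
  stopifnot(is.finite(effect), n >= 2)
  if (family == "paired_t") {
    ncp <- effect * sqrt(n)
    df <- n - 1
  } else if (family == "independent_t") {
    stopifnot(!is.null(n2), n2 >= 2)
    ncp <- effect * sqrt(n * n2 / (n + n2))
    df <- n + n2 - 2
  }
  if (family %in% c("paired_t", "independent_t")) {
    tcrit <- stats::qt(1 - alpha / 2, df)
    pw <- stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-tcrit, df, ncp = ncp)
    return(structure(pw, method = "noncentral_t"))
  }
  # Monte-Carlo under a matched normal shift alternative
  m <- if (family == "mann_whitney") {
    sqrt(2) * stats::qnorm((min(abs(effect), 0.999) + 1) / 2)
  } else {
    stats::qnorm(pmin(pmax(effect, 1e-3), 1 - 1e-3)) / sqrt(2)
  }
  rej <- with_seed(seed, {
    vapply(seq_len(n_sim), function(i) {
      if (family == "mann_whitney") {
        x <- stats::rnorm(n, m)
        y <- stats::rnorm(n2)
        suppressWarnings(
          stats::wilcox.test(x, y, exact = FALSE)$p.value
        ) < alpha
      } else {
        d <- stats::rnorm(n, m)
        suppressWarnings(
          stats::wilcox.test(d, exact = FALSE)$p.value
        ) < alpha
      }
    }, logical(1))
  })
  structure(mean(rej), method = "monte_carlo_shift")
}

# slope of y ~ x by least squares, closed form
ls_slope <- function(x, y) stats::cov(x, y) / stats::var(x)

#' Univariate regression with a BCa bootstrap CI for the slope
#'
#' Ordinary least squares of `y` on `x`, reporting r, R-squared, the model
#' F statistic F(1, n-2) with its p-value, and a bias-corrected accelerated
#' (BCa) bootstrap 95% confidence interval for the slope over `n_boot`
#' case resamples (bias correction from the bootstrap distribution's
#' median displacement, acceleration from the jackknife skewness).
#'
#' @param x,y Numeric vectors, n >= 4, `x` non-constant.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Seed for resampling.
#' @param conf Confidence level (default 0.95).
#' @return A `regression_result`: list with slope, intercept, r, r_squared,
#'   f, df1, df2, p, ci_lower, ci_upper, n_boot, seed.
#' @export
linear_regression_bca <- function(x, y, n_boot = 2000, seed = 1L,
                                  conf = 0.95) {
  n <- length(x)
  stopifnot(n >= 4L, length(y) == n)
  if (stats::var(x) == 0) stop("x is constant", call. = FALSE)
  slope <- ls_slope(x, y)
  intercept <- mean(y) - slope * mean(x)
  r <- stats::cor(x, y)
  r2 <- r^2
  df2 <- n - 2
  f <- df2 * r2 / (1 - r2)
  p <- stats::pf(f, 1, df2, lower.tail = FALSE)

  boots <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    apply(idx, 1L, function(ii) {
      xi <- x[ii]
      if (stats::var(xi) == 0) return(NA_real_)
      ls_slope(xi, y[ii])
    })
  })
  boots <- boots[is.finite(boots)]
  # bias correction
  z0 <- stats::qnorm(mean(boots < slope) + 0.5 * mean(boots == slope))
  # acceleration from jackknife
  jack <- vapply(seq_len(n), function(i) ls_slope(x[-i], y[-i]), numeric(1))
  jm <- mean(jack)
  num <- sum((jm - jack)^3)
  den <- 6 * (sum((jm - jack)^2))^1.5
  a <- if (den == 0) 0 else num / den
  alpha2 <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  zalpha <- stats::qnorm(alpha2)
  adj <- stats::pnorm(z0 + (z0 + zalpha) / (1 - a * (z0 + zalpha)))
  ci <- unname(stats::quantile(boots, adj, type = 7))
  structure(
    list(slope = slope, intercept = intercept, r = r, r_squared = r2,
         f = f, df1 = 1L, df2 = df2, p = p,
         ci_lower = ci[1], ci_upper = ci[2], n_boot = n_boot, seed = seed),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "<regression> slope = %.4f [%.4f, %.4f], r = %.3f, R2 = %.3f, F(%d,%d) = %.3f, p = %.4g\n",
    x$slope, x$ci_lower, x$ci_upper, x$r, x$r_squared, x$df1, x$df2, x$f, x$p))
  invisible(x)
}

#' Implied correlation from a regression F statistic
#'
#' For a univariate model, `|r| = sqrt(F / (F + df2))`.
#'
#' @param f F statistic with 1 numerator df.
#' @param df2 Denominator degrees of freedom (n - 2).
#' @return Implied absolute correlation.
#' @export
r_from_f <- function(f, df2) sqrt(f / (f + df2))
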