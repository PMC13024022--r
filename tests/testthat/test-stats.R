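test_that("Shapiro-Wilk dispatch is calibrated and powered", {
  rej <- vapply(1:200, function(s) {
    withr::with_seed(s, shapiro_wilk(rnorm(50))$p < 0.05)
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.04)
  rej_exp <- vapply(1:100, function(s) {
    withr::with_seed(1000 + s, shapiro_wilk(rexp(50))$p < 0.05)
  }, logical(1))
  expect_gt(mean(rej_exp), 0.5)
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  const <- shapiro_wilk(rep(1, 10))
  expect_true(const$degenerate)
  expect_true(is.na(const$normal))
})

test_that("summary-statistic t-tests reproduce the demographic comparisons", {
  # younger group first: t = (mean_Y - mean_O)/SE, pooled variance, df = 35
  age <- t_independent_from_summary(23.105, 1.729, 19, 66.722, 6.086, 18)
  expect_equal(age$statistic, -30.010, tolerance = 0.01 / 30)
  expect_equal(age$df, 35)
  smi <- t_independent_from_summary(6.924, 0.789, 19, 7.350, 0.578, 18)
  expect_equal(smi$statistic, -1.866, tolerance = 0.01)
  vfa <- t_independent_from_summary(83.642, 36.440, 19, 98.533, 42.518, 18)
  expect_equal(vfa$statistic, -1.146, tolerance = 0.01)
  plm <- t_independent_from_summary(126.753, 46.731, 19, 109.781, 24.070, 18)
  expect_equal(plm$statistic, 1.377, tolerance = 0.01)
  expect_error(t_independent_from_summary(1, 0, 5, 1, 0, 5), "sd")
})

test_that("raw-sample and summary-statistic t routes agree exactly", {
  withr::with_seed(1, {
    x <- rnorm(12, 5, 2)
    y <- rnorm(15, 4, 1.5)
  })
  a <- t_independent(x, y)
  b <- t_independent_from_summary(mean(x), sd(x), 12, mean(y), sd(y), 15)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-10)
  expect_equal(a$p, b$p, tolerance = 1e-10)
  expect_equal(a$effect, b$effect, tolerance = 1e-10)
  expect_equal(t_independent(c(1, 2, 3), c(2, 1, 3))$statistic, 0)
})

test_that("Mann-Whitney U matches brute-force pair counting", {
  for (s in 1:5) {
    withr::with_seed(s, {
      x <- sample(1:20, 8, replace = TRUE)
      y <- sample(1:20, 7, replace = TRUE)
    })
    st <- mann_whitney_u(x, y)
    expect_equal(st$statistic, oracle_u_count(x, y))
    expect_equal(st$effect, oracle_cliffs_delta(x, y), tolerance = 1e-12)
  }
  # fully separated groups hit the extreme values
  sep <- mann_whitney_u(101:119, 1:18)
  expect_equal(sep$statistic, 19 * 18)
  expect_equal(sep$effect, 1)
  expect_equal(mann_whitney_u(1:18, 101:118)$statistic, 0)
})

test_that("Cliff's delta identities hold, including the printed accuracy contrast", {
  expect_equal(cliffs_delta_from_u(305, 19, 18), 0.784, tolerance = 1e-3)
  expect_equal(cliffs_delta_from_u(19 * 18 / 2, 19, 18), 0)
  expect_equal(cliffs_delta_from_u(19 * 18, 19, 18), 1)
  expect_error(cliffs_delta_from_u(400, 19, 18), "U must lie")
})

test_that("paired tests dispatch by normality and use the declared effect conventions", {
  withr::with_seed(2, {
    pre <- rnorm(19, 10, 2)
    post <- pre + rnorm(19, 1, 1)      # normal differences -> t branch
  })
  st <- paired_tests(pre, post)
  expect_equal(st$test, "t_paired")
  expect_equal(st$effect, st$statistic / sqrt(19), tolerance = 1e-12)
  # paired d identity at the printed values: t = 2.485, n = 19 -> d = 0.570
  expect_equal(2.485 / sqrt(19), 0.570, tolerance = 1e-3)
  expect_equal(4.186 / sqrt(19), 0.960, tolerance = 1e-3)
  withr::with_seed(3, {
    pre2 <- rnorm(19)
    post2 <- pre2 + rcauchy(19)        # heavy tails -> wilcoxon branch
  })
  st2 <- paired_tests(pre2, post2)
  expect_equal(st2$test, "wilcoxon_signed_rank")
  expect_equal(st2$effect_convention, "rank_ratio")
  np <- st2$n_nonzero
  expect_true(st2$effect >= 0 && st2$effect <= 1)
  # rank-ratio identity at the printed values: W = 184, n = 19 -> 0.968
  expect_equal(184 / (19 * 20 / 2), 0.968, tolerance = 1e-3)
  # all positive differences give W = max and rank ratio 1
  st3 <- paired_tests(rep(0, 10), exp(seq(0.1, 2, length.out = 10)))
  if (st3$test == "wilcoxon_signed_rank") expect_equal(st3$effect, 1)
  expect_error(paired_tests(1:5, 1:5), "zero")
})

test_that("BH adjustment matches the hand-computed step-up rule", {
  expect_equal(bh_fdr(0.02), 0.02)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  withr::with_seed(4, p <- runif(20))
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  o <- sample(20)
  expect_equal(bh_fdr(p[o]), adj[o])      # order equivariant
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("the performance index is correct responses per unit reaction time", {
  expect_equal(perf_index(100, 2), 50)
  expect_equal(perf_index(0, 1.3), 0)
  expect_equal(perf_index(60, 2), perf_index(60, 1) / 2)
  expect_error(perf_index(10, 0), "positive")
  expect_error(perf_index(-1, 1), "non-negative")
})

test_that("post hoc power behaves like the noncentral-t computation", {
  expect_equal(as.numeric(posthoc_power(0, 19, 18, "independent_t")), 0.05,
               tolerance = 1e-6)
  big <- posthoc_power(2.791, 19, 18, "independent_t")
  expect_gt(as.numeric(big), 0.99)
  # monotone in |d| at fixed n
  pws <- vapply(c(0.2, 0.5, 0.8, 1.2), function(d) {
    as.numeric(posthoc_power(d, 19, family = "paired_t"))
  }, numeric(1))
  expect_true(all(diff(pws) > 0))
  # nonparametric Monte-Carlo route returns a sane probability
  pw_mw <- posthoc_power(0.784, 19, 18, "mann_whitney", n_sim = 300, seed = 5)
  expect_true(as.numeric(pw_mw) > 0.3 && as.numeric(pw_mw) <= 1)
  expect_equal(attr(pw_mw, "method"), "monte_carlo_shift")
})

test_that("regression identities hold and the F statistic implies r", {
  x <- 1:10
  rr <- linear_regression_bca(x, 2 * x, n_boot = 200, seed = 1)
  expect_equal(rr$r, 1, tolerance = 1e-12)
  expect_equal(rr$r_squared, 1, tolerance = 1e-12)
  withr::with_seed(5, {
    xr <- rnorm(18)
    yr <- 0.7 * xr + rnorm(18, sd = 0.7)
  })
  rr2 <- linear_regression_bca(xr, yr, n_boot = 500, seed = 2)
  expect_equal(rr2$r_squared, rr2$r^2, tolerance = 1e-12)
  expect_equal(rr2$f, rr2$df2 * rr2$r_squared / (1 - rr2$r_squared),
               tolerance = 1e-10)
  expect_true(rr2$ci_lower < rr2$ci_upper)
  expect_error(linear_regression_bca(rep(1, 10), rnorm(10)), "constant")
  # the printed F(1,16) = 45.981 implies |r| = 0.861
  expect_equal(r_from_f(45.981, 16), 0.861, tolerance = 1e-3)
})

test_that("BCa intervals roughly cover the true slope at moderate n", {
  hits <- vapply(1:60, function(s) {
    withr::with_seed(s, {
      x <- rnorm(18)
      y <- 0.7 * x + rnorm(18, sd = sqrt(1 - 0.49))
    })
    rr <- linear_regression_bca(x, y, n_boot = 400, seed = s)
    rr$ci_lower <= 0.7 && 0.7 <= rr$ci_upper
  }, logical(1))
  expect_gt(mean(hits), 0.85)
})
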