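fs <- 500

test_that("Welch configuration yields the documented frequency resolution", {
  withr::with_seed(1, {
    rec <- recording(matrix(rnorm(30 * fs), 1), fs, "CZ")
  })
  p <- welch_psd(segment_epochs(rec, 5, 1), nfft = 2500)
  expect_equal(p$resolution, 0.2)
  expect_equal(diff(p$freqs[1:2]), 0.2)
  expect_true(all(p$psd >= 0))
  expect_error(welch_psd(segment_epochs(rec, 5, 1), nfft = 100), "nfft")
})

test_that("Parseval: sine and white-noise power are recovered by integration", {
  t_axis <- seq_len(30 * fs) / fs
  A <- 3
  rec <- recording(matrix(A * sin(2 * pi * 10 * t_axis), 1), fs, "CZ")
  p <- welch_psd(segment_epochs(rec, 5, 1), 2500)
  total <- pracma::trapz(p$freqs, p$psd[1, ])
  expect_equal(total, A^2 / 2, tolerance = 0.05)
  withr::with_seed(7, {
    wn <- recording(matrix(rnorm(30 * fs, sd = 2), 1), fs, "CZ")
  })
  pw <- welch_psd(segment_epochs(wn, 5, 1), 2500)
  expect_equal(pracma::trapz(pw$freqs, pw$psd[1, ]), 4, tolerance = 0.4)
})

test_that("band_power integrates the PSD over the band", {
  withr::with_seed(2, {
    rec <- recording(matrix(rnorm(30 * fs), 1), fs, "CZ")
  })
  p <- welch_psd(segment_epochs(rec, 5, 1), 2500)
  # flat synthetic spectrum: alpha (8-12 Hz) power = 4c
  p$psd[] <- 0.5
  expect_equal(unname(band_power(p, eeg_bands("alpha"))), 4 * 0.5,
               tolerance = 1e-10)
  p$psd[] <- 0
  expect_equal(unname(band_power(p, eeg_bands("delta"))), 0)
  # a 10 Hz sine concentrates its power in alpha
  t_axis <- seq_len(30 * fs) / fs
  ps <- welch_psd(segment_epochs(
    recording(matrix(sin(2 * pi * 10 * t_axis), 1), fs, "CZ"), 5, 1), 2500)
  expect_gt(band_power(ps, eeg_bands("alpha"))[1],
            20 * band_power(ps, eeg_bands("beta"))[1])
  expect_error(band_power(ps, band_definition("hf", 200, 300)), "outside")
})

test_that("scale equivariance: scaling a signal by k scales band power by k^2", {
  withr::with_seed(3, {
    rec <- recording(matrix(rnorm(2 * 20 * fs), 2), fs, c("A", "B"))
  })
  p1 <- band_power_table(welch_psd(segment_epochs(rec, 5, 1), 2500))
  rec3 <- recording(3 * rec$data, fs, rec$channel_labels)
  p3 <- band_power_table(welch_psd(segment_epochs(rec3, 5, 1), 2500))
  expect_equal(unclass(p3), 9 * unclass(p1), tolerance = 1e-9)
})

test_that("channel permutation equivariance of the PSD", {
  withr::with_seed(4, {
    rec <- recording(matrix(rnorm(3 * 20 * fs), 3), fs, c("A", "B", "C"))
  })
  p <- welch_psd(segment_epochs(rec, 5, 1), 2500)
  perm <- c(3, 1, 2)
  recp <- recording(rec$data[perm, ], fs, rec$channel_labels[perm])
  pp <- welch_psd(segment_epochs(recp, 5, 1), 2500)
  expect_equal(pp$psd, p$psd[perm, ], tolerance = 1e-12)
})

test_that("delta_psd is elementwise post minus pre", {
  withr::with_seed(5, {
    a <- matrix(abs(rnorm(10)), 2, 5,
                dimnames = list(c("A", "B"), eeg_bands()$band))
  })
  expect_equal(delta_psd(a, a), 0 * a, ignore_attr = TRUE)
  expect_equal(delta_psd(a, 2 * a), unclass(a), ignore_attr = TRUE)
  b <- a
  rownames(b) <- c("B", "A")
  expect_error(delta_psd(a, b), "mismatch")
})

test_that("an injected alpha power increase is recovered as a positive delta", {
  m <- default_montage()
  deltas <- vapply(1:5, function(s) {
    truth <- cohort_truth(n_young = 2, n_old = 2, seed = 100 + s)
    pair <- simulate_subject_pair(truth, "Y01", duration = 20)
    bp <- function(rec) {
      band_power_table(welch_psd(segment_epochs(rec, 5, 1), 2500))
    }
    delta_psd(bp(pair$pre), bp(pair$post))["C3", "alpha"]
  }, numeric(1))
  expect_gt(mean(deltas), 0)
  expect_gt(mean(deltas > 0), 0.6)
})

test_that("zero-delta subjects differ only by the noise realization", {
  truth <- cohort_truth(n_young = 2, n_old = 2,
                        power_effects = data.frame(
                          group = character(), channel = character(),
                          band = character(), center_freq = numeric(),
                          amplitude = numeric(), delta = numeric()),
                        coupling_effects = data.frame(
                          group = character(), region_i = character(),
                          region_j = character(), band = character(),
                          center_freq = numeric(), phase_lag = numeric(),
                          amp_pre = numeric(), amp_post = numeric()),
                        seed = 9)
  pair <- simulate_subject_pair(truth, "Y01", duration = 10)
  expect_false(identical(pair$pre$data, pair$post$data))
  # same marginal power scale
  expect_equal(sd(pair$pre$data), sd(pair$post$data), tolerance = 0.1)
})

test_that("channel-wise pre/post tests flag degenerate channels without crashing", {
  withr::with_seed(6, {
    mk <- function() {
      m <- matrix(abs(rnorm(10)), 2, 5,
                  dimnames = list(c("A", "B"), eeg_bands()$band))
      m
    }
    pre <- replicate(6, mk(), simplify = FALSE)
    post <- lapply(pre, function(m) {
      m2 <- m + matrix(rnorm(10, sd = 0.1), 2, 5)
      m2["B", ] <- m["B", ]   # degenerate: zero differences
      m2
    })
  })
  res <- channelwise_prepost_tests(pre, post, "alpha")
  expect_equal(nrow(res), 2)
  expect_equal(res$test[res$channel == "B"], "degenerate")
  expect_true(is.na(res$p[res$channel == "B"]))
  expect_false(is.na(res$p[res$channel == "A"]))
  expect_error(channelwise_prepost_tests(pre[1:2], post[1:2], "alpha"),
               "3 subjects")
})
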