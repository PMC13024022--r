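test_that("oscillator specs validate their band and coupling fields", {
  expect_error(oscillator("alpha", 20, 1), "outside")
  expect_error(oscillator("alpha", 10, 1, coupled_regions = "L-T"),
               "exactly two")
  o <- oscillator("alpha", 10, 2, target_channels = "CZ")
  expect_s3_class(o, "oscillator_spec")
})

test_that("simulated recordings are seeded, reproducible and reject degenerate input", {
  m <- default_montage()
  osc <- list(oscillator("alpha", 10, 2, target_channels = "CZ"))
  r1 <- simulate_recording(m, osc, duration = 5, seed = 3)
  r2 <- simulate_recording(m, osc, duration = 5, seed = 3)
  expect_identical(r1$data, r2$data)
  r3 <- simulate_recording(m, osc, duration = 5, seed = 4)
  expect_false(identical(r1$data, r3$data))
  expect_error(simulate_recording(m, list(), duration = 5,
                                  noise_amplitude = 0), "degenerate")
  expect_error(simulate_recording(m, osc, duration = 5, fs = 256), "500 or 1000")
})

test_that("an oscillator concentrates its variance inside its band", {
  m <- default_montage()
  base <- simulate_recording(m, list(), duration = 20, noise_amplitude = 5,
                             seed = 10)
  with_osc <- simulate_recording(
    m, list(oscillator("alpha", 10, 6, target_channels = "CZ")),
    duration = 20, noise_amplitude = 5, seed = 10)
  # background shares the seed, so the difference isolates the component
  added <- with_osc$data["CZ", ] - base$data["CZ", ]
  rec <- recording(matrix(added, 1), 500, "CZ")
  p <- welch_psd(segment_epochs(rec, 5, 1), 2500)
  total <- pracma::trapz(p$freqs, p$psd[1, ])
  inband <- band_power(p, eeg_bands("alpha"))[1]
  expect_gt(inband / total, 0.6)
  # Welch peak lies in the alpha band
  pk <- p$freqs[which.max(p$psd[1, ])]
  expect_true(pk >= 8 && pk <= 12)
})

test_that("coupled regions show strong wPLI at a quarter-cycle lag but not at zero lag", {
  m <- default_montage()
  mk <- function(lag, seed) {
    rec <- simulate_recording(
      m, list(oscillator("alpha", 10, 8, phase_lag = lag,
                         coupled_regions = c("L-T", "M-F"))),
      duration = 40, noise_amplitude = 3, seed = seed)
    wpli_matrix(map_to_regions(rec, m),
                eeg_bands("alpha"))$weights["L-T", "M-F"]
  }
  expect_gt(mk(pi / 2, 1), 0.8)
  lagged0 <- vapply(1:5, function(s) mk(0, 10 + s), numeric(1))
  expect_lt(mean(lagged0), 0.1)
})

test_that("cohort truth is reproducible and validates its correlation targets", {
  t1 <- cohort_truth(seed = 5)
  t2 <- cohort_truth(seed = 5)
  expect_identical(t1$subject_power, t2$subject_power)
  expect_identical(t1$subject_coupling, t2$subject_coupling)
  expect_equal(nrow(t1$subjects), 37)
  badR <- matrix(0.99, 5, 5); diag(badR) <- 1; badR[1, 2] <- badR[2, 1] <- -0.99
  expect_error(cohort_truth(correlations = badR), "positive definite")
  expect_error(simulate_subject_pair(t1, "Z99"), "unknown subject")
})

test_that("the cohort bundle realizes group structure and stays reproducible", {
  truth <- cohort_truth(seed = 21)
  co1 <- simulate_cohort(truth)
  co2 <- simulate_cohort(cohort_truth(seed = 21))
  expect_identical(co1$behavioral, co2$behavioral)
  expect_identical(co1$body, co2$body)
  b <- co1$behavioral
  expect_equal(nrow(b), 37)
  expect_true(all(is.na(b$MoCA_B[b$group == "young"])))
  expect_true(all(!is.na(b$MoCA_B[b$group == "old"])))
  expect_true(all(b$N_c <= b$N_total & b$N_c >= 0))
  expect_equal(b$Acc, b$N_c / b$N_total, tolerance = 1e-12)
  expect_true(all(b$T > 0))
  expect_true(all(co1$body$BMI > 0 & co1$body$VFA > 0 & co1$body$P_LM > 0))
  # configured directions: younger faster and more accurate
  expect_gt(mean(b$Acc[b$group == "young"]), mean(b$Acc[b$group == "old"]))
  expect_lt(mean(b$T[b$group == "young"]), mean(b$T[b$group == "old"]))
})

test_that("a configured accuracy gap is recovered as the matching Cohen's d", {
  bp <- oscnet:::default_behavioral_params()
  # set the latent gap to 2 SDs and check the realized standardized gap
  bp$acc_logit_mean <- c(young = bp$acc_logit_mean[["old"]] +
                           2 * bp$acc_logit_sd,
                         old = bp$acc_logit_mean[["old"]])
  ds <- vapply(1:12, function(s) {
    co <- simulate_cohort(cohort_truth(behavioral = bp, seed = 300 + s))
    b <- co$behavioral
    t_independent(b$Acc[b$group == "young"], b$Acc[b$group == "old"])$effect
  }, numeric(1))
  expect_lt(abs(mean(ds) - 2), 0.5)
})

test_that("older-group correlation targets are realized in expectation", {
  cors <- vapply(1:10, function(s) {
    co <- simulate_cohort(cohort_truth(seed = 400 + s))
    b <- co$behavioral[co$behavioral$group == "old", ]
    body <- co$body[co$body$group == "old", ]
    c(cor(b$MoCA_B, b$Acc), cor(b$MoCA_B, body$VFA))
  }, numeric(2))
  expect_gt(mean(cors[1, ]), 0.6)   # target +0.86
  expect_lt(mean(cors[2, ]), -0.2)  # target -0.53
})

test_that("null cohorts produce nominal behavioral false-positive rates", {
  bp <- oscnet:::default_behavioral_params()
  bp$acc_logit_mean <- c(young = 1.8, old = 1.8)
  bp$rt_meanlog <- c(young = log(1.5), old = log(1.5))
  ps <- vapply(1:40, function(s) {
    co <- simulate_cohort(cohort_truth(behavioral = bp, seed = 500 + s))
    b <- co$behavioral
    t_independent(b$T[b$group == "young"], b$T[b$group == "old"])$p
  }, numeric(1))
  expect_lt(mean(ps < 0.05), 0.2)  # ~5% expected; wide band at 40 runs
  expect_gt(mean(ps < 0.05), -0.01)
})
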