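fs <- 500

region_ts_from <- function(data, labels = paste0("R", seq_len(nrow(data)))) {
  structure(list(data = data, region_labels = labels, fs = fs),
            class = "region_ts")
}

test_that("region mapping is the unweighted member average", {
  m <- default_montage()
  withr::with_seed(1, {
    rec <- recording(matrix(rnorm(30 * 1000), 30), fs, m$channel_labels)
  })
  rts <- map_to_regions(rec, m)
  expect_equal(dim(rts$data), c(16, 1000))
  # single-channel region equals that channel
  expect_equal(rts$data["L-PreF", ], unname(rec$data["FP1", ]))
  # multi-channel region equals the mean
  lt <- colMeans(rec$data[c("T3", "T5"), ])
  expect_equal(rts$data["L-T", ], lt)
  # identical channels: average equals either; opposite channels cancel
  rec2 <- rec
  rec2$data["T5", ] <- rec2$data["T3", ]
  expect_equal(map_to_regions(rec2, m)$data["L-T", ],
               unname(rec2$data["T3", ]))
  rec3 <- rec
  rec3$data["T5", ] <- -rec3$data["T3", ]
  expect_equal(max(abs(map_to_regions(rec3, m)$data["L-T", ])), 0)
})

test_that("wPLI matches a brute-force evaluation of its definition", {
  withr::with_seed(2, {
    z <- matrix(complex(real = rnorm(4 * 600), imaginary = rnorm(4 * 600)),
                4, 600)
  })
  expect_equal(oscnet:::wpli_from_analytic(z), oracle_wpli(z),
               tolerance = 1e-12)
  # pipeline matrix on stochastic lagged signals vs the same definition
  x <- make_lagged_pair(6000, fs, 10, pi / 3, seed = 3)
  rts <- region_ts_from(x)
  m <- wpli_matrix(rts, eeg_bands("alpha"))
  expect_true(all(m$weights >= 0 & m$weights <= 1))
  expect_equal(m$weights, t(m$weights))
  expect_equal(unname(diag(m$weights)), c(0, 0))
})

test_that("constant 90-degree lag gives wPLI of one; zero lag gives zero", {
  t_axis <- seq_len(20 * fs) / fs
  x <- rbind(sin(2 * pi * 10 * t_axis), sin(2 * pi * 10 * t_axis - pi / 2))
  m <- wpli_matrix(region_ts_from(x), eeg_bands("alpha"))
  expect_equal(m$weights[1, 2], 1, tolerance = 1e-5)
  # proportional signals: Im C identically ~0, entry 0 by convention
  y <- rbind(sin(2 * pi * 10 * t_axis), 2 * sin(2 * pi * 10 * t_axis))
  m0 <- wpli_matrix(region_ts_from(y), NULL)
  expect_equal(m0$weights[1, 2], 0)
})

test_that("instantaneous mixtures of independent sources stay near the null", {
  vals <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      n <- 60 * fs
      s1 <- rnorm(n); s2 <- rnorm(n)
      x <- rbind(s1 + 0.4 * s2, 0.4 * s1 + s2)
    })
    wpli_matrix(region_ts_from(x), eeg_bands("alpha"))$weights[1, 2]
  }, numeric(1))
  expect_lt(mean(vals), 0.1)
})

test_that("estimator variance shrinks as the window count grows", {
  wpli_at <- function(n_sec, seed) {
    withr::with_seed(seed, {
      x <- rbind(rnorm(n_sec * fs), rnorm(n_sec * fs))
    })
    wpli_matrix(region_ts_from(x), eeg_bands("alpha"))$weights[1, 2]
  }
  few <- vapply(1:12, function(s) wpli_at(20, s), numeric(1))      # 10 windows
  many <- vapply(1:12, function(s) wpli_at(120, 100 + s), numeric(1)) # 60
  expect_lt(var(many), var(few))
})

test_that("mean connectivity strength averages the upper triangle", {
  w <- matrix(0.5, 16, 16); diag(w) <- 0
  cm <- structure(list(weights = w, band = "alpha", n_windows = 1,
                       region_labels = paste0("R", 1:16)),
                  class = "conn_matrix")
  expect_equal(mean_connectivity_strength(cm), 0.5)
  expect_equal(mean_connectivity_strength(matrix(0, 16, 16)), 0)
  withr::with_seed(4, {
    r <- matrix(runif(256), 16); r <- (r + t(r)) / 2; diag(r) <- 0
  })
  pairs <- combn(16, 2)
  brute <- mean(r[cbind(pairs[1, ], pairs[2, ])])
  expect_equal(mean_connectivity_strength(r), brute, tolerance = 1e-12)
})

test_that("edge differences are antisymmetric and recover injected coupling", {
  mk <- function(w) structure(list(weights = w, band = "alpha"),
                              class = c("conn_matrix"))
  withr::with_seed(5, {
    a <- matrix(runif(16), 4); a <- (a + t(a)) / 2; diag(a) <- 0
    b <- matrix(runif(16), 4); b <- (b + t(b)) / 2; diag(b) <- 0
  })
  expect_equal(edge_difference(mk(a), mk(a)), 0 * a)
  expect_equal(edge_difference(mk(a), mk(b)),
               -edge_difference(mk(b), mk(a)))
  expect_error(edge_difference(mk(a), structure(list(weights = b,
                                                     band = "beta"),
                                                class = "conn_matrix")),
               "band mismatch")
  # simulated coupling increase shows up on the injected edge
  mont <- default_montage()
  deltas <- vapply(1:5, function(s) {
    mk_rec <- function(amp, sd_seed) {
      simulate_recording(mont, list(
        oscillator("theta", 6, amp, phase_lag = pi / 2,
                   coupled_regions = c("L-T", "M-F"))),
        duration = 20, noise_amplitude = 5, seed = sd_seed)
    }
    pre <- wpli_matrix(map_to_regions(mk_rec(1.5, 2 * s), mont),
                       eeg_bands("theta"))
    post <- wpli_matrix(map_to_regions(mk_rec(3.5, 2 * s + 1), mont),
                        eeg_bands("theta"))
    edge_difference(pre, post)["L-T", "M-F"]
  }, numeric(1))
  expect_gt(mean(deltas), 0)
})
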