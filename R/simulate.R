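# Synthetic EEG cohort generator.
#
# Signals are a 1/f^a Gaussian background plus band-limited oscillatory
# components (narrowband-filtered noise carriers, or pure sinusoids).
# Inter-region coupling is injected by placing one shared carrier on two
# regions with a fixed analytic-signal phase shift between them, so the
# resulting wPLI is controllable: a nonzero lag gives strong phase-lag
# coupling, a zero lag emulates pure volume conduction (to which the wPLI
# must be blind). Pre-to-post effects are injected by rescaling oscillator
# amplitudes (power deltas) or coupling carriers (connectivity deltas).

#' Band-limited oscillator specification
#'
#' @param band Band label (one of [eeg_bands()] or a custom name when
#'   `low`/`high` are implied by `center_freq +/- bandwidth/2`).
#' @param center_freq Centre frequency in Hz; must lie inside the band.
#' @param amplitude Component amplitude in microvolts (sine-peak
#'   equivalent: the component RMS is `amplitude/sqrt(2)`); >= 0.
#' @param target_channels Channel labels receiving the component
#'   (independent realizations per channel); ignored when
#'   `coupled_regions` is given.
#' @param phase_lag Phase lag in radians between the two coupled regions.
#' @param coupled_regions Optional length-2 character vector of region
#'   labels sharing one carrier (first leads by `phase_lag`).
#' @param bandwidth Carrier bandwidth in Hz for `waveform = "narrowband"`.
#' @param waveform `"narrowband"` (filtered-noise carrier, default) or
#'   `"sine"` (random-phase sinusoid).
#' @return An `oscillator_spec` list.
#' @export
oscillator <- function(band, center_freq, amplitude, target_channels = NULL,
                       phase_lag = 0, coupled_regions = NULL, bandwidth = 1,
                       waveform = c("narrowband", "sine")) {
  waveform <- match.arg(waveform)
  stopifnot(amplitude >= 0, center_freq > 0)
  canonical <- eeg_bands()
  if (band %in% canonical$band) {
    b <- canonical[canonical$band == band, ]
    if (center_freq < b$low || center_freq > b$high) {
      stop("center_freq ", center_freq, " Hz outside ", band, " band (",
           b$low, "-", b$high, " Hz)", call. = FALSE)
    }
  }
  if (!is.null(coupled_regions) && length(coupled_regions) != 2L) {
    stop("coupled_regions must name exactly two regions", call. = FALSE)
  }
  structure(list(band = band, center_freq = center_freq,
                 amplitude = amplitude, target_channels = target_channels,
                 phase_lag = phase_lag, coupled_regions = coupled_regions,
                 bandwidth = bandwidth, waveform = waveform),
            class = "oscillator_spec")
}

# 1/f^exponent Gaussian noise via FFT spectral shaping, unit RMS
power_law_noise <- function(n, exponent) {
  x <- stats::rnorm(n)
  if (exponent == 0) return(x / stats::sd(x))
  X <- stats::fft(x)
  m <- seq_len(n) - 1
  f <- pmin(m, n - m)                  # symmetric frequency index
  f[1] <- 1                            # placeholder; DC is zeroed below
  shaped <- X * f^(-exponent / 2)
  shaped[1] <- 0
  out <- Re(stats::fft(shaped, inverse = TRUE) / n)
  out / stats::sd(out)
}

# narrowband unit-RMS carrier: white noise band-limited around center_freq
# in the frequency domain (numerically stable at very narrow bandwidths,
# and exactly band-limited so the component's variance stays in its band)
narrowband_carrier <- function(n, fs, center, bandwidth) {
  lo <- max(center - bandwidth / 2, 0.05)
  hi <- min(center + bandwidth / 2, fs / 2 * 0.99)
  X <- stats::fft(stats::rnorm(n))
  f <- (seq_len(n) - 1) * fs / n
  f_sym <- pmin(f, fs - f)                 # two-sided frequency axis
  X[f_sym < lo | f_sym > hi] <- 0
  x <- Re(stats::fft(X, inverse = TRUE) / n)
  x / stats::sd(x)
}

# shift a narrowband signal's phase by `lag` radians via its analytic signal
phase_shift <- function(x, lag) {
  Re(analytic_signal(x) * exp(-1i * lag))
}

#' Simulate a multichannel resting-state recording
#'
#' @param montage A `montage`.
#' @param oscillators List of [oscillator()] specs (may be empty if
#'   `noise_amplitude > 0`).
#' @param duration Length in seconds (>= 2).
#' @param fs Sampling rate, 500 or 1000 Hz.
#' @param noise_exponent Background spectral exponent a in 1/f^a.
#' @param noise_amplitude Background RMS in microvolts.
#' @param seed RNG seed; identical seeds give identical sample arrays.
#' @return An `eeg_recording` (channels x samples, physical-ref state).
#' @export
simulate_recording <- function(montage, oscillators, duration = 300,
                               fs = 500, noise_exponent = 1,
                               noise_amplitude = 10, seed = 1L) {
  stopifnot(inherits(montage, "montage"), duration >= 2)
  if (!fs %in% c(500, 1000)) stop("fs must be 500 or 1000 Hz", call. = FALSE)
  if (length(oscillators) == 0L && noise_amplitude == 0) {
    stop("degenerate all-zero signal: no oscillators and no background noise",
         call. = FALSE)
  }
  n <- round(duration * fs)
  chans <- montage$channel_labels
  with_seed(seed, {
    data <- matrix(0, length(chans), n, dimnames = list(chans, NULL))
    if (noise_amplitude > 0) {
      for (i in seq_along(chans)) {
        data[i, ] <- noise_amplitude * power_law_noise(n, noise_exponent)
      }
    }
    t_axis <- seq_len(n) / fs
    for (osc in oscillators) {
      rms <- osc$amplitude / sqrt(2)
      if (rms == 0) next
      if (!is.null(osc$coupled_regions)) {
        members <- lapply(osc$coupled_regions, function(r) {
          names(montage$region_map)[montage$region_map == r]
        })
        if (any(lengths(members) == 0)) {
          stop("coupled region not present in montage", call. = FALSE)
        }
        carrier <- if (osc$waveform == "sine") {
          sqrt(2) * sin(2 * pi * osc$center_freq * t_axis +
                          stats::runif(1, 0, 2 * pi))
        } else {
          narrowband_carrier(n, fs, osc$center_freq, osc$bandwidth)
        }
        lagged <- phase_shift(carrier, osc$phase_lag)
        for (ch in members[[1]]) data[ch, ] <- data[ch, ] + rms * carrier
        for (ch in members[[2]]) data[ch, ] <- data[ch, ] + rms * lagged
      } else {
        targets <- osc$target_channels %||% chans
        unknown <- setdiff(targets, chans)
        if (length(unknown)) {
          stop("oscillator targets unknown channels: ",
               paste(unknown, collapse = ", "), call. = FALSE)
        }
        for (ch in targets) {
          comp <- if (osc$waveform == "sine") {
            sqrt(2) * sin(2 * pi * osc$center_freq * t_axis +
                            stats::runif(1, 0, 2 * pi))
          } else {
            narrowband_carrier(n, fs, osc$center_freq, osc$bandwidth)
          }
          data[ch, ] <- data[ch, ] + rms * comp
        }
      }
    }
    recording(data, fs, chans)
  })
}

default_power_effects <- function() {
  rbind(
    data.frame(group = "young", channel = c("C3", "C4", "CZ", "CP5", "CP6",
                                            "T3", "T4", "T5"),
               band = "alpha", center_freq = 10, amplitude = 4, delta = 0.5,
               stringsAsFactors = FALSE),
    data.frame(group = "old", channel = c("PO4", "T6"),
               band = "gamma", center_freq = 36, amplitude = 2, delta = 0.4,
               stringsAsFactors = FALSE)
  )
}

default_coupling_effects <- function() {
  data.frame(
    group = "young",
    region_i = c("L-T", "L-T", "R-PreF"),
    region_j = c("M-F", "M-P", "R-P"),
    band = c("theta", "alpha", "beta"),
    center_freq = c(6, 10, 20),
    phase_lag = pi / 2,
    amp_pre = c(2, 3, 1.5),
    amp_post = c(3, 4.5, 2.2),
    stringsAsFactors = FALSE
  )
}

default_behavioral_params <- function() {
  list(
    # accuracy on the logit scale: bounded support matching Acc in (0, 1)
    acc_logit_mean = c(young = 2.2, old = 1.4), acc_logit_sd = 0.45,
    # reaction time lognormal: positive support, right-skewed
    rt_meanlog = c(young = log(1.15), old = log(1.85)), rt_sdlog = 0.22,
    moca_mean = 24, moca_sd = 3,
    bmi_mean = c(young = 23.769, old = 24.608),
    bmi_sd = c(young = 3.277, old = 4.185),
    smi_mean = c(young = 6.924, old = 7.350),
    smi_sd = c(young = 0.789, old = 0.578),
    vfa_mean = c(young = 83.642, old = 98.533),
    vfa_sd = c(young = 36.440, old = 42.518),
    plm_mean = c(young = 126.753, old = 109.781),
    plm_sd = c(young = 46.731, old = 24.070),
    task_seconds = 900
  )
}

# target rank correlations among the older group's latent variables,
# realized through a Gaussian copula so each marginal keeps its own family
default_correlation_targets <- function() {
  vars <- c("moca", "acc", "rt", "vfa", "plm")
  R <- diag(5)
  dimnames(R) <- list(vars, vars)
  R["moca", "acc"] <- 0.86
  R["moca", "rt"] <- -0.61
  R["moca", "vfa"] <- -0.53
  R["moca", "plm"] <- 0.51
  R["acc", "rt"] <- -0.60
  R["acc", "vfa"] <- -0.45
  R["acc", "plm"] <- 0.45
  R["rt", "vfa"] <- 0.30
  R["rt", "plm"] <- -0.30
  R["vfa", "plm"] <- -0.25
  R[lower.tri(R)] <- t(R)[lower.tri(R)]
  R
}

#' Cohort ground truth
#'
#' Bundles every configurable effect of the synthetic cohort: group sizes,
#' recording parameters, baseline oscillators, group-level pre-to-post
#' power and coupling deltas (expanded deterministically to per-subject
#' deltas with a subject-level random effect), behavioral parameters, and
#' the target correlation structure of the older group's cognitive and
#' metabolic variables.
#'
#' Defaults emulate the study conditions: 19 younger and 18 older adults,
#' 5-minute eyes-open recordings at 500 Hz over a 30-channel montage; a
#' posterior alpha rhythm as baseline; younger adults receive a widespread
#' alpha power increase post-task plus theta/alpha/beta coupling increases
#' (left-temporal and right-prefrontal hubs), older adults a focal gamma
#' increase at PO4/T6; the older group's accuracy, reaction time, MoCA,
#' visceral fat and lower-limb torque are coupled through a Gaussian
#' copula (cognitive score rising with accuracy and limb strength, falling
#' with visceral fat).
#'
#' @param n_young,n_old Group sizes (>= 2).
#' @param duration,fs Recording length (s) and sampling rate (Hz).
#' @param noise_exponent,noise_amplitude 1/f background parameters.
#' @param baseline List of [oscillator()] specs present pre and post.
#' @param power_effects data.frame(group, channel, band, center_freq,
#'   amplitude, delta): oscillator amplitude `amplitude` pre, scaled to
#'   `amplitude*sqrt(1+delta)` post (delta = fractional power change).
#' @param coupling_effects data.frame(group, region_i, region_j, band,
#'   center_freq, phase_lag, amp_pre, amp_post).
#' @param subject_sd SD of the per-subject random effect added to each
#'   group-level delta.
#' @param behavioral List of behavioral/body-composition parameters (see
#'   source of `default_behavioral_params`).
#' @param correlations Target latent correlation matrix for the older
#'   group (must be positive definite).
#' @param seed Master seed; identical seeds give bit-identical cohorts.
#' @return A `cohort_truth` object with per-subject effect tables
#'   (`subjects`, `subject_power`, `subject_coupling`).
#' @export
cohort_truth <- function(n_young = 19, n_old = 18, duration = 300, fs = 500,
                         noise_exponent = 1, noise_amplitude = 10,
                         baseline = list(
                           oscillator("alpha", 10, 3,
                                      target_channels = c("O1", "O2", "OZ",
                                                          "PO3", "PO4"))
                         ),
                         power_effects = default_power_effects(),
                         coupling_effects = default_coupling_effects(),
                         subject_sd = 0.1,
                         behavioral = default_behavioral_params(),
                         correlations = default_correlation_targets(),
                         seed = 42L) {
  stopifnot(n_young >= 2, n_old >= 2)
  ev <- eigen(correlations, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop("infeasible correlation matrix: not positive definite ",
         "(min eigenvalue ", signif(min(ev), 3), ")", call. = FALSE)
  }
  subjects <- data.frame(
    subject = c(sprintf("Y%02d", seq_len(n_young)),
                sprintf("O%02d", seq_len(n_old))),
    group = c(rep("young", n_young), rep("old", n_old)),
    stringsAsFactors = FALSE
  )
  # deterministic per-subject expansion of the group-level deltas
  subject_power <- with_seed(derive_seed(seed, "subject-power"), {
    do.call(rbind, lapply(seq_len(nrow(subjects)), function(i) {
      rows <- power_effects[power_effects$group == subjects$group[i], ,
                            drop = FALSE]
      if (nrow(rows) == 0) return(NULL)
      rows$subject <- subjects$subject[i]
      rows$delta <- pmax(rows$delta + stats::rnorm(nrow(rows), 0, subject_sd),
                         -0.9)
      rows
    }))
  })
  subject_coupling <- with_seed(derive_seed(seed, "subject-coupling"), {
    do.call(rbind, lapply(seq_len(nrow(subjects)), function(i) {
      rows <- coupling_effects[coupling_effects$group == subjects$group[i], ,
                               drop = FALSE]
      if (nrow(rows) == 0) return(NULL)
      rows$subject <- subjects$subject[i]
      jit <- 1 + stats::rnorm(nrow(rows), 0, subject_sd)
      rows$amp_post <- pmax(rows$amp_pre +
                              (rows$amp_post - rows$amp_pre) * jit, 0)
      rows
    }))
  })
  structure(
    list(n_young = n_young, n_old = n_old, duration = duration, fs = fs,
         noise_exponent = noise_exponent, noise_amplitude = noise_amplitude,
         baseline = baseline, power_effects = power_effects,
         coupling_effects = coupling_effects, subject_sd = subject_sd,
         behavioral = behavioral, correlations = correlations,
         subjects = subjects, subject_power = subject_power,
         subject_coupling = subject_coupling, seed = as.integer(seed)),
    class = "cohort_truth"
  )
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat(sprintf("<cohort_truth> %d young + %d old, %g s @ %g Hz, seed %d\n",
              x$n_young, x$n_old, x$duration, x$fs, x$seed))
  invisible(x)
}

subject_oscillators <- function(truth, subject_id, condition) {
  osc <- truth$baseline
  sp <- truth$subject_power
  if (!is.null(sp)) {
    rows <- sp[sp$subject == subject_id, , drop = FALSE]
    for (k in seq_len(nrow(rows))) {
      amp <- rows$amplitude[k] *
        if (condition == "post") sqrt(1 + rows$delta[k]) else 1
      osc <- c(osc, list(oscillator(rows$band[k], rows$center_freq[k], amp,
                                    target_channels = rows$channel[k])))
    }
  }
  sc <- truth$subject_coupling
  if (!is.null(sc)) {
    rows <- sc[sc$subject == subject_id, , drop = FALSE]
    for (k in seq_len(nrow(rows))) {
      amp <- if (condition == "post") rows$amp_post[k] else rows$amp_pre[k]
      osc <- c(osc, list(oscillator(rows$band[k], rows$center_freq[k], amp,
                                    phase_lag = rows$phase_lag[k],
                                    coupled_regions = c(rows$region_i[k],
                                                        rows$region_j[k]))))
    }
  }
  osc
}

#' Simulate one subject's pre/post recording pair
#'
#' The post recording embodies the subject's ground-truth power and
#' coupling deltas; pre and post are otherwise independent noise
#' realizations of the same generative model.
#'
#' @param truth A `cohort_truth`.
#' @param subject_id Subject identifier present in `truth$subjects`.
#' @param montage Montage (default [default_montage()]).
#' @param duration Override of `truth$duration` (e.g. for quick checks).
#' @return List with elements `pre` and `post` (`eeg_recording`s).
#' @export
simulate_subject_pair <- function(truth, subject_id,
                                  montage = default_montage(),
                                  duration = truth$duration) {
  stopifnot(inherits(truth, "cohort_truth"))
  if (!subject_id %in% truth$subjects$subject) {
    stop("unknown subject id: ", subject_id, call. = FALSE)
  }
  rec_for <- function(condition) {
    simulate_recording(
      montage, subject_oscillators(truth, subject_id, condition),
      duration = duration, fs = truth$fs,
      noise_exponent = truth$noise_exponent,
      noise_amplitude = truth$noise_amplitude,
      seed = derive_seed(truth$seed, paste(subject_id, condition))
    )
  }
  list(pre = rec_for("pre"), post = rec_for("post"))
}

#' Simulate a full cohort bundle
#'
#' Generates the behavioral and body-composition tables (group gaps and
#' older-group correlations realized by construction through a Gaussian
#' copula over latent normals) and exposes the EEG recordings through a
#' deterministic accessor rather than materializing ~gigabytes of signal.
#'
#' @param truth A `cohort_truth`.
#' @param montage Montage used for the recordings.
#' @return List with `truth`, `subjects`, `behavioral` (subject, group,
#'   N_total, N_c, T, Acc, Perf, MoCA_B — MoCA only for the old group),
#'   `body` (subject, group, BMI, SMI, VFA, P_LM) and `recording(subject,
#'   condition)`, a function returning the `eeg_recording`.
#' @export
simulate_cohort <- function(truth, montage = default_montage()) {
  stopifnot(inherits(truth, "cohort_truth"))
  bp <- truth$behavioral
  gen_group <- function(group, n) {
    R <- if (group == "old") truth$correlations else diag(5)
    z <- matrix(stats::rnorm(n * 5), n, 5) %*% chol(R)
    colnames(z) <- c("moca", "acc", "rt", "vfa", "plm")
    acc_lat <- stats::plogis(bp$acc_logit_mean[group] +
                               bp$acc_logit_sd * z[, "acc"])
    rt <- exp(bp$rt_meanlog[group] + bp$rt_sdlog * z[, "rt"])
    n_total <- pmax(10L, round(bp$task_seconds / (rt + 0.4)))
    n_c <- pmin(n_total, pmax(0L, round(acc_lat * n_total)))
    # lognormal VFA matched to the group's target mean/SD
    v_cv2 <- (bp$vfa_sd[group] / bp$vfa_mean[group])^2
    v_sdlog <- sqrt(log(1 + v_cv2))
    v_meanlog <- log(bp$vfa_mean[group]) - v_sdlog^2 / 2
    data.frame(
      group = group,
      N_total = n_total, N_c = n_c, T = rt, Acc = n_c / n_total,
      MoCA_B = if (group == "old") {
        pmin(30L, pmax(0L, round(bp$moca_mean + bp$moca_sd * z[, "moca"])))
      } else {
        NA_integer_
      },
      BMI = pmax(15, stats::rnorm(n, bp$bmi_mean[group], bp$bmi_sd[group])),
      SMI = pmax(4, stats::rnorm(n, bp$smi_mean[group], bp$smi_sd[group])),
      VFA = exp(v_meanlog + v_sdlog * z[, "vfa"]),
      P_LM = pmax(20, bp$plm_mean[group] + bp$plm_sd[group] * z[, "plm"]),
      stringsAsFactors = FALSE
    )
  }
  tabs <- with_seed(derive_seed(truth$seed, "behavioral"), {
    rbind(gen_group("young", truth$n_young), gen_group("old", truth$n_old))
  })
  tabs$subject <- truth$subjects$subject
  tabs$Perf <- perf_index(tabs$N_c, tabs$T)
  behavioral <- tabs[, c("subject", "group", "N_total", "N_c", "T", "Acc",
                         "Perf", "MoCA_B")]
  body <- tabs[, c("subject", "group", "BMI", "SMI", "VFA", "P_LM")]
  rownames(behavioral) <- rownames(body) <- NULL
  list(
    truth = truth,
    subjects = truth$subjects,
    behavioral = behavioral,
    body = body,
    recording = function(subject, condition = c("pre", "post")) {
      condition <- match.arg(condition)
      simulate_subject_pair(truth, subject, montage)[[condition]]
    }
  )
}

#' Canonical injected subnetwork for recovery experiments
#'
#' An eight-edge connected subnetwork: a left-temporal hub linked to
#' midline-frontal, central, parietal and occipital regions (plus one
#' left-parietal spur) — the kind of star-like enhancement cluster the
#' NBS is designed to detect.
#'
#' @return data.frame with columns `region_i`, `region_j` (8 rows).
#' @export
injected_subnetwork <- function() {
  data.frame(
    region_i = c("L-T", "L-T", "L-T", "L-T", "L-T", "L-T", "L-T", "L-T"),
    region_j = c("M-F", "R-C", "M-C", "M-P", "R-O", "M-O", "L-O", "L-P"),
    stringsAsFactors = FALSE
  )
}

#' Simulate a paired connectivity cohort at the matrix level
#'
#' Generates per-subject pre/post wPLI-like matrices directly (bypassing
#' signal simulation), for calibration and recovery experiments on the
#' paired network statistics: each subject's pre matrix is a common base
#' pattern plus subject noise, and the post matrix adds an edge-wise delta
#' that is zero-mean except on `effect_edges`, where its mean is
#' `effect_size` times the delta SD (i.e. `effect_size` is the per-edge
#' paired Cohen's d).
#'
#' @param n Number of subjects.
#' @param effect_edges `NULL` for a null cohort, or a data.frame with
#'   `region_i`/`region_j` (e.g. [injected_subnetwork()]).
#' @param effect_size Per-edge paired Cohen's d of the injected delta.
#' @param base_level,base_sd Mean and spread of the shared base matrix.
#' @param subject_sd SD of the subject-level deviation from the base.
#' @param delta_sd SD of the pre-to-post edge delta.
#' @param regions Region labels (default the 16-region montage labels).
#' @param seed RNG seed.
#' @return List with `pre` and `post` (lists of symmetric matrices in
#'   \[0, 1\]) and `effect_edges`.
#' @export
simulate_connectivity_cohort <- function(n, effect_edges = NULL,
                                         effect_size = 1.2,
                                         base_level = 0.3, base_sd = 0.05,
                                         subject_sd = 0.03, delta_sd = 0.04,
                                         regions = default_montage()$region_labels,
                                         seed = 1L) {
  nr <- length(regions)
  sym01 <- function(m) {
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 0
    pmin(pmax(m, 0), 1)
  }
  eff <- matrix(0, nr, nr, dimnames = list(regions, regions))
  if (!is.null(effect_edges)) {
    for (k in seq_len(nrow(effect_edges))) {
      i <- effect_edges$region_i[k]
      j <- effect_edges$region_j[k]
      eff[i, j] <- eff[j, i] <- effect_size * delta_sd
    }
  }
  with_seed(seed, {
    base <- matrix(stats::rnorm(nr * nr, base_level, base_sd), nr, nr,
                   dimnames = list(regions, regions))
    base <- sym01(base)
    pre <- post <- vector("list", n)
    for (s in seq_len(n)) {
      dev <- sym01(base + matrix(stats::rnorm(nr * nr, 0, subject_sd), nr, nr))
      delta <- matrix(stats::rnorm(nr * nr, 0, delta_sd), nr, nr)
      delta[lower.tri(delta)] <- t(delta)[lower.tri(delta)]
      diag(delta) <- 0
      pre[[s]] <- dev
      post[[s]] <- pmin(pmax(dev + delta + eff, 0), 1)
      dimnames(pre[[s]]) <- dimnames(post[[s]]) <- list(regions, regions)
    }
    list(pre = pre, post = post, effect_edges = effect_edges)
  })
}
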