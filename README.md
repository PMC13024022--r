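# oscnet

Resting-state EEG analysis of pre/post intervention designs: band-power
spectra, weighted-phase-lag-index (wPLI) functional networks, sparsity-AUC
graph topology, network-based-statistic (NBS) permutation inference, and a
behavioral/metabolic correlation layer — plus a seeded synthetic-cohort
generator so every stage can be validated against known ground truth.

## Who this is for

Researchers analysing multichannel resting-state EEG recorded before and
after an acute intervention (e.g. a motor–cognitive dual task) in two
groups (e.g. younger vs older adults), who want a reproducible,
fully-tested implementation of the standard analysis chain:

```
raw EEG ──► preprocess ──► Welch PSD / band powers ──► channel-wise pre/post tests
                 │
                 └──► 16-region wPLI ──► whole-brain strength, NBS
                              └──► thresholded graphs ──► Eg/Eloc/Lp/Cp/Dc/Bc AUC
behavioral + body composition ──► group tests, univariate regressions (BCa CIs)
```

## The core quantities

* **Welch PSD**, 5 s Hamming epochs at 1 s steps (80% overlap), nfft 2500
  at 500 Hz → 0.2 Hz resolution; band powers over delta 0.5–4, theta 4–8,
  alpha 8–12, beta 12–30, gamma 30–45 Hz; ΔPSD = post − pre.
* **wPLI** between region-averaged signals,
  `wPLI = |E[Im C]| / E[|Im C|]` with `C` the analytic cross-spectrum —
  insensitive to zero-lag (volume-conducted) coupling.
* **Graph topology** on proportionally thresholded binary graphs over
  sparsities 0.2–0.6 (step 0.05): global/local efficiency, characteristic
  path length, clustering, degree and betweenness centrality, summarized
  by trapezoidal AUC.
* **Statistics**: Shapiro–Wilk-dispatched t / Wilcoxon / Mann–Whitney
  tests with Cohen's d (`d = t/√n` paired), Cliff's delta
  (`|2U/(n₁n₂) − 1|`) and the rank ratio `p̂ = W / (n'(n'+1)/2)`;
  Benjamini–Hochberg FDR; NBS (cluster-forming p < 0.01, sign-flip
  permutations, component size statistic); univariate regressions with
  BCa bootstrap CIs; `Perf = N_c / T`.

## Worked example

Simulate two regions coupled at a quarter-cycle phase lag in the alpha
band, recover the coupling as wPLI, and run the effect-size identities
used for group reporting:

```r
library(oscnet)

mont <- default_montage()
rec <- simulate_recording(
  mont,
  list(oscillator("alpha", 10, 8, phase_lag = pi / 2,
                  coupled_regions = c("L-T", "M-F"))),
  duration = 40, noise_amplitude = 3, seed = 7)
m <- wpli_matrix(map_to_regions(rec, mont), eeg_bands("alpha"))
m$weights["L-T", "M-F"]
#> [1] 0.9999873

# the same edge without any phase lag (pure volume conduction)
rec0 <- simulate_recording(
  mont, list(oscillator("alpha", 10, 8, phase_lag = 0,
                        coupled_regions = c("L-T", "M-F"))),
  duration = 40, noise_amplitude = 3, seed = 7)
wpli_matrix(map_to_regions(rec0, mont), eeg_bands("alpha"))$weights["L-T", "M-F"]
#> [1] 0.1531375

# effect-size conventions
cliffs_delta_from_u(305, n1 = 19, n2 = 18)   # accuracy group contrast
#> [1] 0.7836257
2.485 / sqrt(19)                             # paired Cohen's d from t
#> [1] 0.5700981
r_from_f(45.981, df2 = 16)                   # |r| implied by F(1,16)
#> [1] 0.8613108
```

The first number says the injected quarter-cycle coupling is recovered as
near-perfect phase-lag consistency; the second that an instantaneous
(zero-lag) copy of the same carrier is suppressed to the estimator's null
level for a 40 s recording (a single-edge null value fluctuates seed to
seed; the tests assert a 10-seed mean at or below 0.1). The last three
reproduce the package's effect-size conventions from reported test
statistics: a dominance gap of 0.78 between group accuracy distributions,
a paired standardized change of 0.57, and a correlation of 0.86 implied by
a univariate model F.

A full synthetic study runs through one call:

```r
cfg <- run_config(
  truth = cohort_truth(n_young = 5, n_old = 5, duration = 10, seed = 42),
  bands = eeg_bands()[eeg_bands()$band %in% c("theta", "alpha"), ],
  n_perm = 200, n_boot = 200, seed = 42, out_dir = "run1")
report <- run_pipeline(cfg)
report_tables(report)$table1   # demographic-style comparison
```

Identical config and seed give byte-identical outputs.

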