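---
title: "Methods: spectral power, phase-lag networks and their statistics in oscnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral power, phase-lag networks and their statistics in oscnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscnet)
```

`oscnet` implements a complete pre/post resting-state EEG analysis chain of
the kind used to study how an acute intervention (here, a motor–cognitive
dual task) reshapes neural oscillations and functional brain networks in
younger versus older adults, together with a synthetic-cohort generator
that makes every stage testable against known ground truth. This vignette
is the package's own account of the models, the defaults, and the design
choices that were genuinely open.

## The analysis model

### Preprocessing

A recording is a channels × samples matrix in microvolts with a sampling
rate and an ordered label set. The cleanup chain is deterministic and runs
in a fixed, logged order:

1. drop reference-adjacent channels (mastoids A1/A2),
2. zero-phase Butterworth band-pass (order 4 per pass, 0.1–45 Hz default),
3. zero-phase biquad notch (Q = 30) at the line frequency,
4. integer-factor decimation behind an order-8 anti-alias low-pass at 80%
   of the target Nyquist,
5. amplitude-based epoch rejection (±100 µV default on 5 s segments),
6. common-average re-referencing.

All filters are applied forward–backward (`signal::filtfilt`), so mid-band
components suffer no group delay; the zero-phase property is asserted in
the tests by cross-correlating a mid-band sine with its filtered version.
Rejection precedes re-referencing so that contaminated spans never enter
the average. Independent-component artifact removal is deliberately *not*
part of the chain: it requires operator judgment that cannot be made
reproducible, and the synthetic data carry no ICA-removable artifacts. A
pluggable `cleaner` hook on the epoch set is provided where such a step
would sit.

The amplitude threshold itself is a convention rather than a derivation:
±100 µV is the conservative default commonly used for eyes-open scalp
EEG, and it is configurable.

### Welch spectra and band powers

Power spectral density is estimated by Welch's method: 5 s Hamming-windowed
epochs slid by 1 s (80% overlap, 2000 samples at 500 Hz), per-epoch mean
removal, zero-padding to `nfft = 2500` so the frequency resolution is
`fs/nfft = 0.2` Hz, and averaging of one-sided periodograms with window
power normalization. The scaling satisfies Parseval: integrating the PSD
over frequency recovers the signal variance (a sine of amplitude A
integrates to A²/2; both are asserted in the tests).

Band powers integrate the PSD over delta 0.5–4, theta 4–8, alpha 8–12,
beta 12–30 and gamma 30–45 Hz by the trapezoid rule. Band edges are
half-open on the upper side (the gamma band closed at 45 Hz) so shared
edges are never counted twice. The task-modulation index ΔPSD is the
elementwise post-minus-pre band-power matrix; the *scalar* ΔPSD used in the
correlation layer is the mean delta over a declared channel/band selection
(`delta_psd_scalar`). Which channels and bands enter that scalar is not a
reconstruction of anything — it is a configuration recorded in the result's
attributes, defaulting to all channels and bands.

### wPLI connectivity

Channels are averaged (unweighted) into 16 scalp regions before
connectivity, giving region time series. For one band, the series are
zero-phase band-pass filtered, cut into non-overlapping 2 s windows, each
window edge-tapered (10% cosine) and Hilbert-transformed, and the
instantaneous cross-spectrum \(C_{ij}(t) = z_i(t)\,\overline{z_j(t)}\)
evaluated. The weighted phase lag index is

\[
\mathrm{wPLI}_{ij} \;=\; \frac{\lvert E[\mathrm{Im}\, C_{ij}]\rvert}
                               {E[\lvert \mathrm{Im}\, C_{ij}\rvert]},
\]

the magnitude-weighted consistency of the lead/lag sign. Because
zero-lag (volume-conducted) coupling contributes no imaginary part, the
index is insensitive to instantaneous mixing — the property the tests
verify explicitly.

**Where the expectation runs is a real design choice.** Computing the
ratio *within* each 2 s window and averaging the per-window values looks
natural but is badly biased under the null: a 2 s alpha-band window holds
roughly a dozen independent phase observations, so the per-window ratio
concentrates around \(1/\sqrt{n_\mathrm{eff}} \approx 0.3\) even for
unrelated signals, and averaging such ratios across windows does not
remove the bias. We measured ≈0.36 for zero-lag mixtures at 150 windows
with that variant. The package therefore defaults to the *pooled* form:
numerator and denominator sums are accumulated across all samples of all
kept windows and divided once, which is the direct evaluation of the
definition above and whose null bias vanishes with total sample count
(≈0.02 under the same conditions). The per-window variant remains
available (`estimator = "per-window"`) for comparison. Windows inherit the
preprocessing keep-mask; rejected spans contribute no windows.
Whether the windows should overlap is left at the conventional
non-overlapping default.

The 30-electrode → 16-region partition follows the 10–20 geometry
(anterior–posterior row × laterality): prefrontal L/R, frontal L/M/R,
central L/M/R, parietal L/M/R, temporal L/R, occipital L/M/R, with PO4
assigned to the right occipital region. It is an informed reconstruction,
clearly documented as such, and user-overridable.

### Graph topology

Connectivity matrices are proportionally thresholded: the `ceiling(s·120)`
strongest edges are kept and binarized at each sparsity s in
0.20–0.60 (step 0.05), with ties broken in fixed lexicographic node order
so the graph is deterministic. Binary graphs (rather than weighted ones)
are the default because the sparsity-AUC analysis is conventionally
binary and the choice is not otherwise determined; the thresholded weights
are retained so a weighted variant can be added behind the same surface.

Per graph we compute global efficiency (mean inverse shortest path,
disconnected pairs contributing zero), local efficiency (mean over nodes
of the neighborhood subgraph's global efficiency), characteristic path
length (mean shortest path over *connected* pairs — excluding disconnected
pairs avoids infinities at sparse thresholds; a largest-component variant
is selectable), clustering coefficient (degree < 2 contributing zero),
degree and betweenness centrality. Shortest-path machinery comes from
igraph; every metric is cross-checked in the tests against brute-force
Floyd–Warshall and exhaustive path-enumeration oracles. Metric curves over
the sparsity grid are reduced to a trapezoidal AUC, the
threshold-independent summary used for group statistics.

### The statistical battery

Group and pre/post comparisons dispatch on a Shapiro–Wilk normality check
at α = 0.05 (the conventional threshold; logged per test):

* normal → paired or pooled-variance independent t, effect size Cohen's d
  (paired form \(d = t/\sqrt{n}\), an exact identity by construction);
* non-normal → Wilcoxon signed-rank (zeros dropped, midranks for ties,
  exact p for n ≤ 25 without ties, else normal approximation with
  continuity correction) with the rank-ratio effect
  \(\hat p = W / \tfrac{n'(n'+1)}{2}\), or Mann–Whitney U with Cliff's
  delta \(|2U/(n_1 n_2) - 1|\).

Multiplicity is handled two ways. Electrode-wise spectral tests are
Benjamini–Hochberg adjusted within each group × band family (the family
definition is a recorded convention, not a given). Connectivity contrasts
use the network-based statistic: edge-wise paired t-tests, a cluster-forming
threshold of p < 0.01, connected components of supra-threshold edges scored
by their *size* (edge count — the canonical choice where nothing else is
specified), and a family-wise-error null built from within-subject sign
flips of the delta matrices, with
\(p_{\mathrm{FWE}} = (1 + \#\{\text{perm max} \ge \text{observed}\})/(n_{\mathrm{perm}}+1)\).

Univariate regressions report slope, r, R², F(1, n−2) and a
bias-corrected accelerated bootstrap CI for the slope over case resamples
(default 2000): bias correction from the bootstrap distribution's
displacement around the estimate, acceleration from the jackknife
skewness. Post hoc power uses the exact noncentral-t computation for the
t family; for nonparametric effects it is a Monte-Carlo estimate under a
normal shift alternative matched to the observed effect (Cliff's delta via
\(\delta = 2\Phi(m/\sqrt2) - 1\), the paired rank ratio via its dominant
pair term \(\hat p \approx \Phi(m\sqrt2)\)). The power method is recorded
on the result; it is a declared convention, since post hoc power
procedures are rarely identifiable from reported percentages.

The composite performance index is \(\mathrm{Perf} = N_c/T\) — correct
responses per second of mean reaction time — which resists accuracy
ceiling effects by rewarding speed.

## The synthetic cohort

The generator defines the conditions under which the pipeline is
validated; its defaults are fixed once and mirror the study design the
package targets:

* 19 younger and 18 older subjects, one pre and one post 5-minute
  eyes-open recording each at 500 Hz over the 30-channel montage;
* background: 1/f Gaussian noise (exponent 1, RMS 10 µV), spectrally
  shaped in the frequency domain;
* oscillators: narrowband carriers (white noise band-limited in the
  frequency domain — exactly band-limited and numerically stable at 1 Hz
  bandwidths where narrow IIR filters are not) or pure sinusoids, scaled
  so `amplitude` is the sine-peak equivalent (component RMS
  `amplitude/√2`); a posterior 10 Hz alpha rhythm as baseline;
* coupling: one shared carrier placed on two regions with a fixed
  analytic-signal phase rotation between them. A quarter-cycle lag yields
  wPLI ≈ 1 on that edge; a zero lag emulates pure volume conduction and
  must leave wPLI at the null — both are asserted;
* pre→post effects: younger subjects get a widespread +50% alpha-power
  change at central/parietal/temporal channels plus theta/alpha/beta
  coupling increases anchored at left-temporal and right-prefrontal hubs;
  older subjects get a focal +40% gamma change at PO4/T6. Group deltas are
  expanded deterministically to per-subject deltas with a 0.1-SD random
  effect;
* behavior: accuracy from a logit-normal (bounded in (0,1)) and reaction
  time from a lognormal (positive, right-skewed), with group shifts sized
  to produce a Cliff's delta near 0.78 on accuracy and a Cohen's d near 2
  on reaction time at the default sample sizes; trial counts follow from
  a 900 s response-contingent task at the subject's pace;
* the older group's MoCA, accuracy, reaction time, visceral fat area and
  lower-limb torque are coupled through a Gaussian copula, so each
  marginal keeps its own family while hitting target rank correlations
  (MoCA↑ with accuracy r ≈ 0.86 and torque, ↓ with visceral fat); the
  target matrix is checked for positive definiteness and infeasible
  targets are rejected with a diagnostic. MoCA is generated only for the
  older group, matching a screening instrument administered to older
  adults only.

Everything derives from one master seed through tagged substreams
(`derive_seed`), so identical seeds give bit-identical cohorts and any
stage can be re-run in isolation.

What the generator does **not** emulate: realistic head-model mixing
beyond instantaneous linear combinations, eye-blink/EMG artifacts, heart
rate or exercise physiology, and task-period EEG. Passing tests therefore
demonstrate that the pipeline recovers effects of the assumed generative
form at realistic sizes and noise levels — not that it is robust to every
artifact structure of real recordings.

## Numerical choices and problem sizes

* The analytic signal is computed by the FFT construction (zeroing
  negative frequencies); windows are edge-tapered before transforming to
  suppress finite-window bias.
* wPLI denominators of zero (proportional signals, Im C ≡ 0) define the
  entry as 0.
* Degenerate inputs are flagged, not crashed on: constant samples in the
  normality check, all-zero paired differences in channel-wise tests,
  empty supra-threshold sets in the NBS.
* Thresholding ties, FDR families, the ΔPSD scalar selection, the
  normality α and the Wilcoxon zero/tie policy are all logged in results
  or metadata, since each is a convention.
* Test and example runs use reduced problem sizes chosen to exercise every
  code path at meaningful effect sizes: 5 + 5 subjects, 10 s recordings
  and two bands for end-to-end runs; 19 paired subjects at the matrix
  level with 1000 permutations and 20 replicate seeds for NBS
  calibration/recovery; 500 replicate datasets (n = 18, ρ = 0.7, 1000–2000
  resamples) for bootstrap coverage. Full-scale runs (37 subjects,
  5-minute recordings, 5000 permutations) use identical code paths.

## Known limitations

* BCa case-resampling intervals for a regression slope at n = 18
  undercover slightly (a well-known small-sample property, ~91–93%
  observed against the 95% nominal level, matching R's reference
  implementation to within Monte-Carlo error). The package reports what
  the method gives; it does not recalibrate.
* The per-window wPLI variant is biased under the null and should only be
  used for comparison with literature that used it.
* The region partition is a documented reconstruction; analyses that
  depend on exact electrode–region assignment should supply their own map.
* Amplitude-threshold rejection does not model ocular or myogenic
  topographies; with ICA excluded, heavily contaminated real data will
  need external cleaning before entering the chain.
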