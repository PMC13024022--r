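# Welch spectral estimation and band powers.
#
# Scaling convention: one-sided power spectral density in uV^2/Hz with
# window power normalization sum(w^2), so the trapezoid/rectangle integral
# of the PSD over frequency recovers the signal variance (Parseval).

#' Welch power spectral density of an epoch set
#'
#' Per kept epoch and channel: remove the epoch mean, apply a Hamming
#' window, zero-pad to `nfft`, take the one-sided periodogram, then average
#' periodograms over epochs. With 5 s epochs at 500 Hz and `nfft = 2500`
#' the frequency resolution is 0.2 Hz.
#'
#' @param es An `epoch_set` (overlapping epochs give the classic Welch
#'   variance reduction).
#' @param nfft FFT length in samples; must be at least the epoch length.
#' @return A `psd_result`: list with `freqs` (Hz), `psd` (channel x
#'   frequency matrix, uV^2/Hz), `nfft`, `resolution` (= fs/nfft) and
#'   `channel_labels`.
#' @export
welch_psd <- function(es, nfft = dim(es$epochs)[3]) {
  stopifnot(inherits(es, "epoch_set"))
  kept <- which(es$kept_mask)
  if (length(kept) == 0L) stop("no kept epochs", call. = FALSE)
  L <- dim(es$epochs)[3]
  if (nfft < L) stop("nfft must be >= epoch sample count", call. = FALSE)
  n_ch <- dim(es$epochs)[2]
  w <- signal::hamming(L)
  U <- sum(w^2)                       # window power normalization
  n_freq <- floor(nfft / 2) + 1L
  acc <- matrix(0, n_ch, n_freq)
  for (e in kept) {
    x <- matrix(es$epochs[e, , ], nrow = n_ch)
    x <- x - rowMeans(x)              # per-epoch detrend (constant)
    xw <- sweep(x, 2L, w, "*")
    if (nfft > L) xw <- cbind(xw, matrix(0, n_ch, nfft - L))
    X <- t(apply(xw, 1L, stats::fft))
    P <- (Mod(X[, seq_len(n_freq), drop = FALSE])^2) / (es$fs * U)
    # one-sided: double everything except DC (and Nyquist when nfft even)
    dbl <- rep(2, n_freq)
    dbl[1] <- 1
    if (nfft %% 2 == 0) dbl[n_freq] <- 1
    acc <- acc + sweep(P, 2L, dbl, "*")
  }
  psd <- acc / length(kept)
  rownames(psd) <- es$channel_labels
  structure(
    list(freqs = (seq_len(n_freq) - 1) * es$fs / nfft, psd = psd,
         nfft = nfft, resolution = es$fs / nfft,
         channel_labels = es$channel_labels),
    class = "psd_result"
  )
}

#' @export
print.psd_result <- function(x, ...) {
  cat(sprintf("<psd_result> %d ch, %g-%g Hz @ %g Hz resolution\n",
              nrow(x$psd), min(x$freqs), max(x$freqs), x$resolution))
  invisible(x)
}

#' Integrate a PSD over a frequency band
#'
#' Trapezoidal integral of the PSD over `[low, high]` per channel. Band
#' edges are handled half-open on the upper side at the bin level via the
#' canonical band grid; for the integral itself the trapezoid over the
#' in-band frequency bins is used.
#'
#' @param psd A `psd_result`.
#' @param band One-row band data.frame (see [eeg_bands()]).
#' @return Named numeric vector of band powers (uV^2), one per channel.
#' @export
band_power <- function(psd, band) {
  stopifnot(inherits(psd, "psd_result"))
  if (band$low < min(psd$freqs) || band$high > max(psd$freqs)) {
    stop("band ", band$band, " outside the PSD frequency grid", call. = FALSE)
  }
  idx <- which(psd$freqs >= band$low & psd$freqs <= band$high)
  if (length(idx) < 2L) stop("band narrower than frequency resolution",
                             call. = FALSE)
  f <- psd$freqs[idx]
  apply(psd$psd[, idx, drop = FALSE], 1L, function(p) pracma::trapz(f, p))
}

#' Band-power table for one recording condition
#'
#' @param psd A `psd_result`.
#' @param bands Band data.frame, default [eeg_bands()].
#' @param subject,condition Optional tags stored as attributes.
#' @return channel x band numeric matrix (uV^2).
#' @export
band_power_table <- function(psd, bands = eeg_bands(), subject = NA,
                             condition = NA) {
  vals <- sapply(seq_len(nrow(bands)), function(i) {
    band_power(psd, bands[i, , drop = FALSE])
  })
  colnames(vals) <- bands$band
  structure(vals, subject = subject, condition = condition)
}

#' Post-minus-pre band-power change
#'
#' The task-induced spectral modulation index: elementwise `post - pre`
#' over the common channel x band grid.
#'
#' @param pre,post channel x band matrices from [band_power_table()] with
#'   identical dimnames.
#' @return Matrix of deltas, same shape.
#' @export
delta_psd <- function(pre, post) {
  if (!identical(dimnames(pre), dimnames(post))) {
    stop("pre/post montage or band mismatch", call. = FALSE)
  }
  unclass(post) - unclass(pre)
}

#' Channel-wise paired pre/post tests on band power
#'
#' For one band: per channel, a paired test of post vs pre across subjects,
#' dispatched by a Shapiro-Wilk normality check on the paired differences
#' (paired t when normal, Wilcoxon signed-rank otherwise), with
#' Benjamini-Hochberg adjustment across the channels of the band.
#'
#' @param pre_list,post_list Lists (one element per subject) of channel x
#'   band matrices from [band_power_table()].
#' @param band Band name (column present in the tables).
#' @return A data.frame: channel, test, statistic, p, p_fdr, effect,
#'   effect_convention. Degenerate channels (all-zero differences) are
#'   flagged with `test = "degenerate"` and NA statistics.
#' @export
channelwise_prepost_tests <- function(pre_list, post_list, band) {
  n <- length(pre_list)
  if (n < 3L || length(post_list) != n) {
    stop("need matched pre/post tables for at least 3 subjects", call. = FALSE)
  }
  channels <- rownames(pre_list[[1]])
  pre_m <- sapply(pre_list, function(m) m[, band])   # channel x subject
  post_m <- sapply(post_list, function(m) m[, band])
  rows <- lapply(seq_along(channels), function(i) {
    res <- tryCatch(paired_tests(pre_m[i, ], post_m[i, ]),
                    error = function(e) NULL)
    if (is.null(res)) {
      return(data.frame(channel = channels[i], test = "degenerate",
                        statistic = NA_real_, p = NA_real_,
                        effect = NA_real_, effect_convention = NA_character_,
                        stringsAsFactors = FALSE))
    }
    data.frame(channel = channels[i], test = res$test,
               statistic = res$statistic, p = res$p, effect = res$effect,
               effect_convention = res$effect_convention,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  ok <- !is.na(out$p)
  out$p_fdr[ok] <- bh_fdr(out$p[ok])
  out[, c("channel", "test", "statistic", "p", "p_fdr", "effect",
          "effect_convention")]
}

#' Scalar task-modulation summary for correlation analyses
#'
#' Collapses a subject's channel x band delta matrix to one number: the
#' mean delta over a declared channel/band selection. Which channels and
#' bands enter is a configuration choice (typically those that reached
#' within-group significance); the selection used is recorded in the
#' attributes of the result.
#'
#' @param delta channel x band delta matrix from [delta_psd()].
#' @param channels,bands Selection; defaults to all.
#' @return Single number with attributes `channels` and `bands`.
#' @export
delta_psd_scalar <- function(delta, channels = rownames(delta),
                             bands = colnames(delta)) {
  sel <- delta[channels, bands, drop = FALSE]
  structure(mean(sel), channels = channels, bands = bands)
}
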