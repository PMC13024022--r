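# Minimal European Data Format (EDF) writer/reader for interchange of
# simulated recordings: ASCII header, 16-bit little-endian samples in
# 1-second data records. Covers continuous uniform-rate signals only (no
# annotations, no EDF+ discontinuities).

fixed_field <- function(x, width) {
  s <- substr(format(x, scientific = FALSE, trim = TRUE), 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16 bits over each channel's physical range;
#' the duration is truncated to whole seconds (EDF data records are 1 s).
#'
#' @param rec An `eeg_recording`.
#' @param path Output file path.
#' @param patient,recording_id Header free-text fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, patient = "X", recording_id = "X") {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer needs integer fs",
                                       call. = FALSE)
  n_rec <- floor(ncol(rec$data) / fs)
  if (n_rec < 1) stop("recording shorter than one EDF record (1 s)",
                      call. = FALSE)
  ns <- nrow(rec$data)
  data <- rec$data[, seq_len(n_rec * fs), drop = FALSE]
  pmin_ <- apply(data, 1L, min)
  pmax_ <- apply(data, 1L, max)
  flat <- pmax_ - pmin_ < 1e-9
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  # pad so the 2-decimal header range never clips the extremes
  pmin_ <- pmin_ - 0.01
  pmax_ <- pmax_ + 0.01
  dmin <- -32768L
  dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    fixed_field("0", 8),
    fixed_field(patient, 80),
    fixed_field(recording_id, 80),
    fixed_field("01.01.00", 8),
    fixed_field("00.00.00", 8),
    fixed_field(256 + 256 * ns, 8),
    fixed_field("", 44),
    fixed_field(n_rec, 8),
    fixed_field(1, 8),
    fixed_field(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  per_sig <- function(vals, width) {
    writeChar(paste(vapply(vals, fixed_field, "", width = width),
                    collapse = ""), con, eos = NULL)
  }
  per_sig(rec$channel_labels, 16)
  per_sig(rep("", ns), 80)
  per_sig(rep("uV", ns), 8)
  per_sig(sprintf("%.2f", pmin_), 8)
  per_sig(sprintf("%.2f", pmax_), 8)
  per_sig(rep(dmin, ns), 8)
  per_sig(rep(dmax, ns), 8)
  per_sig(rep("", ns), 80)
  per_sig(rep(fs, ns), 8)
  per_sig(rep("", ns), 32)

  # re-read the header's printed physical range so scaling round-trips
  pmin_h <- as.numeric(sprintf("%.2f", pmin_))
  pmax_h <- as.numeric(sprintf("%.2f", pmax_))
  gain <- (pmax_h - pmin_h) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      seg <- data[ch, ((r - 1) * fs + 1):(r * fs)]
      dig <- as.integer(round((seg - pmin_h[ch]) / gain[ch]) + dmin)
      writeBin(pmin(pmax(dig, dmin), dmax), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return An `eeg_recording` (physical units restored from the header
#'   scaling; values match the written signal to 16-bit quantization).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                       # version
  rd(80); rd(80); rd(8); rd(8)
  rd(8)                       # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  sig_field <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- sig_field(16)
  sig_field(80)               # transducer
  sig_field(8)                # dimension
  pmin_ <- as.numeric(sig_field(8))
  pmax_ <- as.numeric(sig_field(8))
  dmin <- as.numeric(sig_field(8))
  dmax <- as.numeric(sig_field(8))
  sig_field(80)               # prefilter
  spr <- as.integer(sig_field(8))
  sig_field(32)
  if (length(unique(spr)) != 1L) {
    stop("mixed per-signal sampling rates are not supported", call. = FALSE)
  }
  fs <- spr[1] / rec_dur
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[ch], size = 2, signed = TRUE,
                     endian = "little")
      data[ch, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
        (dig - dmin[ch]) * gain[ch] + pmin_[ch]
    }
  }
  recording(data, fs, labels)
}

#' Write a cohort to disk as EDF files plus CSV tables
#'
#' One EDF per subject and condition, a `manifest.csv` (subject, group,
#' condition, file), `behavioral.csv` and `body_composition.csv`.
#'
#' @param cohort A cohort bundle from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param duration Optional recording-length override in seconds.
#' @return The manifest data.frame, invisibly.
#' @export
write_cohort_edf <- function(cohort, dir, duration = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_len(nrow(cohort$subjects))) {
    id <- cohort$subjects$subject[i]
    for (cond in c("pre", "post")) {
      rec <- if (is.null(duration)) {
        cohort$recording(id, cond)
      } else {
        simulate_subject_pair(cohort$truth, id, duration = duration)[[cond]]
      }
      f <- file.path(dir, sprintf("%s_%s.edf", id, cond))
      write_edf(rec, f, patient = id, recording_id = cond)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = id, group = cohort$subjects$group[i], condition = cond,
        file = basename(f), stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$behavioral, file.path(dir, "behavioral.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$body, file.path(dir, "body_composition.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
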