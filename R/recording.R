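#' Construct a multichannel EEG recording
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector, one label per row of `data`.
#' @param reference_state `"physical-ref"` (as acquired, relative to a
#'   physical reference electrode) or `"average"` (common average).
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(data, fs, channel_labels,
                      reference_state = c("physical-ref", "average")) {
  reference_state <- match.arg(reference_state)
  data <- as.matrix(data)
  if (!is.numeric(data) || any(!is.finite(data))) {
    stop("recording data must be a finite numeric matrix", call. = FALSE)
  }
  if (length(channel_labels) != nrow(data)) {
    stop("channel_labels length (", length(channel_labels),
         ") must equal the number of data rows (", nrow(data), ")",
         call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a single positive number", call. = FALSE)
  }
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = as.character(channel_labels),
         reference_state = reference_state),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz (%.1f s), ref: %s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              x$reference_state))
  invisible(x)
}

#' Remove channels from a recording
#'
#' Typical first preprocessing step: dropping reference-adjacent electrodes
#' (e.g. the bilateral mastoids A1/A2) before any filtering. The order of
#' the remaining channels is preserved.
#'
#' @param rec An `eeg_recording`.
#' @param labels Character vector of channel labels to remove; must all be
#'   present in the recording. An empty set returns the recording unchanged.
#' @return The recording without the named channels.
#' @export
drop_channels <- function(rec, labels) {
  stopifnot(inherits(rec, "eeg_recording"))
  labels <- as.character(labels)
  if (length(labels) == 0L) {
    return(rec)
  }
  unknown <- setdiff(labels, rec$channel_labels)
  if (length(unknown)) {
    stop("unknown channel label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  keep <- !(rec$channel_labels %in% labels)
  recording(rec$data[keep, , drop = FALSE], rec$fs,
            rec$channel_labels[keep], rec$reference_state)
}
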