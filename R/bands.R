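#' Canonical EEG frequency bands
#'
#' The five-band partition used throughout the pipeline: delta 0.5--4 Hz,
#' theta 4--8 Hz, alpha 8--12 Hz, beta 12--30 Hz, gamma 30--45 Hz. Band
#' intervals are treated as half-open `[low, high)` except the top band,
#' which is closed at 45 Hz, so shared edges are never double counted.
#'
#' @param name Optional band name; if given, returns that single band.
#' @return A data.frame with columns `band`, `low`, `high` (Hz), or a
#'   one-row data.frame when `name` is given.
#' @examples
#' eeg_bands()
#' eeg_bands("alpha")
#' @export
eeg_bands <- function(name = NULL) {
  bands <- data.frame(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    low  = c(0.5, 4, 8, 12, 30),
    high = c(4, 8, 12, 30, 45),
    stringsAsFactors = FALSE
  )
  if (is.null(name)) {
    return(bands)
  }
  name <- tolower(name)
  hit <- bands[bands$band == name, , drop = FALSE]
  if (nrow(hit) == 0L) {
    stop("unknown band: ", name, call. = FALSE)
  }
  hit
}

#' Define a frequency band
#'
#' @param name Band label.
#' @param low,high Band limits in Hz, `low < high`.
#' @return A one-row data.frame usable wherever a canonical band is.
#' @export
band_definition <- function(name, low, high) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(is.finite(low) && is.finite(high) && low < high)) {
    stop("band limits must be finite with low < high", call. = FALSE)
  }
  data.frame(band = name, low = low, high = high, stringsAsFactors = FALSE)
}
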