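#' Default 30-channel montage with a 16-region partition
#'
#' Thirty scalp electrodes of the International 10--20 system (the 32-channel
#' layout of a wireless research cap minus the bilateral mastoids A1/A2),
#' partitioned into 16 scalp regions: left/right prefrontal (`L-PreF`,
#' `R-PreF`), left/midline/right frontal (`L-F`, `M-F`, `R-F`), central
#' (`L-C`, `M-C`, `R-C`), parietal (`L-P`, `M-P`, `R-P`), left/right temporal
#' (`L-T`, `R-T`) and left/midline/right occipital (`L-O`, `M-O`, `R-O`).
#'
#' The partition is an informed reconstruction built from the 10--20
#' geometry (anterior-posterior row and laterality of each electrode); it is
#' not copied from any published appendix. Notably `PO4` is assigned to the
#' right occipital region `R-O` together with `O2`. Override `region_map`
#' to use a different partition.
#'
#' @param region_map Optional named character vector (channel -> region)
#'   replacing the default partition. Must cover 30 unique channels and
#'   leave no region empty.
#' @return An object of class `montage`: a list with `channel_labels`
#'   (ordered, length 30), `region_labels` (ordered, length 16) and
#'   `region_map` (named character vector channel -> region).
#' @examples
#' m <- default_montage()
#' length(m$channel_labels)   # 30
#' length(m$region_labels)    # 16
#' m$region_map[["PO4"]]      # "R-O"
#' @export
default_montage <- function(region_map = NULL) {
  channels <- c(
    "FP1", "FP2",
    "F7", "F3", "FZ", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6",
    "T3", "C3", "CZ", "C4", "T4",
    "CP5", "CP1", "CP2", "CP6",
    "T5", "P3", "PZ", "P4", "T6",
    "PO3", "O1", "OZ", "O2", "PO4"
  )
  regions <- c(
    "L-PreF", "R-PreF",
    "L-F", "M-F", "R-F",
    "L-C", "M-C", "R-C",
    "L-P", "M-P", "R-P",
    "L-T", "R-T",
    "L-O", "M-O", "R-O"
  )
  if (is.null(region_map)) {
    region_map <- c(
      FP1 = "L-PreF", FP2 = "R-PreF",
      F7 = "L-F", F3 = "L-F", FC5 = "L-F",
      FZ = "M-F", FC1 = "M-F", FC2 = "M-F",
      F4 = "R-F", F8 = "R-F", FC6 = "R-F",
      C3 = "L-C",
      CZ = "M-C", CP1 = "M-C", CP2 = "M-C",
      C4 = "R-C",
      CP5 = "L-P", P3 = "L-P",
      PZ = "M-P",
      CP6 = "R-P", P4 = "R-P",
      T3 = "L-T", T5 = "L-T",
      T4 = "R-T", T6 = "R-T",
      PO3 = "L-O", O1 = "L-O",
      OZ = "M-O",
      PO4 = "R-O", O2 = "R-O"
    )
  }
  validate_montage(structure(
    list(
      channel_labels = channels,
      region_labels = regions,
      region_map = region_map[channels]
    ),
    class = "montage"
  ))
}

validate_montage <- function(m) {
  stopifnot(inherits(m, "montage"))
  ch <- m$channel_labels
  if (anyDuplicated(ch)) stop("duplicate channel labels in montage", call. = FALSE)
  if (any(is.na(m$region_map))) {
    stop("every channel must map to exactly one region", call. = FALSE)
  }
  if (!all(m$region_map %in% m$region_labels)) {
    stop("region_map uses labels outside the declared region set", call. = FALSE)
  }
  empty <- setdiff(m$region_labels, unique(m$region_map))
  if (length(empty)) {
    stop("empty region(s): ", paste(empty, collapse = ", "), call. = FALSE)
  }
  m
}

#' @export
print.montage <- function(x, ...) {
  cat("<montage> ", length(x$channel_labels), " channels, ",
      length(x$region_labels), " regions\n", sep = "")
  tab <- split(names(x$region_map), x$region_map)[x$region_labels]
  for (r in x$region_labels) {
    cat(sprintf("  %-6s %s\n", r, paste(tab[[r]], collapse = " ")))
  }
  invisible(x)
}
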