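# Recording container: channels x samples in microvolts, with extended
# 10-20 channel labels, sampling rate and event annotations.

#' Construct an EEG recording
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param channels character vector of unique extended 10-20 labels,
#'   one per row of `data`.
#' @param fs sampling rate in Hz.
#' @param annotations `data.frame` with columns `label` (character) and
#'   `sample` (1-based sample index), or `NULL`.
#' @param subject optional subject identifier carried through the pipeline.
#' @param meta optional named list of extra metadata.
#' @return a `recording` object.
#' @export
recording <- function(data, channels, fs, annotations = NULL, subject = NA_character_,
                      meta = list()) {
  data <- as.matrix(data)
  channels <- as.character(channels)
  if (nrow(data) != length(channels)) stop("one label per data row required")
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  if (is.null(annotations)) {
    annotations <- data.frame(label = character(), sample = integer())
  }
  annotations <- as.data.frame(annotations)[, c("label", "sample")]
  if (nrow(annotations) &&
      (any(annotations$sample < 1) || any(annotations$sample > ncol(data)))) {
    stop("annotation sample indices out of bounds")
  }
  rownames(data) <- channels
  structure(list(data = data, channels = channels, fs = fs,
                 annotations = annotations, subject = subject, meta = meta),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (!is.na(x$subject)) cat("  subject:", x$subject, "\n")
  cat("  channels:", paste(utils::head(x$channels, 8), collapse = ", "),
      if (length(x$channels) > 8) "..." else "", "\n")
  cat("  annotations:", nrow(x$annotations), "\n")
  invisible(x)
}

#' @export
dim.recording <- function(x) dim(x$data)

n_samples <- function(rec) ncol(rec$data)
n_channels <- function(rec) nrow(rec$data)

# replace data matrix, preserving labels/annotations
set_data <- function(rec, data) {
  stopifnot(all(dim(data) == dim(rec$data)))
  rec$data <- data
  rownames(rec$data) <- rec$channels
  rec
}

subset_channels <- function(rec, keep) {
  idx <- match(keep, rec$channels)
  if (anyNA(idx)) stop("unknown channels: ", paste(keep[is.na(idx)], collapse = ", "))
  rec$data <- rec$data[idx, , drop = FALSE]
  rec$channels <- rec$channels[idx]
  rec
}

#' Standard 32-channel gel montage labels
#'
#' Extended 10-20 labels for a 32-channel actiCAP-style gel montage, in cap
#' order.
#' @return character vector of length 32.
#' @export
montage_32 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6",
    "T7", "C3", "Cz", "C4", "T8",
    "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
    "P7", "P3", "Pz", "P4", "P8",
    "PO9", "O1", "Oz", "O2", "PO10")
}

#' Peripheral channels removed before analysis
#'
#' The twelve peripheral electrodes most exposed to myoelectric and motion
#' artifact, removed from the 32-channel montage so that 20 scalp channels
#' remain.
#' @return character vector of length 12.
#' @export
peripheral_labels <- function() {
  c("Fp1", "Fp2", "F7", "F8", "T7", "T8",
    "TP9", "TP10", "P7", "P8", "PO9", "PO10")
}

#' Retained 20-channel analysis montage
#' @return character vector of length 20.
#' @export
montage_retained <- function() setdiff(montage_32(), peripheral_labels())
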