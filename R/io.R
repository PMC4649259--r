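# Recording input/output: BrainVision-style header/marker/data triplets
# (ASCII data format, so the triplet is plain text) and a simple delimited
# dialect. Ground truth from the synthetic generator travels as a JSON
# sidecar.

#' Write a recording as a BrainVision-style triplet
#'
#' Writes `<stem>.vhdr`, `<stem>.vmrk` and `<stem>.dat` (vectorized ASCII
#' data, one channel per row). Annotations become stimulus markers.
#'
#' @param rec a [recording()].
#' @param stem output path without extension.
#' @return invisibly, the three file paths.
#' @export
write_brainvision <- function(rec, stem) {
  vhdr <- paste0(stem, ".vhdr"); vmrk <- paste0(stem, ".vmrk")
  dat <- paste0(stem, ".dat")
  base <- basename(stem)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", base, ".dat"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=ASCII",
    "DataOrientation=VECTORIZED",
    paste0("NumberOfChannels=", n_channels(rec)),
    paste0("SamplingInterval=", format(1e6 / rec$fs, scientific = FALSE)),
    "[ASCII Infos]",
    "DecimalSymbol=.",
    "SkipLines=0",
    "SkipColumns=0",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(n_channels(rec)), rec$channels)
  )
  writeLines(hdr, vhdr)
  mk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", base, ".dat"),
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0")
  if (nrow(rec$annotations)) {
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                        seq_len(nrow(rec$annotations)) + 1L,
                        rec$annotations$label, rec$annotations$sample))
  }
  writeLines(mk, vmrk)
  con <- file(dat, "w")
  on.exit(close(con))
  for (i in seq_len(n_channels(rec))) {
    writeLines(paste(format(rec$data[i, ], trim = TRUE, digits = 10),
                     collapse = " "), con)
  }
  invisible(c(vhdr, vmrk, dat))
}

parse_bv_ini <- function(lines) {
  kv <- grep("=", lines, fixed = TRUE, value = TRUE)
  kv <- kv[!startsWith(kv, ";")]
  eq <- regexpr("=", kv, fixed = TRUE)
  stats::setNames(substring(kv, eq + 1), substring(kv, 1, eq - 1))
}

#' Read a BrainVision-style triplet
#'
#' Supports the ASCII data format written by [write_brainvision()]
#' (vectorized or multiplexed orientation).
#'
#' @param vhdr path to the `.vhdr` header.
#' @return a [recording()].
#' @export
read_brainvision <- function(vhdr) {
  lines <- readLines(vhdr, warn = FALSE)
  kv <- parse_bv_ini(lines)
  if (toupper(kv[["DataFormat"]] %||% "ASCII") != "ASCII") {
    stop("only ASCII BrainVision data supported")
  }
  fs <- 1e6 / as.numeric(kv[["SamplingInterval"]])
  nch <- as.integer(kv[["NumberOfChannels"]])
  chans <- vapply(seq_len(nch), function(i) {
    strsplit(kv[[paste0("Ch", i)]], ",", fixed = TRUE)[[1]][1]
  }, character(1))
  dir <- dirname(vhdr)
  dat <- file.path(dir, kv[["DataFile"]])
  rows <- strsplit(trimws(readLines(dat, warn = FALSE)), "[[:space:]]+")
  m <- do.call(rbind, lapply(rows, as.numeric))
  if (toupper(kv[["DataOrientation"]] %||% "VECTORIZED") == "MULTIPLEXED") {
    m <- t(m)
  }
  ann <- data.frame(label = character(), sample = integer())
  vmrk <- file.path(dir, kv[["MarkerFile"]] %||% "")
  if (file.exists(vmrk)) {
    mk <- parse_bv_ini(readLines(vmrk, warn = FALSE))
    mk <- mk[grepl("^Mk", names(mk))]
    parts <- lapply(mk, function(v) strsplit(v, ",", fixed = TRUE)[[1]])
    stim <- Filter(function(p) p[1] == "Stimulus", parts)
    if (length(stim)) {
      ann <- data.frame(label = vapply(stim, `[`, "", 2),
                        sample = as.integer(vapply(stim, `[`, "", 3)))
    }
  }
  recording(m, chans, fs, ann)
}

#' Write a recording in the plain delimited dialect
#'
#' `<stem>.tsv` holds one column per channel plus a leading `sample` column;
#' `<stem>_annotations.tsv` and `<stem>_meta.json` hold markers and metadata.
#'
#' @inheritParams write_brainvision
#' @export
write_recording_delim <- function(rec, stem) {
  df <- data.frame(sample = seq_len(n_samples(rec)), t(rec$data),
                   check.names = FALSE)
  utils::write.table(df, paste0(stem, ".tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(rec$annotations, paste0(stem, "_annotations.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(fs = rec$fs, subject = rec$subject,
                            channels = rec$channels),
                       paste0(stem, "_meta.json"), auto_unbox = TRUE)
  invisible(stem)
}

#' Read a recording written by [write_recording_delim()]
#' @param stem path stem used when writing.
#' @return a [recording()].
#' @export
read_recording_delim <- function(stem) {
  df <- utils::read.delim(paste0(stem, ".tsv"), check.names = FALSE)
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"), simplifyVector = TRUE)
  ann_path <- paste0(stem, "_annotations.tsv")
  ann <- if (file.exists(ann_path)) utils::read.delim(ann_path) else NULL
  if (!is.null(ann) && !nrow(ann)) ann <- NULL
  recording(t(as.matrix(df[, -1, drop = FALSE])), meta$channels, meta$fs,
            ann, subject = meta$subject %||% NA_character_)
}

# Ground-truth sidecar -------------------------------------------------

write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth_to_json(truth), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

truth_to_json <- function(truth) {
  truth$blocks <- lapply(truth$blocks, function(b) {
    b$A <- lapply(seq_len(dim(b$A)[3]), function(k) unclass(b$A[, , k]))
    b
  })
  truth
}
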