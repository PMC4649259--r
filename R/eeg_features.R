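# Band-limited EEG features per channel and 1-s segment, in three domains:
# time (amplitude statistics on band-filtered signals), frequency
# (multitaper power spectral density) and wavelet (Morlet scalogram).

#' Study frequency bands
#'
#' delta 1-4, theta 4-7.5, alpha 8-12, beta 15-25, gamma 30-50 Hz.
#' @return `data.frame` with `name`, `low`, `high`.
#' @export
band_definitions <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             low = c(1, 4, 8, 15, 30),
             high = c(4, 7.5, 12, 25, 50))
}

# --- discrete prolate spheroidal sequences (Slepian tapers) -----------
# Tridiagonal formulation; cached per (N, NW, k). Used by the multitaper
# PSD; no installed package provides DPSS.
.dpss_cache <- new.env(parent = emptyenv())

dpss_tapers <- function(n, nw = 2, k = 3) {
  key <- paste(n, nw, k, sep = "_")
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  w <- nw / n
  t <- 0:(n - 1)
  M <- matrix(0, n, n)
  diag(M) <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  M[cbind(1:(n - 1), 2:n)] <- off
  M[cbind(2:n, 1:(n - 1))] <- off
  ev <- eigen(M, symmetric = TRUE)
  tap <- ev$vectors[, seq_len(k), drop = FALSE]
  # normalize and fix sign (positive mean for symmetric tapers)
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    if (sum(tap[, j]) < 0) tap[, j] <- -tap[, j]
  }
  .dpss_cache[[key]] <- tap
  tap
}

#' Multitaper power spectral density
#'
#' DPSS (Slepian) tapered periodograms averaged over tapers, evaluated on
#' an integer frequency grid.
#'
#' @param x numeric signal (one channel, one segment).
#' @param fs sampling rate Hz.
#' @param freqs frequency grid in Hz (defaults to 1..50).
#' @param nw time-bandwidth product.
#' @param k number of tapers.
#' @return named numeric vector of PSD values (muV^2/Hz) at `freqs`.
#' @export
multitaper_psd <- function(x, fs, freqs = 1:50, nw = 2, k = 3) {
  n <- length(x)
  if (max(freqs) > fs / 2) stop("frequency grid beyond Nyquist")
  tap <- dpss_tapers(n, nw, k)
  x <- x - mean(x)
  df <- fs / n
  idx <- round(freqs / df) + 1L
  if (any(idx > n)) stop("frequency grid beyond FFT resolution")
  p <- 0
  for (j in seq_len(ncol(tap))) {
    sp <- Mod(stats::fft(x * tap[, j]))^2 / fs
    p <- p + sp[idx]
  }
  stats::setNames(2 * p / ncol(tap), freqs)  # one-sided
}

#' Morlet wavelet scalogram
#'
#' Complex Morlet convolution per frequency row. The number of cycles grows
#' with frequency (capped) so that low rows fit a 1-s segment while every
#' band keeps at least 3 rows on the integer grid.
#'
#' @param x numeric signal.
#' @param fs sampling rate Hz.
#' @param freqs frequency rows in Hz.
#' @return matrix `length(freqs) x length(x)` of complex coefficients.
#' @export
morlet_scalogram <- function(x, fs, freqs = 1:50) {
  n <- length(x)
  out <- matrix(0 + 0i, length(freqs), n)
  xz <- x - mean(x)
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    ncyc <- min(7, max(1.5, f / 4))
    sd_t <- ncyc / (2 * pi * f)
    half <- min(n - 1, ceiling(3.5 * sd_t * fs))
    t <- (-half:half) / fs
    env <- exp(-t^2 / (2 * sd_t^2))
    kern <- env * exp(2i * pi * f * t)
    kern <- kern / (sum(env) / 2)   # unit-amplitude sinusoid -> |W| ~ 1
    m <- length(kern)
    nfft <- stats::nextn(n + m - 1, 2)
    X <- stats::fft(c(xz, rep(0, nfft - n)))
    K <- stats::fft(c(kern, rep(0 + 0i, nfft - m)))
    full <- stats::fft(X * K, inverse = TRUE) / nfft
    out[i, ] <- full[(half + 1):(half + n)]
  }
  rownames(out) <- freqs
  out
}

band_rows <- function(freqs, low, high) which(freqs >= low & freqs <= high)

#' Time-domain features of one 1-s segment
#'
#' Kurtosis, standard deviation, maximum absolute amplitude and Shannon
#' entropy (32-bin amplitude histogram), computed on the unfiltered segment
#' and on each of the five band-filtered versions: 4 x 6 = 24 values.
#'
#' @param x numeric segment (length = fs).
#' @param fs sampling rate Hz.
#' @param bands band table as from [band_definitions()].
#' @return named numeric vector of 24 values; attribute `degenerate` flags
#'   constant inputs (kurtosis reported as 0).
#' @export
time_domain_features <- function(x, fs, bands = band_definitions()) {
  out <- numeric(0); degen <- FALSE
  variants <- c("broadband", bands$name)
  for (b in variants) {
    v <- if (b == "broadband") x else {
      row <- bands[bands$name == b, ]
      sos_filtfilt(band_filter(row$low, row$high, fs), x)
    }
    s <- amp_stats(v)
    degen <- degen || isTRUE(attr(s, "degenerate"))
    out <- c(out, stats::setNames(as.numeric(s),
                                  paste(b, c("kurtosis", "sd", "max",
                                             "entropy"), sep = ".")))
  }
  structure(out, degenerate = degen)
}

# the four amplitude statistics shared by the time-domain paths;
# constant input: entropy 0, kurtosis undefined -> 0 with a flag
amp_stats <- function(v) {
  sdv <- stats::sd(v)
  if (sdv == 0) {
    return(structure(c(0, 0, max(abs(v)), 0), degenerate = TRUE))
  }
  h <- graphics::hist(v, breaks = 32, plot = FALSE)$counts
  c(e1071::kurtosis(v), sdv, max(abs(v)), shannon_entropy(h))
}

#' Frequency-domain features of one 1-s segment
#'
#' Multitaper PSD on the 1-50 Hz grid; per band: total power (in-band PSD
#' integral), standard deviation of in-band PSD values, and Shannon entropy
#' of the in-band PSD normalized to a probability vector: 3 x 5 = 15.
#'
#' @inheritParams time_domain_features
#' @param freqs PSD evaluation grid in Hz.
#' @return named numeric vector of 15 values.
#' @export
frequency_domain_features <- function(x, fs, bands = band_definitions(),
                                      freqs = 1:50) {
  psd <- multitaper_psd(x, fs, freqs = freqs)
  out <- numeric(0)
  for (i in seq_len(nrow(bands))) {
    rows <- band_rows(freqs, bands$low[i], bands$high[i])
    if (!length(rows)) stop("band outside frequency grid: ", bands$name[i])
    p <- psd[rows]
    vals <- c(power = sum(p) * diff(freqs)[1], sd = stats::sd(p),
              entropy = shannon_entropy(p))
    out <- c(out, stats::setNames(as.numeric(vals),
                                  paste(bands$name[i], names(vals), sep = ".")))
  }
  out
}

#' Wavelet-domain features of one 1-s segment
#'
#' Morlet scalogram over 1-50 Hz; per band the same three statistics
#' computed on squared coefficient magnitudes: power (mean), SD, and
#' Shannon entropy of the per-row mean power normalized to probabilities.
#'
#' @inheritParams frequency_domain_features
#' @return named numeric vector of 15 values.
#' @export
wavelet_domain_features <- function(x, fs, bands = band_definitions(),
                                    freqs = 1:50) {
  sc <- Mod(morlet_scalogram(x, fs, freqs))^2
  out <- numeric(0)
  for (i in seq_len(nrow(bands))) {
    rows <- band_rows(freqs, bands$low[i], bands$high[i])
    if (!length(rows)) stop("band outside frequency grid: ", bands$name[i])
    blk <- sc[rows, , drop = FALSE]
    vals <- c(power = mean(blk), sd = stats::sd(as.vector(blk)),
              entropy = shannon_entropy(rowMeans(blk)))
    out <- c(out, stats::setNames(as.numeric(vals),
                                  paste(bands$name[i], names(vals), sep = ".")))
  }
  out
}

#' Build a feature table from segmented epochs
#'
#' One row per 1-s segment; columns are per-channel features of the chosen
#' domain (24/channel time, 15/channel frequency or wavelet). The 20-channel
#' retained montage therefore yields 480 time-domain columns. Column
#' metadata (domain, channel, band, statistic) is attached as the
#' `feature_info` attribute.
#'
#' @param epochs an `epoch_set` (from [segment_epochs()]) or a list of them
#'   (multiple subjects).
#' @param domain `"time"`, `"frequency"` or `"wavelet"`.
#' @param classes optional class labels per piece: a
#'   [cluster_images()] result or named character vector; baseline epochs
#'   are always labeled `"baseline"`.
#' @param bands band table.
#' @return a `feature_table`: `data.frame` with id columns `subject`,
#'   `piece`, `segment`, `class` followed by feature columns.
#' @export
build_feature_table <- function(epochs, domain = c("time", "frequency",
                                                   "wavelet"),
                                classes = NULL, bands = band_definitions()) {
  domain <- match.arg(domain)
  if (inherits(epochs, "epoch_set")) epochs <- list(epochs)
  fun <- switch(domain, time = time_domain_features,
                frequency = frequency_domain_features,
                wavelet = wavelet_domain_features)
  class_of <- function(piece) {
    if (piece == "baseline") return("baseline")
    if (is.null(classes)) return(NA_character_)
    lab <- if (inherits(classes, "complexity_classes")) classes$labels else classes
    key <- sub("^piece_", "", piece)
    out <- lab[match(piece, names(lab))]
    if (is.na(out)) out <- lab[match(key, names(lab))]
    unname(out)
  }
  rows <- list()
  for (es in epochs) {
    for (ep in es$epochs) {
      nseg <- length(ep$segments)
      slen <- ncol(ep$segments[[1]])
      if (domain == "time") {
        # band-filter once per epoch channel, then slice segments: avoids
        # per-segment filter transients and repeated filter start-up
        per_seg <- vector("list", nseg)
        for (ci in seq_len(nrow(ep$data))) {
          variants <- c(list(broadband = ep$data[ci, ]),
                        stats::setNames(lapply(seq_len(nrow(bands)), function(b) {
                          sos_filtfilt(band_filter(bands$low[b], bands$high[b],
                                                   es$fs), ep$data[ci, ])
                        }), bands$name))
          for (k in seq_len(nseg)) {
            idx <- ((k - 1) * slen + 1):(k * slen)
            v <- unlist(lapply(names(variants), function(b) {
              stats::setNames(as.numeric(amp_stats(variants[[b]][idx])),
                              paste(b, c("kurtosis", "sd", "max", "entropy"),
                                    sep = "."))
            }))
            per_seg[[k]] <- c(per_seg[[k]],
                              stats::setNames(v, paste(domain, es$channels[ci],
                                                       names(v), sep = ".")))
          }
        }
        for (k in seq_len(nseg)) {
          rows[[length(rows) + 1]] <- c(
            list(subject = es$subject, piece = ep$piece, segment = k,
                 class = class_of(ep$piece)), as.list(per_seg[[k]]))
        }
      } else {
        for (k in seq_len(nseg)) {
          seg <- ep$segments[[k]]
          feats <- unlist(lapply(seq_len(nrow(seg)), function(ci) {
            v <- fun(seg[ci, ], es$fs, bands = bands)
            stats::setNames(as.numeric(v),
                            paste(domain, es$channels[ci], names(v), sep = "."))
          }))
          rows[[length(rows) + 1]] <- c(
            list(subject = es$subject, piece = ep$piece, segment = k,
                 class = class_of(ep$piece)), as.list(feats))
        }
      }
    }
  }
  if (!length(rows)) stop("no segments to featurize")
  df <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, check.names = FALSE)
  }))
  fcols <- setdiff(names(df), c("subject", "piece", "segment", "class"))
  parts <- strsplit(fcols, ".", fixed = TRUE)
  info <- data.frame(name = fcols,
                     domain = vapply(parts, `[`, "", 1),
                     channel = vapply(parts, `[`, "", 2),
                     band = vapply(parts, `[`, "", 3),
                     statistic = vapply(parts, `[`, "", 4))
  per_chan <- if (domain == "time") 24L else 15L
  nch <- length(unique(info$channel))
  if (length(fcols) != per_chan * nch) {
    stop("feature/montage mismatch: expected ", per_chan * nch, " columns")
  }
  structure(df, feature_info = info, domain = domain,
            class = c("feature_table", "data.frame"))
}

#' Column metadata of a feature table
#' @param table a `feature_table`.
#' @return `data.frame` with domain/channel/band/statistic per column.
#' @export
feature_info <- function(table) attr(table, "feature_info")

#' Numeric feature matrix of a feature table
#' @param table a `feature_table`.
#' @return numeric matrix (rows = segments).
#' @export
feature_matrix <- function(table) {
  as.matrix(table[, feature_info(table)$name, drop = FALSE])
}

#' Write a feature table and its metadata sidecar
#' @param table a `feature_table`.
#' @param stem path stem; writes `<stem>.tsv` and `<stem>_features.tsv`.
#' @export
write_feature_table <- function(table, stem) {
  utils::write.table(as.data.frame(table), paste0(stem, ".tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(feature_info(table), paste0(stem, "_features.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(stem)
}
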