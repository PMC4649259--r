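# Butterworth filtering as second-order-section (biquad) cascades.
#
# EEG preprocessing needs high-order Butterworth designs at extreme
# normalized cutoffs (0.1 Hz at 1000 Hz sampling). A single
# transfer-function realization of such a filter is numerically unstable
# in double precision, so designs are kept factored: analog Butterworth
# prototype -> frequency transform -> bilinear transform -> conjugate
# pole/zero pairs grouped into biquads. Each biquad is applied with
# stats::filter (C-level recursion) initialized at its steady-state
# response to the first sample, which removes start-up transients even
# for second-scale time constants.

#' Design a Butterworth filter as second-order sections
#'
#' @param order filter order (poles). For `type = "pass"` the total order is
#'   `2 * order` (order poles per band edge).
#' @param w critical frequency(ies), normalized to Nyquist (0 < w < 1).
#'   Length 2 for `type = "pass"`.
#' @param type `"low"`, `"high"` or `"pass"`.
#' @return a `butter_sos` object: matrix with rows `(b0, b1, b2, 1, a1, a2)`.
#' @examples
#' f <- butter_sos(8, 0.1 / 500, type = "high")  # 0.1 Hz high-pass at 1 kHz
#' @export
butter_sos <- function(order, w, type = c("low", "high", "pass")) {
  type <- match.arg(type)
  stopifnot(order >= 1, all(w > 0), all(w < 1))
  if (type == "pass" && length(w) != 2) stop("band-pass needs two edges")
  k <- seq_len(order)
  p <- complex(modulus = 1, argument = pi * (2 * k - 1) / (2 * order) + pi / 2)
  warp <- function(wd) 4 * tan(pi * wd / 2)  # bilinear constant fs2 = 4
  zs <- complex(0)
  if (type == "low") {
    wc <- warp(w)
    p <- p * wc
    kgain <- wc^order
  } else if (type == "high") {
    wc <- warp(w)
    p <- wc / p
    zs <- rep(0 + 0i, order)
    kgain <- 1
  } else {
    w1 <- warp(w[1]); w2 <- warp(w[2])
    bw <- w2 - w1; w0 <- sqrt(w1 * w2)
    pb <- complex(0)
    for (pp in p) {
      a <- pp * bw / 2
      s <- sqrt(a^2 - w0^2)
      pb <- c(pb, a + s, a - s)
    }
    p <- pb
    zs <- rep(0 + 0i, order)
    kgain <- bw^order
  }
  fs2 <- 4
  pd <- (fs2 + p) / (fs2 - p)
  zd <- c((fs2 + zs) / (fs2 - zs), rep(-1 + 0i, length(p) - length(zs)))
  kd <- kgain * Re(prod(fs2 - zs) / prod(fs2 - p))
  sos <- zpk_to_sos(zd, pd, kd)
  structure(sos, class = "butter_sos", w = w, type = type, order = order)
}

# expand roots into polynomial coefficients (highest degree first)
poly_from_roots <- function(r) {
  p <- 1
  for (x in r) p <- c(p, 0) - c(0, p * x)
  p
}

# Group conjugate pole/zero pairs into biquads, worst-conditioned poles first.
zpk_to_sos <- function(z, p, k) {
  p <- p[order(-Mod(p))]
  used <- rep(FALSE, length(z))
  rows <- list()
  while (length(p)) {
    if (abs(Im(p[1])) > 1e-10) {
      j <- which(abs(p - Conj(p[1])) < 1e-8 & seq_along(p) != 1)[1]
      pp <- c(p[1], p[j]); p <- p[-c(1, j)]
    } else {
      j <- setdiff(which(abs(Im(p)) <= 1e-10), 1)[1]
      if (!is.na(j)) { pp <- c(p[1], p[j]); p <- p[-c(1, j)] }
      else { pp <- p[1]; p <- p[-1] }
    }
    zz <- complex(0)
    for (i in seq_along(pp)) {
      avail <- which(!used)
      if (!length(avail)) break
      j <- avail[which.min(Mod(z[avail] - pp[1]))]
      used[j] <- TRUE
      zz <- c(zz, z[j])
    }
    b <- Re(poly_from_roots(zz)); a <- Re(poly_from_roots(pp))
    rows[[length(rows) + 1]] <- c(b, rep(0, 3 - length(b)), a, rep(0, 3 - length(a)))
  }
  m <- do.call(rbind, rows)
  m[1, 1:3] <- m[1, 1:3] * k
  m
}

# One biquad, steady-state initialized at x0 (removes DC start-up transient).
biquad_apply <- function(b, a, x, x0 = x[1]) {
  g <- sum(b) / sum(a)
  xx <- c(x0, x0, x)
  v <- as.numeric(stats::filter(xx, b, method = "convolution", sides = 1))[-(1:2)]
  as.numeric(stats::filter(v, -a[2:3], method = "recursive", init = c(g * x0, g * x0)))
}

#' Apply a second-order-section filter (single pass)
#'
#' @param sos a [butter_sos()] design.
#' @param x numeric vector.
#' @return filtered vector, same length.
#' @export
sos_filter <- function(sos, x) {
  for (i in seq_len(nrow(sos))) x <- biquad_apply(sos[i, 1:3], sos[i, 4:6], x)
  x
}

#' Zero-phase (forward-backward) second-order-section filtering
#'
#' Applies the cascade forward then time-reversed, squaring the magnitude
#' response and cancelling phase, the convention used for EEG band filters.
#'
#' @inheritParams sos_filter
#' @return filtered vector, same length as `x`.
#' @export
sos_filtfilt <- function(sos, x) {
  rev(sos_filter(sos, rev(sos_filter(sos, x))))
}

#' Magnitude/complex response of an sos cascade
#'
#' @param sos a [butter_sos()] design.
#' @param f frequencies in Hz.
#' @param fs sampling rate in Hz.
#' @param zero_phase if `TRUE`, return the squared-magnitude (forward-backward)
#'   response; otherwise the complex single-pass response.
#' @return complex (single pass) or numeric (zero-phase magnitude) vector.
#' @export
sos_response <- function(sos, f, fs, zero_phase = FALSE) {
  w <- 2 * pi * f / fs
  e <- exp(-1i * outer(w, 0:2))
  h <- rep(1 + 0i, length(w))
  for (i in seq_len(nrow(sos))) {
    h <- h * as.vector(e %*% sos[i, 1:3]) / as.vector(e %*% sos[i, 4:6])
  }
  if (zero_phase) Mod(h)^2 else h
}

# Per-session cache of band-pass designs keyed by (low, high, fs, order).
.filter_cache <- new.env(parent = emptyenv())

band_filter <- function(low, high, fs, order = 4) {
  key <- paste(low, high, fs, order, sep = "_")
  if (is.null(.filter_cache[[key]])) {
    .filter_cache[[key]] <- butter_sos(order, c(low, high) / (fs / 2), type = "pass")
  }
  .filter_cache[[key]]
}
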