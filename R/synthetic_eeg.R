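# Synthetic EEG with known directed ground truth.
#
# Channels are damped second-order (VAR(2)) oscillators; directed coupling
# is realized as off-diagonal lag-1 coefficients. A schedule of coupling
# (onset, offset) windows yields piecewise-constant coefficient regimes, so
# the time-varying connectivity stage can be validated against a known step.

#' Specify a ground-truth VAR connectivity structure
#'
#' @param n_channels number of channels.
#' @param osc_freq per-channel oscillator center frequency in Hz (recycled).
#' @param damping per-channel pole radius in (0, 1); closer to 1 gives a
#'   sharper spectral peak (recycled).
#' @param couplings `data.frame` with columns `source`, `target` (channel
#'   indices), `gain` (lag-1 coefficient), and optionally `onset`, `offset`
#'   in seconds for time-varying regimes (defaults: always on).
#' @param noise_scale innovation standard deviation in microvolts.
#' @param target_sd if set, per-channel innovation scales are calibrated
#'   (via the stationary covariance of each regime) so every channel's
#'   output standard deviation is `target_sd` microvolts; `noise_scale` is
#'   then ignored. Keeps clean EEG within a realistic span regardless of
#'   oscillator sharpness and coupling chains.
#' @param labels optional channel labels (default `Ch1..Chn`).
#' @return a `connectivity_spec` object.
#' @export
connectivity_spec <- function(n_channels, osc_freq = 10, damping = 0.95,
                              couplings = NULL, noise_scale = 5,
                              target_sd = NULL, labels = NULL) {
  stopifnot(n_channels >= 1, all(damping > 0), all(damping < 1),
            noise_scale > 0)
  osc_freq <- rep_len(osc_freq, n_channels)
  damping <- rep_len(damping, n_channels)
  if (is.null(couplings)) {
    couplings <- data.frame(source = integer(), target = integer(),
                            gain = numeric())
  }
  couplings <- as.data.frame(couplings)
  if (nrow(couplings)) {
    if (is.null(couplings$onset)) couplings$onset <- 0
    if (is.null(couplings$offset)) couplings$offset <- Inf
    if (any(couplings$source < 1 | couplings$source > n_channels) ||
        any(couplings$target < 1 | couplings$target > n_channels)) {
      stop("coupling indices out of range")
    }
    if (any(!is.finite(couplings$gain))) stop("coupling gains must be finite")
  } else {
    couplings$onset <- numeric(0); couplings$offset <- numeric(0)
  }
  if (is.null(labels)) labels <- paste0("Ch", seq_len(n_channels))
  structure(list(n_channels = n_channels, osc_freq = osc_freq,
                 damping = damping, couplings = couplings,
                 noise_scale = noise_scale, target_sd = target_sd,
                 labels = labels),
            class = "connectivity_spec")
}

companion_matrix <- function(A) {
  n <- dim(A)[1]; p <- dim(A)[3]
  C <- matrix(0, n * p, n * p)
  for (k in seq_len(p)) C[1:n, ((k - 1) * n + 1):(k * n)] <- A[, , k]
  if (p > 1) C[(n + 1):(n * p), 1:(n * (p - 1))] <- diag(n * (p - 1))
  C
}

# per-channel stationary output SD of a stable VAR with diagonal
# innovation SDs q, by iterating the discrete Lyapunov recursion
stationary_sd <- function(A, q) {
  n <- dim(A)[1]; p <- dim(A)[3]
  C <- companion_matrix(A)
  Q <- matrix(0, n * p, n * p)
  diag(Q)[1:n] <- q^2
  S <- Q
  for (i in 1:1000) {
    S2 <- C %*% S %*% t(C) + Q
    if (max(abs(S2 - S)) < 1e-10 * max(abs(S2), 1e-12)) { S <- S2; break }
    S <- S2
  }
  sqrt(pmax(diag(S)[1:n], 0))
}

# innovation SDs that give every channel the target output SD
calibrate_noise <- function(A, target_sd) {
  n <- dim(A)[1]
  q <- rep(target_sd, n)
  for (i in 1:8) {
    s <- stationary_sd(A, q)
    s[s == 0] <- target_sd
    q <- q * target_sd / s
  }
  q
}

# VAR(2) coefficient array (n x n x 2) for one regime: diagonal damped
# oscillators plus the lag-1 couplings active in the regime.
regime_coefficients <- function(spec, fs, active) {
  n <- spec$n_channels
  A <- array(0, dim = c(n, n, 2))
  for (i in seq_len(n)) {
    r <- spec$damping[i]
    A[i, i, 1] <- 2 * r * cos(2 * pi * spec$osc_freq[i] / fs)
    A[i, i, 2] <- -r^2
  }
  if (nrow(active)) {
    for (j in seq_len(nrow(active))) {
      A[active$target[j], active$source[j], 1] <-
        A[active$target[j], active$source[j], 1] + active$gain[j]
    }
  }
  A
}

# Spectral radius of the VAR companion matrix.
companion_radius <- function(A) {
  n <- dim(A)[1]; p <- dim(A)[3]
  C <- matrix(0, n * p, n * p)
  for (k in seq_len(p)) C[1:n, ((k - 1) * n + 1):(k * n)] <- A[, , k]
  if (p > 1) C[(n + 1):(n * p), 1:(n * (p - 1))] <- diag(n * (p - 1))
  max(Mod(eigen(C, only.values = TRUE)$values))
}

# Split [0, duration] into regimes at coupling onset/offset boundaries.
coupling_blocks <- function(spec, duration) {
  cp <- spec$couplings
  brk <- sort(unique(c(0, duration,
                       pmin(pmax(cp$onset, 0), duration),
                       pmin(cp$offset[is.finite(cp$offset)], duration))))
  brk <- brk[brk <= duration]
  lapply(seq_len(length(brk) - 1), function(b) {
    t0 <- brk[b]; t1 <- brk[b + 1]
    mid <- (t0 + t1) / 2
    act <- cp[cp$onset <= mid & cp$offset > mid, , drop = FALSE]
    list(t0 = t0, t1 = t1, active = act)
  })
}

#' Simulate a VAR(2) EEG recording with ground truth
#'
#' @param spec a [connectivity_spec()].
#' @param duration seconds.
#' @param fs sampling rate in Hz; must exceed twice the largest oscillator
#'   frequency.
#' @param seed integer; output is byte-identical for identical seeds.
#' @return list with elements `recording` (a [recording()]) and `truth`
#'   (regime blocks with coefficient arrays and coupling matrices).
#' @export
simulate_mvar_eeg <- function(spec, duration, fs, seed = 1) {
  stopifnot(inherits(spec, "connectivity_spec"), duration > 0)
  if (fs <= 2 * max(spec$osc_freq)) {
    stop("fs must exceed twice the largest oscillator frequency")
  }
  blocks <- coupling_blocks(spec, duration)
  for (b in blocks) {
    A <- regime_coefficients(spec, fs, b$active)
    rho <- companion_radius(A)
    if (rho >= 1) {
      stop(sprintf(paste0("unstable VAR regime on [%g, %g) s: spectral ",
                          "radius %.4f >= 1; reduce gains or damping"),
                   b$t0, b$t1, rho))
    }
  }
  n <- spec$n_channels
  total <- round(duration * fs)
  x <- matrix(0, n, total + 2)
  truth_blocks <- vector("list", length(blocks))
  with_seed(seed, {
    noise <- matrix(stats::rnorm(n * total), n, total)
    for (b in seq_along(blocks)) {
      blk <- blocks[[b]]
      A <- regime_coefficients(spec, fs, blk$active)
      q <- if (is.null(spec$target_sd)) rep(spec$noise_scale, n)
           else calibrate_noise(A, spec$target_sd)
      i0 <- round(blk$t0 * fs) + 1L
      i1 <- round(blk$t1 * fs)
      noise[, i0:i1] <- noise[, i0:i1, drop = FALSE] * q
      for (t in i0:i1) {
        tt <- t + 2L
        x[, tt] <- A[, , 1] %*% x[, tt - 1L] + A[, , 2] %*% x[, tt - 2L] +
          noise[, t]
      }
      cm <- matrix(0, n, n)
      if (nrow(blk$active)) {
        cm[cbind(blk$active$target, blk$active$source)] <- blk$active$gain
      }
      truth_blocks[[b]] <- list(t0 = blk$t0, t1 = blk$t1, A = A,
                                coupling = cm)
    }
  })
  rec <- recording(x[, -(1:2), drop = FALSE], spec$labels, fs)
  list(recording = rec,
       truth = list(fs = fs, blocks = truth_blocks, artifacts = NULL))
}

# Artifact injection ---------------------------------------------------

#' One artifact event for [inject_artifacts()]
#'
#' @param type `"blink"`, `"drift"`, `"pop"` or `"dead"`.
#' @param onset,duration seconds.
#' @param amplitude microvolts (peak for blink/pop, peak-to-peak for drift).
#' @param channels labels affected; `NULL` picks a type-appropriate default
#'   (frontal rows for blinks, one channel otherwise).
#' @export
artifact_event <- function(type = c("blink", "drift", "pop", "dead"),
                           onset = 0, duration = 0.4, amplitude = 200,
                           channels = NULL) {
  type <- match.arg(type)
  list(type = type, onset = onset, duration = duration,
       amplitude = amplitude, channels = channels)
}

#' Inject stereotyped artifacts into a recording
#'
#' Adds blink-like frontal transients (raised-cosine bumps), slow sinusoidal
#' drift, high-amplitude square pops, and optionally replaces one channel
#' with decorrelated noise ("dead" channel). Overlapping events of the same
#' type and channel are merged with a warning.
#'
#' @param rec a [recording()].
#' @param plan list of [artifact_event()]s.
#' @param seed integer for the stochastic components.
#' @return list with `recording` (modified) and `intervals` (`data.frame`
#'   of ground-truth artifact spans).
#' @export
inject_artifacts <- function(rec, plan, seed = 1) {
  if (!length(plan)) {
    return(list(recording = rec,
                intervals = data.frame(type = character(),
                                       channel = character(),
                                       start = integer(), end = integer())))
  }
  fs <- rec$fs; total <- n_samples(rec)
  x <- rec$data
  rows <- list()
  # merge overlapping same-type/channel events
  key <- vapply(plan, function(e) {
    paste(e$type, paste(e$channels %||% "", collapse = "+"))
  }, character(1))
  for (k in unique(key)) {
    ev <- plan[key == k]
    if (length(ev) > 1) {
      iv <- cbind(vapply(ev, `[[`, 0, "onset"),
                  vapply(ev, function(e) e$onset + e$duration, 0))
      o <- order(iv[, 1])
      iv <- iv[o, , drop = FALSE]
      if (any(iv[-1, 1] < iv[-nrow(iv), 2])) {
        warning("overlapping artifact events merged")
        merged <- list(); cur <- iv[1, ]
        for (i in seq_len(nrow(iv))[-1]) {
          if (iv[i, 1] < cur[2]) cur[2] <- max(cur[2], iv[i, 2])
          else { merged[[length(merged) + 1]] <- cur; cur <- iv[i, ] }
        }
        merged[[length(merged) + 1]] <- cur
        tmpl <- ev[[1]]
        ev <- lapply(merged, function(m) {
          tmpl$onset <- m[1]; tmpl$duration <- m[2] - m[1]; tmpl
        })
        plan <- c(plan[key != k], ev)
      }
    }
  }
  with_seed(seed, {
    for (e in plan) {
      i0 <- max(1L, round(e$onset * fs) + 1L)
      i1 <- min(total, round((e$onset + e$duration) * fs))
      if (i1 < i0) next
      chans <- e$channels
      if (is.null(chans)) {
        chans <- switch(e$type,
          blink = intersect(c("Fp1", "Fp2", "F3", "Fz", "F4"), rec$channels),
          rec$channels[1])
        if (!length(chans)) chans <- rec$channels[1]
      }
      idx <- match(chans, rec$channels)
      if (anyNA(idx)) stop("artifact channel not in montage")
      span <- i1 - i0 + 1L
      wave <- switch(e$type,
        blink = e$amplitude * (0.5 - 0.5 * cos(2 * pi * seq_len(span) / span)),
        drift = (e$amplitude / 2) * sin(2 * pi * seq_len(span) / span / 2),
        pop = rep(e$amplitude, span),
        dead = NULL)
      if (e$type == "dead") {
        for (ci in idx) {
          x[ci, i0:i1] <- stats::rnorm(span, sd = stats::sd(x[ci, ]) * 0.2)
        }
      } else if (!is.null(wave) && e$amplitude != 0) {
        for (ci in idx) x[ci, i0:i1] <- x[ci, i0:i1] + wave
      }
      for (ci in idx) {
        rows[[length(rows) + 1]] <- data.frame(type = e$type,
                                               channel = rec$channels[ci],
                                               start = i0, end = i1)
      }
    }
  })
  list(recording = set_data(rec, x),
       intervals = if (length(rows)) do.call(rbind, rows) else
         data.frame(type = character(), channel = character(),
                    start = integer(), end = integer()))
}
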