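# Adaptive directed transfer function and pattern-level statistics.
#
# From the time-varying coefficients Lambda(k, t), the frequency-domain
# coefficient matrix is Lambda(f, t) = I - sum_k Lambda(k, t) exp(-i 2 pi
# f dt k); its inverse is the transfer matrix H(f, t), and the normalized
# directed influence of source j on target i is
#   gamma^2(i, j, f, t) = |H_ij|^2 / sum_m |H_im|^2,
# so each target row sums to one over sources at every (f, t).

#' Compute the ADTF tensor of a fitted model
#'
#' @param model an `mvaar_model` (time-varying) or `var_model` (stationary;
#'   yields a single time point).
#' @param freqs frequency grid in Hz.
#' @param t_stride evaluation stride in samples for time-varying models
#'   (default: every 10 ms).
#' @return an `adtf_tensor`: array `gamma2[target, source, frequency,
#'   time]` with `freqs`, `times` (sample indices) and `channels`
#'   attributes. Rows are normalized to sum to 1 over sources.
#' @export
adtf <- function(model, freqs = 1:50, t_stride = NULL) {
  stationary <- inherits(model, "var_model")
  if (!stationary && !inherits(model, "mvaar_model")) {
    stop("model must be an mvaar_model or var_model")
  }
  if (max(freqs) > model$fs / 2) stop("frequency grid beyond Nyquist")
  n <- dim(model$A)[1]; p <- model$p
  dt <- 1 / model$fs
  if (stationary) {
    times <- 1L
    getA <- function(t) model$A
  } else {
    total <- dim(model$A)[4]
    if (is.null(t_stride)) t_stride <- max(1L, round(0.01 * model$fs))
    times <- seq.int(p + 1L, total, by = t_stride)
    getA <- function(t) model$A[, , , t, drop = FALSE][, , , 1]
  }
  phase <- exp(-1i * 2 * pi * outer(freqs * dt, seq_len(p)))  # F x p
  g2 <- array(0, dim = c(n, n, length(freqs), length(times)))
  eye <- diag(n)
  for (ti in seq_along(times)) {
    Ak <- getA(times[ti])
    if (p == 1) Ak <- array(Ak, dim = c(n, n, 1))
    for (fi in seq_along(freqs)) {
      Af <- eye + 0i
      for (k in seq_len(p)) Af <- Af - phase[fi, k] * Ak[, , k]
      H <- tryCatch(solve(Af), error = function(e) {
        warning("near-singular coefficient matrix; ridge-regularized")
        solve(Af + 1e-8 * eye)
      })
      m <- Mod(H)^2
      g2[, , fi, ti] <- m / rowSums(m)
    }
  }
  structure(g2, freqs = freqs, times = times,
            channels = model$channels, fs = model$fs, class = "adtf_tensor")
}

#' @export
print.adtf_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<adtf_tensor> %d x %d channels, %d frequencies, %d time points\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

# resolve a band argument (name or c(low, high)) to frequency-row indices
resolve_band <- function(tensor, band) {
  freqs <- attr(tensor, "freqs")
  if (is.character(band)) {
    bd <- band_definitions()
    row <- bd[bd$name == band, ]
    if (!nrow(row)) stop("unknown band: ", band)
    band <- c(row$low, row$high)
  }
  idx <- which(freqs >= band[1] & freqs <= band[2])
  if (!length(idx)) stop("band outside the tensor's frequency grid")
  idx
}

parse_1020 <- function(labels) {
  m <- regmatches(labels, regexec("^([A-Za-z]+?)([0-9]+|z)$", labels))
  bad <- labels[vapply(m, length, 1L) == 0]
  if (length(bad)) stop("unrecognized 10-20 labels: ",
                        paste(bad, collapse = ", "))
  data.frame(label = labels,
             row = vapply(m, `[`, "", 2),
             suffix = vapply(m, `[`, "", 3))
}

#' Define the six directional connectivity patterns
#'
#' Regions are assigned from extended 10-20 rows: anterior = F/FC rows,
#' posterior = CP/P/PO/O rows (the central C row belongs to neither);
#' left/right by odd/even label suffix, midline (z) excluded from lateral
#' patterns. Each pattern is the full ordered cross product of (source,
#' target) electrodes, self-pairs excluded.
#'
#' @param montage character vector of retained channel labels.
#' @return a `pattern_set`: named list (`A->P`, `P->A`, `L->R`, `R->L`,
#'   `L->L`, `R->R`) of `data.frame`s with `source`, `target` columns.
#' @export
define_patterns <- function(montage = montage_retained()) {
  info <- parse_1020(montage)
  anterior <- info$label[info$row %in% c("F", "FC", "Fp")]
  posterior <- info$label[info$row %in% c("CP", "P", "PO", "O")]
  left <- info$label[info$suffix %in% c("1", "3", "5", "7", "9")]
  right <- info$label[info$suffix %in% c("2", "4", "6", "8", "10")]
  cross <- function(src, tgt) {
    d <- expand.grid(source = src, target = tgt, stringsAsFactors = FALSE)
    d[d$source != d$target, , drop = FALSE]
  }
  structure(list(
    "A->P" = cross(anterior, posterior),
    "P->A" = cross(posterior, anterior),
    "L->R" = cross(left, right),
    "R->L" = cross(right, left),
    "L->L" = cross(left, left),
    "R->R" = cross(right, right)),
    regions = list(anterior = anterior, posterior = posterior,
                   left = left, right = right),
    class = "pattern_set")
}

#' Collect supra-threshold connectivity coefficients for one pattern
#'
#' Gathers gamma^2 over every in-band frequency bin, time point and
#' electrode pair of the pattern, and keeps values above the threshold.
#'
#' @param tensor an [adtf()] result.
#' @param band band name (see [band_definitions()]) or `c(low, high)` Hz.
#' @param pattern a `data.frame` with `source`, `target` label columns
#'   (one element of [define_patterns()]).
#' @param threshold retention threshold on gamma^2 (default 0.3).
#' @return a `pattern_sample`: list with `values`, `threshold`, `band`,
#'   `n_possible` (pairs x bins x time points).
#' @export
pattern_samples <- function(tensor, band, pattern, threshold = 0.3) {
  fidx <- resolve_band(tensor, band)
  chans <- attr(tensor, "channels")
  si <- match(pattern$source, chans)
  ti <- match(pattern$target, chans)
  keep <- !is.na(si) & !is.na(ti)
  if (!all(keep)) {
    message("dropping ", sum(!keep), " pattern pairs absent from montage")
    si <- si[keep]; ti <- ti[keep]
  }
  vals <- numeric(0)
  for (k in seq_along(si)) {
    v <- tensor[ti[k], si[k], fidx, , drop = TRUE]
    vals <- c(vals, as.vector(v))
  }
  structure(list(values = vals[vals > threshold], threshold = threshold,
                 band = band,
                 n_possible = length(si) * length(fidx) * dim(tensor)[4]),
            class = "pattern_sample")
}

sample_values <- function(x) {
  if (inherits(x, "pattern_sample")) x$values else as.numeric(x)
}

#' Compare viewing and baseline connectivity samples
#'
#' Rank-sum (Mann-Whitney) comparison of two unpaired coefficient samples:
#' one-sided (viewing greater, the directional hypothesis) and two-sided,
#' with medians, rank-biserial effect size and normalized histograms on a
#' common grid.
#'
#' @param viewing,baseline `pattern_sample`s or numeric vectors.
#' @return a list report: `p_greater`, `p_two_sided`, medians, `effect`
#'   (rank-biserial correlation), `histograms`.
#' @export
compare_conditions <- function(viewing, baseline) {
  v <- sample_values(viewing); b <- sample_values(baseline)
  if (!length(v) || !length(b)) {
    return(list(comparable = FALSE, reason = "empty sample"))
  }
  wg <- stats::wilcox.test(v, b, alternative = "greater", exact = FALSE)
  w2 <- stats::wilcox.test(v, b, alternative = "two.sided", exact = FALSE)
  auc <- wg$statistic / (length(v) * length(b))
  breaks <- seq(0, 1, by = 0.02)
  hist_of <- function(s) {
    h <- graphics::hist(pmin(s, 1), breaks = breaks, plot = FALSE)
    h$counts / max(1, sum(h$counts))
  }
  list(comparable = TRUE,
       p_greater = wg$p.value, p_two_sided = w2$p.value,
       median_viewing = stats::median(v), median_baseline = stats::median(b),
       effect = as.numeric(2 * auc - 1),
       n = c(viewing = length(v), baseline = length(b)),
       histograms = list(breaks = breaks, viewing = hist_of(v),
                         baseline = hist_of(b)))
}

#' Count supra-threshold connections per electrode pair
#'
#' For each pattern, counts (frequency bin x time point) occurrences of
#' gamma^2 above threshold per ordered pair, and identifies the source
#' channel with the most connections.
#'
#' @param tensor an [adtf()] result.
#' @param band band name or `c(low, high)` Hz.
#' @param patterns a [define_patterns()] result (or subset).
#' @param threshold counting threshold on gamma^2.
#' @return list with `counts` (`data.frame`: pattern, source, target,
#'   count) and `top_source` per pattern.
#' @export
count_strong_connections <- function(tensor, band, patterns, threshold = 0.3) {
  fidx <- resolve_band(tensor, band)
  chans <- attr(tensor, "channels")
  rows <- list()
  for (pn in names(patterns)) {
    pat <- patterns[[pn]]
    si <- match(pat$source, chans); ti <- match(pat$target, chans)
    keep <- !is.na(si) & !is.na(ti)
    si <- si[keep]; ti <- ti[keep]; pat <- pat[keep, , drop = FALSE]
    cnt <- vapply(seq_along(si), function(k) {
      sum(tensor[ti[k], si[k], fidx, ] > threshold)
    }, numeric(1))
    rows[[pn]] <- data.frame(pattern = pn, source = pat$source,
                             target = pat$target, count = cnt)
  }
  counts <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  top <- vapply(split(counts, counts$pattern), function(d) {
    tot <- tapply(d$count, d$source, sum)
    names(tot)[which.max(tot)]
  }, character(1))
  list(counts = counts, top_source = top, threshold = threshold)
}

#' Windowed pattern-mean connectivity timecourse
#'
#' Mean in-band gamma^2 over each pattern's pairs per consecutive window
#' (1 s by default: five values per pattern for a 5-s epoch).
#'
#' @inheritParams count_strong_connections
#' @param window window length in seconds; a partial trailing window is
#'   dropped.
#' @return `data.frame` with `pattern`, `window`, `mean`.
#' @export
pattern_timecourse <- function(tensor, band, patterns, window = 1) {
  fidx <- resolve_band(tensor, band)
  chans <- attr(tensor, "channels")
  times <- attr(tensor, "times"); fs <- attr(tensor, "fs")
  span <- (times - times[1]) / fs
  stride <- if (length(times) > 1) diff(times)[1] else 1
  duration <- (max(times) + stride - times[1]) / fs
  nwin <- floor(duration / window + 1e-9)
  if (nwin < 1) stop("epoch shorter than one window")
  win <- pmin(nwin, floor(span / window) + 1L)
  rows <- list()
  for (pn in names(patterns)) {
    pat <- patterns[[pn]]
    si <- match(pat$source, chans); ti <- match(pat$target, chans)
    keep <- !is.na(si) & !is.na(ti); si <- si[keep]; ti <- ti[keep]
    block <- vapply(seq_along(si), function(k) {
      colMeans(matrix(tensor[ti[k], si[k], fidx, ], nrow = length(fidx)))
    }, numeric(dim(tensor)[4]))   # time x pairs
    pm <- rowMeans(block)
    rows[[pn]] <- data.frame(pattern = pn, window = seq_len(nwin),
                             mean = as.numeric(tapply(pm, win, mean)[seq_len(nwin)]))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Group contrast of pattern connectivity samples
#'
#' Rank-sum comparison between two groups (e.g. gender, age extremes) for
#' each pattern, plus per-group mean strengths.
#'
#' @param samples named list of two groups, each a named list of
#'   `pattern_sample`s (or numeric vectors) keyed by pattern.
#' @return `data.frame` per pattern: group medians/means, two-sided p, and
#'   a `descriptive_only` flag when a sample has fewer than 2 values.
#' @export
group_contrast <- function(samples) {
  if (length(samples) != 2) stop("exactly two groups required")
  gn <- names(samples)
  patterns <- intersect(names(samples[[1]]), names(samples[[2]]))
  if (!length(patterns)) stop("no shared patterns between groups")
  rows <- lapply(patterns, function(pn) {
    a <- sample_values(samples[[1]][[pn]])
    b <- sample_values(samples[[2]][[pn]])
    desc <- length(a) < 2 || length(b) < 2
    p <- if (desc || !length(a) || !length(b)) NA_real_ else {
      stats::wilcox.test(a, b, exact = FALSE)$p.value
    }
    data.frame(pattern = pn, p = p,
               median_1 = if (length(a)) stats::median(a) else NA_real_,
               median_2 = if (length(b)) stats::median(b) else NA_real_,
               mean_1 = if (length(a)) mean(a) else NA_real_,
               mean_2 = if (length(b)) mean(b) else NA_real_,
               descriptive_only = desc)
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- gn
  out
}

#' One Monte-Carlo replicate of the viewing/baseline condition contrast
#'
#' Generates independent short epochs for a baseline and a viewing
#' condition on a 4-channel montage (F3, F4, O1, O2); the viewing condition
#' raises the right-to-left coupling gain by `boost`. Each epoch
#' contributes one exchangeable observation: its mean in-band right-to-left
#' gamma^2. Returns the one-sided rank-sum p-value, the calibration unit
#' for type-I-error studies of [compare_conditions()].
#'
#' @param seed integer seed.
#' @param n_epochs independent epochs per condition.
#' @param boost added right-to-left coupling gain in the viewing condition
#'   (0 gives the null).
#' @param base_gain shared baseline coupling gain.
#' @param fs sampling rate in Hz.
#' @param epoch_s epoch duration in seconds.
#' @param band analysis band.
#' @return list with `p` (one-sided), `viewing`, `baseline` (epoch means).
#' @export
condition_contrast_replicate <- function(seed, n_epochs = 8, boost = 0,
                                         base_gain = 0.05, fs = 250,
                                         epoch_s = 2, band = "alpha") {
  labels <- c("F3", "F4", "O1", "O2")
  rl_pairs <- data.frame(source = c("O2", "F4"), target = c("O1", "F3"))
  make_spec <- function(gain) {
    connectivity_spec(4, osc_freq = 10, damping = c(0.90, 0.90, 0.93, 0.93),
                      couplings = data.frame(source = c(4, 2),
                                             target = c(3, 1),
                                             gain = gain),
                      noise_scale = 5, labels = labels)
  }
  epoch_mean <- function(spec, s) {
    sim <- simulate_mvar_eeg(spec, epoch_s, fs, seed = s)
    model <- fit_mvaar_kalman(sim$recording$data, p = 2, uc = 1e-3, fs = fs)
    tens <- adtf(model, freqs = 8:12, t_stride = round(0.04 * fs))
    ps <- pattern_samples(tens, band, rl_pairs, threshold = 0)
    mean(ps$values)
  }
  base_spec <- make_spec(base_gain)
  view_spec <- make_spec(base_gain + boost)
  baseline <- vapply(seq_len(n_epochs), function(i) {
    epoch_mean(base_spec, child_seed(seed, i))
  }, numeric(1))
  viewing <- vapply(seq_len(n_epochs), function(i) {
    epoch_mean(view_spec, child_seed(seed, 1000 + i))
  }, numeric(1))
  list(p = stats::wilcox.test(viewing, baseline,
                              alternative = "greater")$p.value,
       viewing = viewing, baseline = baseline)
}
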