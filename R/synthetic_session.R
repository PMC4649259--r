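# Synthetic viewing sessions: a baseline block facing a blank wall followed
# by annotated piece-viewing epochs whose oscillator damping and directed
# coupling gains depend on the piece's complexity class.

#' Class-dependent generator parameters
#'
#' Returns, per complexity class, the posterior/frontal oscillator pole
#' radii and the directed coupling gain applied to the session's
#' posterior-to-anterior and right-to-left pairs. Defaults encode the effect
#' structure the downstream stages must detect: viewing suppresses the
#' posterior alpha rhythm, engages frontal activity, and raises directed
#' coupling, more so for complex pieces.
#'
#' @return `data.frame` keyed by `class`.
#' @export
class_gain_table <- function() {
  data.frame(
    class = c("baseline", "moderate", "complex"),
    r_posterior = c(0.97, 0.93, 0.88),
    r_frontal = c(0.90, 0.92, 0.94),
    r_central = c(0.92, 0.92, 0.92),
    coupling_gain = c(0.01, 0.06, 0.12))
}

#' Specify a synthetic recording session
#'
#' @param subject subject identifier.
#' @param pieces `data.frame` with columns `piece` (id), `class`
#'   (`"complex"`/`"moderate"`), `duration` (s).
#' @param baseline_s baseline (blank wall) duration in seconds.
#' @param fs sampling rate in Hz.
#' @param seed integer; fixes the session byte-for-byte.
#' @param age,gender covariates carried into reports; they do not alter the
#'   generator unless `gain_scale` is set.
#' @param gain_scale global multiplier on coupling gains (used for
#'   group-effect simulations).
#' @param montage `"full32"` (peripheral channels synthesized too) or
#'   `"retained"` (20 scalp channels only).
#' @param artifact_plan optional list of [artifact_event()]s.
#' @param gains optional replacement for [class_gain_table()].
#' @return a `session_spec` object.
#' @export
session_spec <- function(subject, pieces, baseline_s = 60, fs = 1000,
                         seed = 1, age = NA, gender = NA_character_,
                         gain_scale = 1, montage = c("full32", "retained"),
                         artifact_plan = NULL, gains = class_gain_table()) {
  montage <- match.arg(montage)
  pieces <- as.data.frame(pieces)
  stopifnot(baseline_s > 0, all(pieces$duration > 0),
            all(pieces$class %in% gains$class))
  structure(list(subject = subject, pieces = pieces, baseline_s = baseline_s,
                 fs = fs, seed = seed, age = age, gender = gender,
                 gain_scale = gain_scale, montage = montage,
                 artifact_plan = artifact_plan, gains = gains),
            class = "session_spec")
}

region_of <- function(labels) {
  ifelse(grepl("^(F|FC|Fp)", labels), "frontal",
         ifelse(grepl("^(O|PO|P)", labels), "posterior", "central"))
}

# Directed pairs raised during viewing: posterior->anterior and
# right->left, on the retained montage. Sources are posterior (10 Hz
# rhythm) and targets frontal/central (6/8 Hz), so no coupling drives a
# target at its own resonance (resonance-matched chains are unstable in
# amplitude even when formally stationary).
session_coupling_pairs <- function(labels) {
  pairs <- rbind(
    data.frame(source = "O1", target = "F3"),   # P->A, L->L
    data.frame(source = "Oz", target = "Fz"),   # P->A
    data.frame(source = "O2", target = "F4"),   # P->A, R->R
    data.frame(source = "Pz", target = "FC1"),  # P->A
    data.frame(source = "O2", target = "F3"),   # R->L (and P->A)
    data.frame(source = "P4", target = "FC5"),  # R->L
    data.frame(source = "P4", target = "C3"))   # R->L
  pairs[pairs$source %in% labels & pairs$target %in% labels, , drop = FALSE]
}

#' Generate a full synthetic session with ground truth
#'
#' Simulates the retained 20-channel scalp montage as a piecewise-constant
#' VAR(2) process (one regime per baseline/piece block, parameters from the
#' spec's class gain table), optionally appends synthesized peripheral
#' channels (attenuated neighbor mixtures plus independent noise), injects
#' any planned artifacts, and annotates block starts.
#'
#' @param spec a [session_spec()].
#' @return list with `recording`, `truth` (per-block class, coupling matrix
#'   and coefficient array; artifact intervals) and `spec`.
#' @export
generate_session <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  core <- montage_retained()
  reg <- region_of(core)
  osc <- ifelse(reg == "posterior", 10, ifelse(reg == "frontal", 6, 8))
  gains <- spec$gains
  blocks <- data.frame(
    label = c("baseline", paste0("piece_", spec$pieces$piece)),
    class = c("baseline", spec$pieces$class),
    duration = c(spec$baseline_s, spec$pieces$duration))
  pairs <- session_coupling_pairs(core)
  t0 <- cumsum(c(0, blocks$duration))
  couplings <- do.call(rbind, lapply(seq_len(nrow(blocks)), function(b) {
    g <- gains[gains$class == blocks$class[b], ]
    data.frame(source = match(pairs$source, core),
               target = match(pairs$target, core),
               gain = g$coupling_gain * spec$gain_scale,
               onset = t0[b], offset = t0[b + 1])
  }))
  # class-dependent damping: encode per block by simulating block-wise
  total_truth <- list()
  segs <- vector("list", nrow(blocks))
  carry <- NULL
  for (b in seq_len(nrow(blocks))) {
    g <- gains[gains$class == blocks$class[b], ]
    damping <- ifelse(reg == "posterior", g$r_posterior,
                      ifelse(reg == "frontal", g$r_frontal, g$r_central))
    cs <- connectivity_spec(length(core), osc_freq = osc, damping = damping,
                            couplings = data.frame(
                              source = match(pairs$source, core),
                              target = match(pairs$target, core),
                              gain = g$coupling_gain * spec$gain_scale),
                            target_sd = 12, labels = core)
    sim <- simulate_mvar_eeg(cs, blocks$duration[b], spec$fs,
                             seed = child_seed(spec$seed, b))
    seg <- sim$recording$data
    if (!is.null(carry)) {
      # soften the block boundary: crossfade first 100 ms with carry tail
      nfade <- min(round(0.1 * spec$fs), ncol(seg))
      w <- seq(0, 1, length.out = nfade)
      seg[, seq_len(nfade)] <- seg[, seq_len(nfade), drop = FALSE] *
        rep(w, each = nrow(seg)) +
        carry[, seq_len(nfade), drop = FALSE] * rep(1 - w, each = nrow(seg))
    }
    carry <- seg[, max(1, ncol(seg) - round(0.2 * spec$fs)):ncol(seg),
                 drop = FALSE]
    segs[[b]] <- seg
    blk <- sim$truth$blocks[[1]]
    blk$t0 <- t0[b]; blk$t1 <- t0[b + 1]
    blk$class <- blocks$class[b]; blk$label <- blocks$label[b]
    total_truth[[b]] <- blk
  }
  x <- do.call(cbind, segs)
  # shared common-mode component (reference-like): gives channels the
  # strong mutual correlation of referential EEG without adding any
  # directed structure; the common average reference removes it exactly.
  cm <- with_seed(child_seed(spec$seed, 555), {
    as.numeric(stats::filter(stats::rnorm(ncol(x), sd = 6),
                             0.95, method = "recursive"))
  })
  x <- x + rep(cm, each = nrow(x))
  ann <- data.frame(label = blocks$label,
                    sample = round(t0[-length(t0)] * spec$fs) + 1L)
  labels <- core
  if (spec$montage == "full32") {
    periph <- peripheral_labels()
    neighbor <- c(Fp1 = "F3", Fp2 = "F4", F7 = "F3", F8 = "F4", T7 = "C3",
                  T8 = "C4", TP9 = "CP5", TP10 = "CP6", P7 = "P3", P8 = "P4",
                  PO9 = "O1", PO10 = "O2")
    px <- with_seed(child_seed(spec$seed, 999), {
      m <- matrix(0, length(periph), ncol(x))
      for (i in seq_along(periph)) {
        src <- x[match(neighbor[[periph[i]]], core), ]
        m[i, ] <- 0.7 * src + stats::rnorm(ncol(x), sd = 10)
      }
      m
    })
    x <- rbind(x, px)
    labels <- c(core, periph)
    # restore cap order
    ord <- match(montage_32(), labels)
    x <- x[ord, , drop = FALSE]
    labels <- labels[ord]
  }
  rec <- recording(x, labels, spec$fs, ann, subject = spec$subject,
                   meta = list(age = spec$age, gender = spec$gender))
  truth <- list(fs = spec$fs, blocks = total_truth, artifacts = NULL)
  if (!is.null(spec$artifact_plan) && length(spec$artifact_plan)) {
    inj <- inject_artifacts(rec, spec$artifact_plan,
                            seed = child_seed(spec$seed, 7))
    rec <- inj$recording
    truth$artifacts <- inj$intervals
  }
  list(recording = rec, truth = truth, spec = spec)
}
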