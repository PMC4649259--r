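test_that("uncoupled identical oscillators give near-zero cross-correlation", {
  spec <- connectivity_spec(4, osc_freq = 10, damping = 0.9)
  sim <- simulate_mvar_eeg(spec, 10, 250, seed = 1)
  cc <- cor(t(sim$recording$data))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.15)
})

test_that("a driven channel inherits the driver's spectral peak", {
  spec <- connectivity_spec(2, osc_freq = c(10, 3), damping = c(0.95, 0.7),
                            couplings = data.frame(source = 1, target = 2,
                                                   gain = 0.5))
  sim <- simulate_mvar_eeg(spec, 10, 250, seed = 2)
  # Welch-style periodogram oracle (smoothed periodogram, base R)
  sp <- spec.pgram(ts(sim$recording$data[2, ], frequency = 250),
                   spans = 11, plot = FALSE)
  peak_hz <- sp$freq[which.max(sp$spec)]
  expect_gte(peak_hz, 8)
  expect_lte(peak_hz, 12)
})

test_that("simulation is deterministic and respects preconditions", {
  spec <- connectivity_spec(3, osc_freq = 10, damping = 0.9)
  a <- simulate_mvar_eeg(spec, 2, 250, seed = 9)
  b <- simulate_mvar_eeg(spec, 2, 250, seed = 9)
  expect_identical(a$recording$data, b$recording$data)
  expect_error(simulate_mvar_eeg(spec, 2, 15, seed = 1), "fs must exceed")
  unstable <- connectivity_spec(2, osc_freq = 10, damping = 0.99,
                                couplings = data.frame(source = c(1, 2),
                                                       target = c(2, 1),
                                                       gain = 1.2))
  expect_error(simulate_mvar_eeg(unstable, 2, 250, seed = 1),
               "spectral radius")
})

test_that("target_sd calibration equalizes channel amplitudes", {
  # heterogeneous damping, no coupling: every channel lands on target
  spec <- connectivity_spec(3, osc_freq = c(10, 6, 8),
                            damping = c(0.97, 0.85, 0.93), target_sd = 12)
  sim <- simulate_mvar_eeg(spec, 20, 250, seed = 3)
  sds <- apply(sim$recording$data, 1, sd)
  expect_true(all(sds > 10 & sds < 14))
  # with coupling, undriven channels stay calibrated and the driven
  # channel stays bounded (innovation floors at zero)
  spec2 <- connectivity_spec(3, osc_freq = c(10, 6, 8),
                             damping = c(0.97, 0.9, 0.93),
                             couplings = data.frame(source = 1, target = 2,
                                                    gain = 0.1),
                             target_sd = 12)
  sds2 <- apply(simulate_mvar_eeg(spec2, 20, 250, seed = 3)$recording$data,
                1, sd)
  expect_true(all(sds2[c(1, 3)] > 10 & sds2[c(1, 3)] < 14))
  expect_lt(sds2[2], 3 * 12)
})

test_that("artifact injection is identity for an empty plan and additive for pops", {
  spec <- connectivity_spec(4, osc_freq = 10, damping = 0.9)
  rec <- simulate_mvar_eeg(spec, 10, 250, seed = 4)$recording
  out <- inject_artifacts(rec, list(), seed = 1)
  expect_identical(out$recording$data, rec$data)
  zero_drift <- inject_artifacts(rec, list(
    artifact_event("drift", onset = 1, duration = 3, amplitude = 0,
                   channels = "Ch1")), seed = 1)
  expect_equal(zero_drift$recording$data, rec$data)
  pop <- inject_artifacts(rec, list(
    artifact_event("pop", onset = 5, duration = 0.2, amplitude = 500,
                   channels = "Ch2")), seed = 1)
  iv <- pop$intervals
  expect_gte(max(abs(pop$recording$data[2, iv$start:iv$end])), 500)
})

test_that("a dead channel loses its windowed correlation with the montage", {
  rec <- make_correlated_recording(6, secs = 10)
  out <- inject_artifacts(rec, list(
    artifact_event("dead", onset = 0, duration = 10, channels = "Ch4")),
    seed = 5)
  # recompute windowed correlations directly (oracle)
  wlen <- 2 * 250
  meds <- vapply(seq_len(5), function(w) {
    seg <- out$recording$data[, ((w - 1) * wlen + 1):(w * wlen)]
    cc <- cor(t(seg))
    median(cc[4, -4])
  }, numeric(1))
  expect_lt(median(meds), 0.2)
})

test_that("overlapping artifact events are merged with a warning", {
  rec <- make_correlated_recording(4, secs = 6)
  expect_warning(
    inject_artifacts(rec, list(
      artifact_event("pop", onset = 1, duration = 1, amplitude = 300,
                     channels = "Ch1"),
      artifact_event("pop", onset = 1.5, duration = 1, amplitude = 300,
                     channels = "Ch1")), seed = 1),
    "merged")
})

test_that("sessions carry ordered annotations and class-specific truth", {
  classes <- rep(c("complex", "moderate"), each = 4)
  spec <- session_spec("s9", pieces = data.frame(piece = 1:8,
                                                 class = classes,
                                                 duration = 6),
                       baseline_s = 60, fs = 250, seed = 6)
  sess <- generate_session(spec)
  ann <- sess$recording$annotations
  expect_equal(nrow(ann), 9)
  expect_equal(ann$label[1], "baseline")
  expect_true(all(diff(ann$sample) > 0))
  # truth blocks: coupling matrices differ from baseline only on the
  # session's designated pairs, with class-dependent gains
  base_cm <- sess$truth$blocks[[1]]$coupling
  cm1 <- sess$truth$blocks[[2]]$coupling   # complex
  diffs <- which(cm1 != base_cm, arr.ind = TRUE)
  gains <- class_gain_table()
  expect_true(all(cm1[diffs] ==
                  gains$coupling_gain[gains$class == "complex"]))
  sess2 <- generate_session(spec)
  expect_identical(sess$recording$data, sess2$recording$data)
})

test_that("null sessions (equal gains) encode no condition contrast", {
  gains <- class_gain_table()
  gains$coupling_gain[] <- 0.05
  gains$r_posterior[] <- 0.93; gains$r_frontal[] <- 0.92
  gains$r_central[] <- 0.92
  spec <- session_spec("s0", pieces = data.frame(piece = 1, class = "complex",
                                                 duration = 6),
                       baseline_s = 12, fs = 250, seed = 7, gains = gains)
  sess <- generate_session(spec)
  cms <- lapply(sess$truth$blocks, `[[`, "coupling")
  expect_equal(cms[[1]], cms[[2]])
})

test_that("synthetic images order luminance spread by class", {
  complex <- generate_synthetic_images("complex", 128, seed = 1)
  moderate <- generate_synthetic_images("moderate", 128, seed = 1)
  baseline <- generate_synthetic_images("baseline", 128, seed = 1)
  expect_equal(luminance_features(baseline)[["dark_fraction"]], 0)
  sds <- c(luminance_features(complex)[["lum_sd"]],
           luminance_features(moderate)[["lum_sd"]],
           luminance_features(baseline)[["lum_sd"]])
  expect_true(sds[1] > sds[2] && sds[2] > sds[3])
  expect_identical(generate_synthetic_images("complex", 64, seed = 3),
                   generate_synthetic_images("complex", 64, seed = 3))
  expect_error(generate_synthetic_images("complex", 32), "64")
})
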