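test_that("high-pass filtering removes offsets and keeps alpha", {
  fs <- 250
  t <- seq_len(10 * fs) / fs
  x <- rbind(rep(100, length(t)), 50 + sin(2 * pi * 10 * t))
  rec <- recording(x, c("Cz", "Pz"), fs)
  out <- highpass_filter(rec)
  expect_lt(max(abs(out$data[1, ])), 1e-8)
  mid <- 500:2000
  expect_equal(sd(out$data[2, mid]), sd(sin(2 * pi * 10 * t)[mid]),
               tolerance = 0.01)
  rec$data[1, 5] <- NA
  expect_error(highpass_filter(rec), "Cz")
})

test_that("bad-channel detection flags only the decorrelated channel", {
  rec <- make_correlated_recording(8, secs = 10, noise_channels = 5)
  rep <- detect_bad_channels(rec, corr_threshold = 0.4)
  expect_identical(rep$rejected, "Ch5")
  # brute-force oracle: windowed correlations computed independently
  wlen <- 500
  flagged <- sapply(seq_len(5), function(w) {
    seg <- rec$data[, ((w - 1) * wlen + 1):(w * wlen)]
    cc <- cor(t(seg)); diag(cc) <- NA
    rowSums(cc < 0.4, na.rm = TRUE) >= 0.8 * 7
  })
  expect_equal(unname(rep$fractions), unname(rowMeans(flagged)))
  clean <- make_correlated_recording(8, secs = 10)
  expect_length(detect_bad_channels(clean, 0.4)$rejected, 0)
  short <- recording(matrix(rnorm(8 * 100), 8), paste0("Ch", 1:8), 250)
  expect_error(detect_bad_channels(short), "shorter")
})

test_that("peripheral removal reduces the 32-channel montage to 20", {
  x <- matrix(rnorm(32 * 500), 32)
  rec <- recording(x, montage_32(), 250)
  out <- remove_peripheral_channels(rec)
  expect_length(out$channels, 20)
  expect_identical(out$channels, montage_retained())
  ident <- remove_peripheral_channels(rec, labels = character(0))
  expect_identical(ident$data, rec$data)
  expect_error(remove_peripheral_channels(rec, labels = montage_32()),
               "no channels")
  expect_error(remove_peripheral_channels(rec, labels = "XX9", strict = TRUE),
               "unknown")
})

test_that("ASR attenuates pops, is identity at infinite threshold, and
           leaves quiet stretches untouched", {
  spec <- connectivity_spec(6, osc_freq = 10, damping = 0.9)
  rec <- simulate_mvar_eeg(spec, 20, 250, seed = 1)$recording
  inj <- inject_artifacts(rec, list(
    artifact_event("pop", onset = 12, duration = 0.3, amplitude = 500,
                   channels = "Ch3")), seed = 2)
  dirty <- inj$recording
  iv <- inj$intervals
  expect_equal(asr_clean(dirty, k_sd = Inf)$data, dirty$data)
  clean <- asr_clean(dirty)
  pre <- max(abs(dirty$data[3, iv$start:iv$end]))
  post <- max(abs(clean$data[3, iv$start:iv$end]))
  expect_lt(post, 0.5 * pre)
  quiet <- 2000:2400
  expect_lt(max(abs(clean$data[, quiet] - dirty$data[, quiet])), 1e-8)
  short_cal <- recording(dirty$data[, 1:500], dirty$channels, 250)
  expect_error(asr_clean(dirty, calibration = short_cal), "5 s")
})

test_that("common average reference zeroes the channel mean", {
  x <- rbind(rnorm(400) + 5, rnorm(400) - 2, rnorm(400))
  rec <- recording(x, c("C3", "Cz", "C4"), 100)
  out <- rereference_car(rec)
  expect_lt(max(abs(colMeans(out$data))), 1e-9)
  pm <- recording(rbind(rep(1, 100), rep(-1, 100)), c("C3", "C4"), 100)
  expect_equal(rereference_car(pm)$data, pm$data)
  expect_error(rereference_car(recording(matrix(1, 1, 100), "Cz", 100)),
               "two channels")
})

test_that("segmentation yields one epoch per annotation with 1-s segments", {
  fs <- 250
  n <- 40 * fs
  x <- matrix(rnorm(2 * n), 2)
  ann <- data.frame(label = c("baseline", paste0("piece_", 1:4)),
                    sample = c(1L, seq(10, 34, by = 8) * fs + 1L))
  rec <- recording(x, c("Cz", "Pz"), fs, ann)
  es <- segment_epochs(rec)
  expect_length(es$epochs, 5)
  expect_true(all(vapply(es$epochs, function(e) length(e$segments), 1L) == 5))
  expect_equal(vapply(es$epochs, `[[`, "", "piece")[1], "baseline")
  # one-segment degenerate split
  es1 <- segment_epochs(rec, epoch_len = 5, sub_len = 5)
  expect_true(all(vapply(es1$epochs, function(e) length(e$segments), 1L) == 1))
  # truncated trailing epoch is dropped with a warning
  ann2 <- rbind(ann, data.frame(label = "piece_5", sample = n - fs))
  rec2 <- recording(x, c("Cz", "Pz"), fs, ann2)
  expect_warning(es2 <- segment_epochs(rec2), "dropped")
  expect_length(es2$epochs, 5)
})

test_that("the full chain preserves reference and montage bookkeeping", {
  sess <- generate_session(tiny_session_spec(seed = 21))
  pp <- preprocess(sess$recording)
  expect_length(pp$recording$channels, 20)
  expect_lt(max(abs(colMeans(pp$recording$data))), 1e-9)
  expect_length(pp$epochs$epochs, 4)  # baseline + 3 pieces
  expect_equal(ncol(pp$epochs$epochs[[1]]$data), 5 * 250)
})
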