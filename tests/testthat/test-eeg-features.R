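fs <- 250
t1s <- seq_len(fs) / fs

test_that("time-domain features count 24 and respond to band content", {
  withr::with_seed(1, x <- rnorm(fs))
  v <- time_domain_features(x, fs)
  expect_length(v, 24)
  expect_equal(v[["broadband.sd"]], sd(x))
  alpha <- sin(2 * pi * 10 * t1s)
  va <- time_domain_features(alpha, fs)
  expect_gt(va[["alpha.max"]], 0.8 * va[["broadband.max"]])
  expect_lt(va[["gamma.sd"]], 0.02)
  const <- time_domain_features(rep(3, fs), fs)
  expect_equal(const[["broadband.kurtosis"]], 0)
  expect_equal(const[["broadband.entropy"]], 0)
  expect_true(attr(const, "degenerate"))
})

test_that("multitaper features count 15 and localize a 10 Hz tone", {
  x <- sin(2 * pi * 10 * t1s)
  v <- frequency_domain_features(x, fs)
  expect_length(v, 15)
  others <- v[c("delta.power", "theta.power", "beta.power", "gamma.power")]
  expect_true(all(v[["alpha.power"]] > 10 * others))
  # entropy bounded by log2(bin count); near the bound for flat spectra
  withr::with_seed(2, {
    ents <- replicate(20, frequency_domain_features(rnorm(fs), fs)[["alpha.entropy"]])
  })
  b <- length(which(1:50 >= 8 & 1:50 <= 12))
  expect_true(all(ents <= log2(b) + 1e-9))
  expect_gt(mean(ents), 0.85 * log2(b))
  expect_error(frequency_domain_features(x, fs,
                                         bands = data.frame(name = "hf",
                                                            low = 60,
                                                            high = 80)),
               "grid")
})

test_that("wavelet features count 15, localize tones, and scale quadratically", {
  x <- sin(2 * pi * 10 * t1s)
  v <- wavelet_domain_features(x, fs)
  expect_length(v, 15)
  expect_gt(v[["alpha.power"]], 10 * v[["gamma.power"]])
  v2 <- wavelet_domain_features(2 * x, fs)
  for (b in band_definitions()$name) {
    expect_equal(v2[[paste0(b, ".power")]], 4 * v[[paste0(b, ".power")]],
                 tolerance = 1e-10)
  }
})

test_that("identical segments produce identical feature rows", {
  withr::with_seed(5, x <- rnorm(fs))
  expect_identical(time_domain_features(x, fs), time_domain_features(x, fs))
  expect_identical(frequency_domain_features(x, fs),
                   frequency_domain_features(x, fs))
})

test_that("feature tables have the documented shape per domain", {
  sess <- generate_session(tiny_session_spec(seed = 31))
  pp <- preprocess(sess$recording)
  ft <- build_feature_table(pp$epochs, domain = "time")
  expect_s3_class(ft, "feature_table")
  expect_equal(nrow(feature_info(ft)), 24 * 20)   # 480 columns
  expect_equal(nrow(ft), 4 * 5)                   # 4 epochs x 5 segments
  expect_false(anyNA(feature_matrix(ft)))
  ff <- build_feature_table(pp$epochs, domain = "frequency")
  expect_equal(nrow(feature_info(ff)), 15 * 20)   # 300 columns
  info <- feature_info(ft)
  expect_setequal(unique(info$channel), montage_retained())
  expect_setequal(unique(info$band),
                  c("broadband", band_definitions()$name))
  # class labels flow from the complexity mapping
  ft2 <- build_feature_table(pp$epochs, domain = "time",
                             classes = c(piece_1 = "complex",
                                         piece_2 = "moderate",
                                         piece_3 = "moderate"))
  expect_setequal(unique(ft2$class), c("baseline", "complex", "moderate"))
})

test_that("dropped epochs shrink the table with a warning, not an error", {
  fs <- 250
  x <- matrix(rnorm(2 * 20 * fs), 2)
  ann <- data.frame(label = c("baseline", "piece_1", "piece_2"),
                    sample = c(1L, 8 * fs, as.integer(19.5 * fs)))
  rec <- recording(x, c("Cz", "Pz"), fs, ann)
  expect_warning(es <- segment_epochs(rec), "dropped")
  ft <- build_feature_table(es, domain = "time")
  expect_equal(nrow(ft), 2 * 5)  # baseline + piece_1 only
})
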