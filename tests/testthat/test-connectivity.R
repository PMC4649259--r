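test_that("Kalman MVAAR recovers a stationary VAR(2) and matches OLS", {
  spec <- connectivity_spec(3, osc_freq = c(10, 6, 8), damping = 0.9,
                            couplings = data.frame(source = c(1, 2),
                                                   target = c(2, 3),
                                                   gain = c(0.3, 0.2)))
  sim <- simulate_mvar_eeg(spec, 5, 250, seed = 42)
  truth <- sim$truth$blocks[[1]]$A
  model <- fit_mvaar_kalman(sim$recording$data, p = 2, uc = 1e-3, fs = 250)
  est <- mvaar_mean_coefficients(model)
  expect_lt(sqrt(mean((est - truth)^2)), 0.1)
  ols <- fit_var_ls(sim$recording$data, p = 2, fs = 250)
  expect_lt(sqrt(mean((est - ols$A)^2)), 0.1)
})

test_that("the filter tracks a coupling step within a second", {
  spec <- connectivity_spec(2, osc_freq = 10, damping = 0.9,
                            couplings = data.frame(source = 1, target = 2,
                                                   gain = 0.4, onset = 2.5,
                                                   offset = Inf))
  hits <- vapply(1:3, function(s) {
    sim <- simulate_mvar_eeg(spec, 5, 250, seed = s)
    m <- fit_mvaar_kalman(sim$recording$data, p = 2, uc = 1e-2, fs = 250)
    traj <- m$A[2, 1, 1, ]
    pre <- mean(traj[500:624]); post <- mean(traj[1000:1250])
    cross <- which(traj[625:1250] > (pre + post) / 2)[1]
    cross / 250
  }, numeric(1))
  expect_true(all(hits < 1))
})

test_that("white noise yields near-zero coefficients", {
  withr::with_seed(5, x <- matrix(rnorm(3 * 1250), 3))
  m <- fit_mvaar_kalman(x, p = 2, uc = 1e-3, fs = 250)
  expect_lt(max(abs(mvaar_mean_coefficients(m))), 0.1)
})

test_that("ADTF rows normalize to one and expose directionality", {
  spec <- connectivity_spec(2, osc_freq = 10, damping = c(0.95, 0.9),
                            couplings = data.frame(source = 1, target = 2,
                                                   gain = 0.4))
  sim <- simulate_mvar_eeg(spec, 5, 250, seed = 7)
  model <- fit_mvaar_kalman(sim$recording$data, p = 2, uc = 1e-3, fs = 250)
  tens <- adtf(model, freqs = 1:50)
  rowsums <- apply(tens, c(1, 3, 4), sum)
  expect_lt(max(abs(rowsums - 1)), 1e-6)
  alpha <- which(attr(tens, "freqs") >= 8 & attr(tens, "freqs") <= 12)
  ratio <- median(tens[2, 1, alpha, ]) / median(tens[1, 2, alpha, ])
  expect_gt(ratio, 5)
})

test_that("an uncoupled model keeps off-diagonal influence small", {
  # closed form: a diagonal coefficient model has a diagonal transfer
  # matrix, so all cross-channel influence is exactly zero
  diag_model <- structure(list(
    A = array(c(diag(3) * 1.2, diag(3) * -0.5), dim = c(3, 3, 2)),
    p = 2, fs = 250, channels = paste0("Ch", 1:3)), class = "var_model")
  tens0 <- adtf(diag_model, freqs = 1:50)
  off <- tens0
  for (i in 1:3) off[i, i, , ] <- 0
  expect_lt(max(off), 1e-12)
  # fitted on uncoupled data: off-diagonal influence stays small after
  # the filter has adapted
  spec <- connectivity_spec(3, osc_freq = c(10, 6, 8), damping = 0.9)
  sim <- simulate_mvar_eeg(spec, 5, 250, seed = 8)
  model <- fit_mvaar_kalman(sim$recording$data, p = 2, uc = 1e-3, fs = 250)
  tens <- adtf(model, freqs = 1:50)
  late <- attr(tens, "times") > 250
  offdiag <- tens[, , , late]
  for (i in 1:3) offdiag[i, i, , ] <- 0
  expect_lt(median(offdiag[offdiag > 0]), 0.1)
})

test_that("pattern definitions follow 10-20 row and side rules", {
  pats <- define_patterns(montage_retained())
  reg <- attr(pats, "regions")
  expect_equal(nrow(pats[["A->P"]]),
               length(reg$anterior) * length(reg$posterior))
  # central row belongs to neither anterior nor posterior
  expect_false(any(c("C3", "Cz", "C4", "CP1") %in%
                   c(reg$anterior)))
  expect_false(any(grepl("z$", c(pats[["L->L"]]$source,
                                 pats[["L->L"]]$target,
                                 pats[["R->L"]]$source))))
  # no self pairs
  expect_false(any(pats[["L->L"]]$source == pats[["L->L"]]$target))
  # shrunken montage drops pairs, does not error
  pats2 <- define_patterns(setdiff(montage_retained(), "O2"))
  expect_lt(nrow(pats2[["P->A"]]), nrow(pats[["P->A"]]))
  expect_error(define_patterns(c("F3", "Qq7x")), "labels")
})

test_that("pattern samples respect thresholds and counting", {
  spec <- connectivity_spec(4, osc_freq = 10, damping = 0.9,
                            labels = c("F3", "F4", "O1", "O2"))
  sim <- simulate_mvar_eeg(spec, 3, 250, seed = 9)
  model <- fit_mvaar_kalman(sim$recording$data, p = 2, uc = 1e-3, fs = 250)
  tens <- adtf(model, freqs = 1:50)
  pats <- define_patterns(c("F3", "F4", "O1", "O2"))
  top <- pattern_samples(tens, "alpha", pats[["R->L"]], threshold = 1)
  expect_length(top$values, 0)
  all_vals <- pattern_samples(tens, "alpha", pats[["R->L"]], threshold = 0)
  expect_length(all_vals$values, all_vals$n_possible)
  counts <- vapply(c(0.1, 0.3, 0.5), function(th) {
    sum(count_strong_connections(tens, "alpha", pats, th)$counts$count)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  c1 <- count_strong_connections(tens, "alpha", pats, 1)
  expect_true(all(c1$counts$count == 0))
})

test_that("a strong single coupling dominates connection counts", {
  spec <- connectivity_spec(4, osc_freq = 10, damping = c(0.95, 0.9, 0.9, 0.9),
                            couplings = data.frame(source = 1, target = 3,
                                                   gain = 0.4),
                            labels = c("O2", "O1", "F3", "F4"))
  sim <- simulate_mvar_eeg(spec, 4, 250, seed = 10)
  model <- fit_mvaar_kalman(sim$recording$data, p = 2, uc = 1e-3, fs = 250)
  tens <- adtf(model, freqs = 1:50)
  pats <- define_patterns(c("O2", "O1", "F3", "F4"))
  cnt <- count_strong_connections(tens, "alpha", pats["R->L"], 0.3)
  d <- cnt$counts
  expect_equal(d$source[which.max(d$count)], "O2")
  expect_equal(d$target[which.max(d$count)], "F3")
  expect_equal(unname(cnt$top_source[["R->L"]]), "O2")
})

test_that("timecourses have one value per window and flag active spans", {
  labels <- c("F3", "F4", "O1", "O2")
  spec <- connectivity_spec(4, osc_freq = 10, damping = 0.9,
                            couplings = data.frame(source = 4, target = 1,
                                                   gain = 0.45, onset = 1,
                                                   offset = 3),
                            labels = labels)
  sim <- simulate_mvar_eeg(spec, 5, 250, seed = 11)
  model <- fit_mvaar_kalman(sim$recording$data, p = 2, uc = 1e-2, fs = 250)
  tens <- adtf(model, freqs = 8:12, t_stride = 5)
  pats <- define_patterns(labels)
  tc <- pattern_timecourse(tens, "alpha", pats["R->L"], window = 1)
  expect_equal(nrow(tc), 5)
  expect_equal(tc$window, 1:5)
  active <- tc$mean[tc$window %in% 2:3]
  expect_gt(mean(active), mean(tc$mean[tc$window == 5]))
})

test_that("condition comparisons behave under null and boosted couplings", {
  null_rep <- condition_contrast_replicate(seed = 1, n_epochs = 6)
  expect_true(null_rep$p > 0 && null_rep$p <= 1)
  boosted <- condition_contrast_replicate(seed = 2, n_epochs = 8,
                                          boost = 0.3)
  expect_lt(boosted$p, 0.05)
  same <- compare_conditions(c(0.4, 0.5, 0.6), c(0.4, 0.5, 0.6))
  expect_equal(same$median_viewing, same$median_baseline)
  empty <- compare_conditions(numeric(0), c(0.5))
  expect_false(empty$comparable)
})

test_that("group contrasts detect global gain differences and not nulls", {
  make_group <- function(gain, seed) {
    r <- condition_contrast_replicate(seed = seed, n_epochs = 10,
                                      boost = gain)
    list("R->L" = r$viewing)
  }
  high <- make_group(0.35, 3)
  low <- make_group(0, 4)
  gc <- group_contrast(list(high = high, low = low))
  expect_lt(gc$p[gc$pattern == "R->L"], 0.05)
  expect_gt(gc$median_1, gc$median_2)
  # permuted assignment destroys the effect
  pooled <- c(high[["R->L"]], low[["R->L"]])
  perm <- withr::with_seed(6, sample(pooled))
  gp <- group_contrast(list(a = list("R->L" = perm[1:10]),
                            b = list("R->L" = perm[11:20])))
  expect_gt(gp$p, 0.05)
  solo <- group_contrast(list(a = list("R->L" = 0.5),
                              b = list("R->L" = c(0.4, 0.6))))
  expect_true(solo$descriptive_only)
})
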