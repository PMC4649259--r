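# Shared fixtures, built in code at test time.

# a recording whose channels share a strong common rhythm (referential
# EEG-like correlation structure), with optional independent-noise channels
make_correlated_recording <- function(n_channels = 8, secs = 10, fs = 250,
                                      noise_channels = integer(0), seed = 11) {
  withr::with_seed(seed, {
    t <- seq_len(secs * fs) / fs
    common <- 20 * sin(2 * pi * 10 * t) + 10 * sin(2 * pi * 6 * t + 1)
    x <- t(vapply(seq_len(n_channels), function(i) {
      common + rnorm(length(t), sd = 4)
    }, numeric(length(t))))
    for (i in noise_channels) x[i, ] <- rnorm(length(t), sd = 20)
    recording(x, paste0("Ch", seq_len(n_channels)), fs)
  })
}

# three well-separated Gaussian blobs in 2-D
make_blobs <- function(n_per = 50, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(cbind(rnorm(n_per, 0), rnorm(n_per, 0)),
               cbind(rnorm(n_per, 6), rnorm(n_per, 6)),
               cbind(rnorm(n_per, 0), rnorm(n_per, 12)))
    list(x = x, labels = rep(1:3, each = n_per))
  })
}

# tiny session spec used across pipeline-level tests
tiny_session_spec <- function(subject = "s1", seed = 1,
                              classes = c("complex", "moderate", "moderate")) {
  session_spec(subject,
               pieces = data.frame(piece = seq_along(classes),
                                   class = classes, duration = 6),
               baseline_s = 12, fs = 250, seed = seed)
}

# solid RGB image on the 0..255 scale
solid_image <- function(r, g, b, size = 64) {
  img <- array(0, dim = c(size, size, 3))
  img[, , 1] <- r; img[, , 2] <- g; img[, , 3] <- b
  img
}
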