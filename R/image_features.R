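# Stimulus image complexity features and class assignment.

# ITU-601 luma weights used to grayscale RGB stimulus images.
LUMA_WEIGHTS <- c(R = 0.299, G = 0.587, B = 0.114)

rgb_to_luminance <- function(img) {
  if (length(dim(img)) != 3 || dim(img)[3] != 3) {
    stop("8-bit RGB input required (H x W x 3)")
  }
  LUMA_WEIGHTS["R"] * img[, , 1] + LUMA_WEIGHTS["G"] * img[, , 2] +
    LUMA_WEIGHTS["B"] * img[, , 3]
}

#' Luminance statistics of an RGB image
#'
#' Grayscales with the standard luma weights (0.299, 0.587, 0.114), then
#' computes mean, standard deviation, kurtosis, skewness, and the fraction
#' of dark pixels (luminance below 64 on the 0..255 scale).
#'
#' @param img numeric array H x W x 3 with values in `[0, 255]`.
#' @param dark_cutoff intensity below which a pixel counts as dark.
#' @return named numeric vector of 5 statistics.
#' @export
luminance_features <- function(img, dark_cutoff = 64) {
  Y <- rgb_to_luminance(img)
  c(lum_mean = mean(Y), lum_sd = stats::sd(Y),
    lum_kurtosis = e1071::kurtosis(as.vector(Y)),
    lum_skewness = e1071::skewness(as.vector(Y)),
    dark_fraction = mean(Y < dark_cutoff))
}

# replicate image edges by r rows / c columns (avoids spurious responses
# at the zero-padding boundary of FFT convolution)
pad_replicate <- function(img, r, c) {
  img <- img[c(rep(1, r), seq_len(nrow(img)), rep(nrow(img), r)), , drop = FALSE]
  img[, c(rep(1, c), seq_len(ncol(img)), rep(ncol(img), c)), drop = FALSE]
}

# 2-D "same" convolution with edge replication via FFT (complex kernels)
conv2_edge <- function(img, kern) {
  r0 <- (nrow(kern) - 1) %/% 2; c0 <- (ncol(kern) - 1) %/% 2
  padded <- pad_replicate(img, r0, c0)
  full <- conv2_same(padded, kern)
  full[(r0 + 1):(r0 + nrow(img)), (c0 + 1):(c0 + ncol(img)), drop = FALSE]
}

# 2-D "same" convolution via FFT (complex kernels allowed)
conv2_same <- function(img, kern) {
  ni <- dim(img); nk <- dim(kern)
  n1 <- ni[1] + nk[1] - 1; n2 <- ni[2] + nk[2] - 1
  pi_ <- matrix(0, n1, n2); pk <- matrix(0 + 0i, n1, n2)
  pi_[seq_len(ni[1]), seq_len(ni[2])] <- img
  pk[seq_len(nk[1]), seq_len(nk[2])] <- kern
  full <- stats::fft(stats::fft(pi_) * stats::fft(pk), inverse = TRUE) /
    (n1 * n2)
  r0 <- (nk[1] - 1) %/% 2; c0 <- (nk[2] - 1) %/% 2
  full[(r0 + 1):(r0 + ni[1]), (c0 + 1):(c0 + ni[2])]
}

gabor_kernel <- function(wavelength, theta, sigma = 0.56 * wavelength) {
  half <- ceiling(2.5 * sigma)
  g <- seq(-half, half)
  X <- matrix(g, length(g), length(g), byrow = TRUE)
  Y <- matrix(g, length(g), length(g))
  xr <- X * cos(theta) + Y * sin(theta)
  yr <- -X * sin(theta) + Y * cos(theta)
  env <- exp(-(xr^2 + yr^2) / (2 * sigma^2))
  kern <- env * exp(1i * 2 * pi * xr / wavelength)
  # remove DC response so constant images map to zero
  kern - env * sum(Re(kern)) / sum(env)
}

#' Gabor-bank texture features
#'
#' Filters the grayscale image with a bank of complex Gabor filters (4
#' dyadic scales x 4 orientations: 0, 45, 90, 135 degrees) and returns the
#' mean and variance of the response magnitudes per filter.
#'
#' @param img numeric array H x W x 3 in `[0, 255]`.
#' @param wavelengths filter wavelengths in pixels.
#' @param orientations filter orientations in radians.
#' @return named numeric vector of `2 * scales * orientations` values.
#' @export
gabor_texture_features <- function(img, wavelengths = c(4, 8, 16, 32),
                                   orientations = pi * (0:3) / 4) {
  Y <- rgb_to_luminance(img)
  out <- numeric(0)
  for (si in seq_along(wavelengths)) {
    for (oi in seq_along(orientations)) {
      kern <- gabor_kernel(wavelengths[si], orientations[oi])
      if (any(dim(kern) > dim(Y))) stop("image smaller than filter support")
      mag <- Mod(conv2_edge(Y, kern))
      nm <- sprintf("gabor_s%d_o%d", si, oi)
      out <- c(out, stats::setNames(c(mean(mag), stats::var(as.vector(mag))),
                                    paste0(nm, c("_mean", "_var"))))
    }
  }
  out
}

#' Gradient-magnitude features
#'
#' Finite-difference intensity gradient map (central differences by
#' default, Sobel optionally) summarized by mean and standard deviation.
#'
#' @param img numeric array H x W x 3 in `[0, 255]`.
#' @param operator `"central"` or `"sobel"`.
#' @return named numeric vector `(grad_mean, grad_sd)`.
#' @export
gradient_features <- function(img, operator = c("central", "sobel")) {
  operator <- match.arg(operator)
  Y <- rgb_to_luminance(img)
  if (operator == "central") {
    gx <- (cbind(Y[, -1], Y[, ncol(Y)]) - cbind(Y[, 1], Y[, -ncol(Y)])) / 2
    gy <- (rbind(Y[-1, ], Y[nrow(Y), ]) - rbind(Y[1, ], Y[-nrow(Y), ])) / 2
  } else {
    sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
    gx <- Re(conv2_same(Y, sx))
    gy <- Re(conv2_same(Y, t(sx)))
  }
  gm <- sqrt(gx^2 + gy^2)
  c(grad_mean = mean(gm), grad_sd = stats::sd(gm))
}

#' Composite block features
#'
#' Splits the grayscale image into `n_blocks` equal blocks and returns each
#' block's mean gray level minus the global mean gray level. Invariant to
#' global additive brightness changes.
#'
#' @param img numeric array H x W x 3 in `[0, 255]`.
#' @param n_blocks number of blocks; factored into the most square grid
#'   (16 gives 4 x 4). The image is cropped to divisible dimensions.
#' @return named numeric vector of `n_blocks` deviations.
#' @export
composite_block_features <- function(img, n_blocks = 16) {
  Y <- rgb_to_luminance(img)
  if (n_blocks > length(Y)) stop("more blocks than pixels")
  nr <- max(Filter(function(d) n_blocks %% d == 0,
                   seq_len(floor(sqrt(n_blocks)))))
  nc <- n_blocks / nr
  h <- (nrow(Y) %/% nr) * nr; w <- (ncol(Y) %/% nc) * nc
  Y <- Y[seq_len(h), seq_len(w), drop = FALSE]
  g <- mean(Y)
  out <- numeric(n_blocks)
  bh <- h / nr; bw <- w / nc
  k <- 1
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      blk <- Y[((r - 1) * bh + 1):(r * bh), ((cc - 1) * bw + 1):(cc * bw)]
      out[k] <- mean(blk) - g
      k <- k + 1
    }
  }
  stats::setNames(out, sprintf("block_%02d", seq_len(n_blocks)))
}

#' Full image feature vector
#'
#' Concatenates luminance, Gabor texture, gradient and composite block
#' features.
#'
#' @inheritParams luminance_features
#' @return named numeric vector (55 values with defaults).
#' @export
image_features <- function(img) {
  c(luminance_features(img), gabor_texture_features(img),
    gradient_features(img), composite_block_features(img))
}

cosine_dist <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  nrm[nrm == 0] <- 1
  s <- (x / nrm) %*% t(x / nrm)
  stats::as.dist(1 - s)
}

#' Assign complexity classes by hierarchical clustering of image features
#'
#' Features are z-scored, hierarchically clustered with average linkage on
#' cosine distance, and the tree cut into three groups. The group holding
#' the blank-wall image is labeled `baseline`; the remaining two are
#' labeled by mean luminance spread (higher SD is `complex`).
#'
#' @param features matrix of image feature vectors (rows = images, named),
#'   e.g. from [image_features()]; must include a `lum_sd` column.
#' @param baseline row name or index of the blank-wall image; default: the
#'   image with the lowest luminance SD.
#' @return a `complexity_classes` object: per-image labels, the linkage
#'   tree, and the metric name.
#' @export
cluster_images <- function(features, baseline = NULL) {
  features <- as.matrix(features)
  if (nrow(features) < 3) stop("need at least 3 images")
  if (nrow(unique(features)) < 3) {
    stop("images collapse into fewer than 3 groups; features too similar")
  }
  if (is.null(rownames(features))) {
    rownames(features) <- paste0("img_", seq_len(nrow(features)))
  }
  if (is.null(baseline)) baseline <- which.min(features[, "lum_sd"])
  if (is.character(baseline)) baseline <- match(baseline, rownames(features))
  z <- zscore_cols(features)
  tree <- stats::hclust(cosine_dist(z), method = "average")
  cut <- stats::cutree(tree, k = 3)
  if (length(unique(cut)) < 3) {
    stop("images collapse into fewer than 3 groups; features too similar")
  }
  base_grp <- cut[baseline]
  rest <- setdiff(unique(cut), base_grp)
  msd <- vapply(rest, function(g) mean(features[cut == g, "lum_sd"]),
                numeric(1))
  labels <- character(nrow(features))
  labels[cut == base_grp] <- "baseline"
  labels[cut == rest[which.max(msd)]] <- "complex"
  labels[cut == rest[which.min(msd)]] <- "moderate"
  structure(list(labels = stats::setNames(labels, rownames(features)),
                 tree = tree, metric = "cosine"),
            class = "complexity_classes")
}

#' @export
print.complexity_classes <- function(x, ...) {
  cat("<complexity_classes>\n")
  print(table(x$labels))
  invisible(x)
}
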