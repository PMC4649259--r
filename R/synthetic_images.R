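# Synthetic stimulus images with controlled visual complexity.
# Images are H x W x 3 arrays on the 0..255 intensity scale.

#' Generate a synthetic stimulus image of a given complexity class
#'
#' * `complex`: dense multi-orientation gratings plus broadband noise,
#'   stretched over the full intensity range (broad luminance spread, many
#'   dark pixels).
#' * `moderate`: a few smooth low-contrast blobs on a mid-gray field.
#' * `baseline`: a near-uniform bright field with slight sensor noise,
#'   emulating a blank white wall (no dark pixels).
#'
#' @param class_label `"complex"`, `"moderate"` or `"baseline"`.
#' @param size image side in pixels (square), at least 64.
#' @param seed integer; identical seeds give identical images.
#' @return numeric array `size x size x 3` with values in `[0, 255]`.
#' @export
generate_synthetic_images <- function(class_label = c("complex", "moderate",
                                                      "baseline"),
                                      size = 128, seed = 1) {
  class_label <- match.arg(class_label)
  if (size < 64) stop("size must be at least 64x64")
  with_seed(seed, {
    xy <- seq_len(size)
    X <- matrix(xy, size, size, byrow = TRUE)
    Y <- matrix(xy, size, size)
    base <- switch(class_label,
      baseline = {
        235 + matrix(stats::rnorm(size^2, sd = 3), size, size)
      },
      moderate = {
        # a consistent composition (fixed blob layout) with per-image
        # variation in amplitude and slight positional jitter, so the
        # class is coherent in feature space
        img <- matrix(160, size, size)
        layout <- cbind(x = c(0.30, 0.70, 0.40, 0.65),
                        y = c(0.30, 0.40, 0.70, 0.72),
                        sign = c(1, -1, 1, -1))
        for (b in 1:4) {
          cx <- (layout[b, "x"] + stats::runif(1, -0.04, 0.04)) * size
          cy <- (layout[b, "y"] + stats::runif(1, -0.04, 0.04)) * size
          sg <- 0.12 * size
          amp <- layout[b, "sign"] * stats::runif(1, 30, 45)
          img <- img + amp * exp(-((X - cx)^2 + (Y - cy)^2) / (2 * sg^2))
        }
        img + matrix(stats::rnorm(size^2, sd = 2), size, size)
      },
      complex = {
        img <- matrix(0, size, size)
        for (g in 1:6) {
          th <- stats::runif(1, 0, pi)
          fr <- stats::runif(1, 2, 16) / size
          ph <- stats::runif(1, 0, 2 * pi)
          img <- img + sin(2 * pi * fr * (X * cos(th) + Y * sin(th)) + ph)
        }
        img <- img + matrix(stats::rnorm(size^2, sd = 1.2), size, size)
        # stretch to full range
        127.5 + 127.5 * img / max(abs(img)) * 1.6
      })
    base <- pmin(255, pmax(0, base))
    rgb_mix <- switch(class_label,
      baseline = c(1.00, 1.00, 0.98),
      moderate = c(1.02, 1.00, 0.95),
      complex = c(1.05, 1.00, 0.90))
    img <- array(0, dim = c(size, size, 3))
    for (k in 1:3) img[, , k] <- pmin(255, pmax(0, base * rgb_mix[k]))
    img
  })
}

#' Read an image file as a 0..255 RGB array
#'
#' Supports PNG (always) and TIFF (if the `tiff` package is installed).
#' Grayscale input is replicated across channels; alpha is dropped.
#'
#' @param path image path.
#' @return numeric array H x W x 3, values in `[0, 255]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the 'tiff' package")
      }
      tiff::readTIFF(path)
    },
    jpg = , jpeg = stop("JPEG input is not supported; convert to PNG"),
    stop("unsupported image format: ", ext))
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' Write a 0..255 RGB array as PNG
#' @param img array H x W x 3, values in `[0, 255]`.
#' @param path output path.
#' @export
write_image <- function(img, path) {
  png::writePNG(img / 255, path)
  invisible(path)
}
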