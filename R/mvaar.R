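# Time-varying multivariate autoregressive modelling.
#
# The MVAAR model  X(t) = sum_k Lambda(k, t) X(t-k) + E(t)  is tracked with
# a Kalman filter over the vectorized coefficients under a random-walk
# state model. All target channels share the regressor vector
# z_t = [X(t-1); ...; X(t-p)] and a scalar innovation variance, so a single
# state-covariance recursion serves every channel; this keeps 20-channel
# fits tractable while leaving per-channel coefficient paths free.

#' Fit a Kalman-filtered time-varying VAR (MVAAR) model
#'
#' @param x channels x samples matrix (a cleaned epoch), or a
#'   [recording()].
#' @param p model order (lags).
#' @param uc update coefficient: relative random-walk state noise added per
#'   step (scales the mean diagonal of the state covariance).
#' @param fs sampling rate in Hz (taken from the recording if given).
#' @return an `mvaar_model`: coefficient array `A[target, source, lag, t]`,
#'   innovation variance path, order, `fs`.
#' @export
fit_mvaar_kalman <- function(x, p = 5, uc = 1e-3, fs = NULL) {
  if (inherits(x, "recording")) { fs <- x$fs; x <- x$data }
  if (is.null(fs)) stop("fs required")
  x <- as.matrix(x)
  n <- nrow(x); total <- ncol(x)
  if (n < 2) stop("need at least 2 channels")
  if (total <= 10 * p) stop("epoch too short for order ", p)
  # standardize channels so the shared innovation variance weighs every
  # channel equally; coefficients are rescaled back on output
  sc <- apply(x, 1, stats::sd)
  sc[sc == 0] <- 1
  labels <- rownames(x)
  x <- x / sc
  d <- n * p
  Theta <- matrix(0, d, n)
  P <- 100 * diag(d)   # diffuse start: early steps behave like least squares
  v <- 1
  A <- array(0, dim = c(n, n, p, total))
  vpath <- numeric(total)
  lagidx <- function(t) as.vector(vapply(seq_len(p), function(k) x[, t - k],
                                         numeric(n)))
  for (t in (p + 1):total) {
    z <- lagidx(t)
    e <- x[, t] - as.vector(crossprod(Theta, z))
    v <- 0.99 * v + 0.01 * mean(e^2)
    q <- uc * mean(diag(P))
    diag(P) <- diag(P) + q
    Pz <- P %*% z
    s <- sum(z * Pz) + v
    if (!is.finite(s) || s <= 0) {
      stop(sprintf("Kalman filter diverged at sample %d (s = %g, v = %g)",
                   t, s, v))
    }
    K <- Pz / s
    Theta <- Theta + K %*% t(e)
    P <- P - tcrossprod(K, Pz)
    for (k in seq_len(p)) {
      # undo standardization: Lambda_ij scales by s_i / s_j
      A[, , k, t] <- t(Theta[((k - 1) * n + 1):(k * n), , drop = FALSE]) *
        outer(sc, 1 / sc)
    }
    vpath[t] <- v
  }
  # coefficients are undefined for the first p samples; hold the first
  # estimate backwards so the time axis aligns with the input
  for (t in seq_len(p)) A[, , , t] <- A[, , , p + 1]
  if (!all(is.finite(A))) stop("Kalman filter produced non-finite coefficients")
  structure(list(A = A, p = p, fs = fs, uc = uc, innovation_var = vpath,
                 channels = labels %||% paste0("Ch", seq_len(n))),
            class = "mvaar_model")
}

#' @export
print.mvaar_model <- function(x, ...) {
  d <- dim(x$A)
  cat(sprintf("<mvaar_model> %d channels, order %d, %d samples @ %g Hz, uc %g\n",
              d[1], x$p, d[4], x$fs, x$uc))
  invisible(x)
}

#' Time-averaged coefficient matrices of an MVAAR model
#'
#' Averages the coefficient path over time after discarding an initial
#' burn-in (the filter's adaptation phase).
#'
#' @param model an `mvaar_model`.
#' @param burn fraction of samples discarded from the start.
#' @return array `n x n x p`.
#' @export
mvaar_mean_coefficients <- function(model, burn = 0.2) {
  total <- dim(model$A)[4]
  keep <- (max(model$p, floor(burn * total)) + 1):total
  apply(model$A[, , , keep, drop = FALSE], c(1, 2, 3), mean)
}

#' Ordinary least-squares VAR fit (stationary)
#'
#' Standard OLS estimate of a time-invariant VAR(p); the stationary
#' comparator for the Kalman-filtered model.
#'
#' @inheritParams fit_mvaar_kalman
#' @return a `var_model`: list with coefficient array `A[target, source,
#'   lag]` and innovation covariance `sigma`.
#' @export
fit_var_ls <- function(x, p = 2, fs = NULL) {
  if (inherits(x, "recording")) { fs <- x$fs; x <- x$data }
  x <- as.matrix(x)
  n <- nrow(x); total <- ncol(x)
  if (total <= n * p + p) stop("too few samples for OLS VAR")
  Y <- t(x[, (p + 1):total, drop = FALSE])
  Z <- do.call(cbind, lapply(seq_len(p), function(k) {
    t(x[, (p + 1 - k):(total - k), drop = FALSE])
  }))
  B <- solve(crossprod(Z), crossprod(Z, Y))   # (n*p) x n
  A <- array(0, dim = c(n, n, p))
  for (k in seq_len(p)) {
    A[, , k] <- t(B[((k - 1) * n + 1):(k * n), , drop = FALSE])
  }
  resid <- Y - Z %*% B
  structure(list(A = A, sigma = stats::cov(resid), p = p, fs = fs,
                 channels = rownames(x) %||% paste0("Ch", seq_len(n))),
            class = "var_model")
}
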