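# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators never disturb the global stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible child seed from a parent seed and a stream index,
# staying below .Machine$integer.max.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + as.numeric(stream) * 1299709) %% 2147483629
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Shannon entropy (bits) of a non-negative weight vector, normalized to
# probabilities. Zero weights contribute nothing; all-zero input -> 0.
shannon_entropy <- function(w) {
  w <- w[w > 0]
  if (!length(w)) return(0)
  p <- w / sum(w)
  -sum(p * log2(p))
}

# z-score columns of a matrix; zero-variance columns map to 0.
zscore_cols <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  scale(x, center = mu, scale = sdv)[, , drop = FALSE]
}

stopifnot_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
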