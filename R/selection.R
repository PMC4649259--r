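# Minimum-redundancy maximum-relevance (mRMR) feature ranking.
#
# Features are discretized into 3 levels at mean +/- SD; mutual information
# is computed from contingency tables; ranking is greedy on the difference
# criterion (relevance minus mean redundancy with already-selected
# features). Deterministic given the discretization.

# 3-level discretization at mean +/- sd
discretize3 <- function(v) {
  m <- mean(v); s <- stats::sd(v)
  if (!is.finite(s) || s == 0) return(rep(1L, length(v)))
  cut(v, breaks = c(-Inf, m - s, m + s, Inf), labels = FALSE)
}

# mutual information (bits) between two discrete vectors
mutual_information <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  pj <- tab / n
  pa <- rowSums(pj); pb <- colSums(pj)
  keep <- pj > 0
  sum(pj[keep] * log2(pj[keep] / outer(pa, pb)[keep]))
}

#' mRMR feature ranking
#'
#' Greedy ranking maximizing mutual information with the class labels while
#' penalizing mean mutual information with already-selected features
#' (difference criterion).
#'
#' @param table a `feature_table` or numeric matrix (columns = features).
#' @param labels class label per row (ignored if `table` is a
#'   `feature_table` with a complete `class` column and `labels` is NULL).
#' @param k number of features to rank (default 50).
#' @return a `feature_ranking`: `data.frame` with `feature`, `score`,
#'   `relevance`, `redundancy`, in selection order; feature metadata kept
#'   as the `feature_info` attribute when available.
#' @export
mrmr_select <- function(table, labels = NULL, k = 50) {
  info <- NULL
  if (inherits(table, "feature_table")) {
    info <- feature_info(table)
    if (is.null(labels)) labels <- table$class
    x <- feature_matrix(table)
  } else {
    x <- as.matrix(table)
    if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  }
  if (is.null(labels) || anyNA(labels)) stop("class labels required")
  if (length(unique(labels)) < 2) stop("need at least 2 classes")
  if (k > ncol(x)) stop("k exceeds feature count")
  disc <- apply(x, 2, discretize3)
  rel <- apply(disc, 2, mutual_information, b = labels)
  selected <- integer(0)
  red_cache <- matrix(NA_real_, ncol(x), ncol(x))
  score <- red <- numeric(k)
  remaining <- seq_len(ncol(x))
  for (step in seq_len(k)) {
    if (!length(selected)) {
      redv <- rep(0, length(remaining))
    } else {
      last <- selected[length(selected)]
      for (j in remaining) {
        if (is.na(red_cache[last, j])) {
          red_cache[last, j] <- mutual_information(disc[, last], disc[, j])
        }
      }
      redv <- colMeans(red_cache[selected, remaining, drop = FALSE])
    }
    sc <- rel[remaining] - redv
    pick <- which.max(sc)
    score[step] <- sc[pick]; red[step] <- redv[pick]
    selected <- c(selected, remaining[pick])
    remaining <- remaining[-pick]
  }
  out <- data.frame(feature = colnames(x)[selected], score = score,
                    relevance = rel[selected], redundancy = red,
                    row.names = NULL)
  structure(out, k = k, feature_info = info,
            class = c("feature_ranking", "data.frame"))
}

#' Per-channel and per-band share of the top-ranked features
#'
#' @param ranking a [mrmr_select()] result with feature metadata.
#' @param k consider the first `k` ranked features (default: the ranking's
#'   own cut).
#' @return list with `channel_pct` (sums to 100) and `band_pct`
#'   (broadband features excluded; sums to 100 when any band-specific
#'   feature is in the top-k).
#' @export
importance_summary <- function(ranking, k = attr(ranking, "k")) {
  info <- attr(ranking, "feature_info")
  if (is.null(info)) stop("ranking carries no feature metadata")
  top <- utils::head(ranking$feature, k)
  meta <- info[match(top, info$name), ]
  channels <- sort(unique(info$channel))
  ch <- table(factor(meta$channel, levels = channels))
  channel_pct <- 100 * as.numeric(ch) / length(top)
  names(channel_pct) <- channels
  bands <- setdiff(sort(unique(info$band)), "broadband")
  bmeta <- meta[meta$band != "broadband", ]
  bd <- table(factor(bmeta$band, levels = bands))
  band_pct <- if (nrow(bmeta)) 100 * as.numeric(bd) / nrow(bmeta)
              else rep(0, length(bands))
  names(band_pct) <- bands
  list(channel_pct = channel_pct, band_pct = band_pct, k = length(top))
}
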