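# Unsupervised extreme-learning-machine embedding and clustering.
#
# A random sigmoid hidden layer with orthonormalized input weights maps
# z-scored features to H; output weights solve the graph-Laplacian-
# regularized generalized eigenproblem
#     (I + lambda * H' L H) v = gamma * H' H v,
# taking the eigenvectors of the 2nd..(n_dim+1)th smallest eigenvalues,
# each normalized so that ||H v|| = 1. The embedding is H %*% V.

#' Unsupervised ELM embedding
#'
#' @param x numeric matrix (observations x features) or `feature_table`.
#' @param n_dim embedding dimensions (number of eigenvectors retained).
#' @param n_hidden hidden-layer width.
#' @param k_neighbors neighbors for the affinity graph.
#' @param lambda graph-regularization weight.
#' @param sigma heat-kernel width; default median pairwise distance.
#' @param seed integer seed for the random hidden layer.
#' @param graph optional precomputed [uselm_graph()]; saves the O(n^2)
#'   neighbor search when embedding the same data repeatedly.
#' @return an `uselm_embedding`: list with `points` (N x n_dim), the model
#'   (`W`, `bias`, `V`) and graph parameters.
#' @export
uselm_embed <- function(x, n_dim = 2, n_hidden = 200, k_neighbors = 7,
                        lambda = 1, sigma = NULL, seed = 1, graph = NULL) {
  if (inherits(x, "feature_table")) x <- feature_matrix(x)
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (n < n_dim + 1) stop("need at least n_dim + 1 observations")
  z <- zscore_cols(x)
  # keep the hidden layer narrower than the sample count so the
  # generalized eigenproblem in hidden space stays well conditioned
  # (but wide enough to supply n_dim + 1 eigenvectors)
  n_hidden <- max(min(n_hidden, n - 1), n_dim + 1)
  if (is.null(graph)) graph <- uselm_graph(z, k_neighbors, sigma)
  L <- graph$L
  sigma <- graph$sigma
  kk <- graph$k
  with_seed(seed, {
    R <- matrix(stats::rnorm(max(n_hidden, d) * min(n_hidden, d)),
                max(n_hidden, d), min(n_hidden, d))
    Q <- qr.Q(qr(R))
    W <- if (n_hidden >= d) t(Q) else Q   # d x n_hidden, orthonormal on the short side
    bias <- stats::runif(n_hidden, -1, 1)
  })
  H <- sigmoid(sweep(z %*% W, 2, bias, `+`))
  gen_eig_smallest <- function(A, B, m) {
    Rb <- chol(B)
    M <- backsolve(Rb, t(backsolve(Rb, t(A), transpose = TRUE)),
                   transpose = TRUE)
    M <- (M + t(M)) / 2
    ev <- eigen(M, symmetric = TRUE)
    idx <- rev(seq_len(ncol(B)))[seq_len(m)]   # smallest first
    backsolve(Rb, ev$vectors[, idx, drop = FALSE])
  }
  A <- diag(n_hidden) + lambda * crossprod(H, L %*% H)
  B <- crossprod(H) + 1e-8 * diag(n_hidden)
  V <- gen_eig_smallest(A, B, n_dim + 1)[, -1, drop = FALSE]
  for (j in seq_len(ncol(V))) {
    nrm <- sqrt(sum((H %*% V[, j])^2))
    if (nrm > 0) V[, j] <- V[, j] / nrm
  }
  structure(list(points = H %*% V, W = W, bias = bias, V = V,
                 n_dim = n_dim, k_neighbors = kk, lambda = lambda,
                 sigma = sigma, center = attr(z, "scaled:center"),
                 scale = attr(z, "scaled:scale")),
            class = "uselm_embedding")
}

#' Affinity graph Laplacian for US-ELM
#'
#' Symmetrized kNN graph with heat-kernel weights on already-standardized
#' data; the width defaults to the median pairwise distance.
#'
#' @param z standardized observation matrix.
#' @param k_neighbors neighbors per observation.
#' @param sigma heat-kernel width (default median pairwise distance).
#' @return list with `L` (unnormalized Laplacian), `sigma`, `k`.
#' @export
uselm_graph <- function(z, k_neighbors = 7, sigma = NULL) {
  n <- nrow(z)
  dmat <- as.matrix(stats::dist(z))
  if (is.null(sigma)) sigma <- stats::median(dmat[upper.tri(dmat)])
  if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  S <- matrix(0, n, n)
  kk <- min(k_neighbors, n - 1)
  for (i in seq_len(n)) {
    nb <- order(dmat[i, ])[2:(kk + 1)]
    S[i, nb] <- exp(-dmat[i, nb]^2 / (2 * sigma^2))
  }
  S <- pmax(S, t(S))
  if (graph_components(S > 0) > 1) {
    warning("kNN graph is disconnected; regularization bridges components")
  }
  list(L = diag(rowSums(S)) - S, sigma = sigma, k = kk)
}

# number of connected components of a logical adjacency matrix
graph_components <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n); comps <- 0
  for (s in seq_len(n)) {
    if (seen[s]) next
    comps <- comps + 1
    queue <- s
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      queue <- c(queue, which(adj[v, ] & !seen))
    }
  }
  comps
}

#' Cluster an embedding with a Gaussian mixture or k-means
#'
#' @param embedding an [uselm_embed()] result or numeric matrix.
#' @importFrom mclust Mclust mclustBIC
#' @param method `"gmm"` (full-covariance Gaussian mixture, fitted by
#'   mclust) or `"kmeans"` (multiple restarts, best inertia).
#' @param n_classes number of clusters.
#' @param seed integer seed.
#' @return a `cluster_result`: list with `assignment`, `method`,
#'   `n_classes`.
#' @export
cluster_embedding <- function(embedding, method = c("gmm", "kmeans"),
                              n_classes = 3, seed = 1) {
  method <- match.arg(method)
  pts <- if (inherits(embedding, "uselm_embedding")) embedding$points
         else as.matrix(embedding)
  if (nrow(pts) < n_classes) stop("fewer observations than clusters")
  if (n_classes == 1) {
    return(structure(list(assignment = rep(1L, nrow(pts)), method = method,
                          n_classes = 1L), class = "cluster_result"))
  }
  assignment <- with_seed(seed, {
    if (method == "gmm") {
      fit <- NULL
      for (mn in list("VVV", c("VVI", "VII"), "EII")) {
        fit <- suppressWarnings(
          mclust::Mclust(pts, G = n_classes, modelNames = mn,
                         verbose = FALSE))
        if (!is.null(fit) && !is.null(fit$classification)) break
      }
      if (is.null(fit)) stop("GMM failed on all covariance families")
      as.integer(fit$classification)
    } else {
      stats::kmeans(pts, centers = n_classes, nstart = 10,
                    iter.max = 200)$cluster
    }
  })
  structure(list(assignment = assignment, method = method,
                 n_classes = as.integer(n_classes)),
            class = "cluster_result")
}

#' Rand index between a clustering and reference labels
#'
#' Plain (unadjusted) Rand index: the fraction of observation pairs on
#' which the two partitions agree (together in both, or apart in both).
#'
#' @param assignment cluster assignment vector.
#' @param labels reference labels, same length.
#' @param adjusted return the adjusted-for-chance version instead.
#' @return accuracy in `[0, 1]`.
#' @export
rand_accuracy <- function(assignment, labels, adjusted = FALSE) {
  if (length(assignment) != length(labels)) stop("length mismatch")
  n <- length(labels)
  if (n < 2) stop("need at least two observations")
  tab <- table(assignment, labels)
  ch2 <- function(v) sum(v * (v - 1) / 2)
  a <- ch2(tab)
  ra <- ch2(rowSums(tab)); cb <- ch2(colSums(tab))
  total <- n * (n - 1) / 2
  if (adjusted) {
    exp_a <- ra * cb / total
    return(as.numeric((a - exp_a) / ((ra + cb) / 2 - exp_a)))
  }
  as.numeric((total + 2 * a - ra - cb) / total)
}

#' Per-observation agreement accuracy (best label matching)
#'
#' Fraction of observations whose cluster matches the reference label under
#' the best one-to-one mapping of cluster ids to labels.
#'
#' @inheritParams rand_accuracy
#' @return accuracy in `[0, 1]`.
#' @export
agreement_accuracy <- function(assignment, labels) {
  tab <- table(assignment, labels)
  k <- max(nrow(tab), ncol(tab))
  m <- matrix(0, k, k)
  m[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  perms <- all_permutations(k)
  best <- 0
  for (p in perms) best <- max(best, sum(m[cbind(seq_len(k), p)]))
  best / length(labels)
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (p in all_permutations(k - 1)) {
      q <- integer(k); q[1] <- i; q[-1] <- setdiff(seq_len(k), i)[p]
      out[[length(out) + 1]] <- q
    }
  }
  out
}

#' Monte-Carlo chance level of random class assignment
#'
#' Draws uniform random assignments against balanced labels and reports the
#' per-observation agreement; converges to 1 / n_classes.
#'
#' @param n observations per replicate.
#' @param n_classes number of classes.
#' @param reps Monte-Carlo replicates.
#' @param seed integer seed.
#' @return list with `mean`, `sd` and the replicate `accuracies`.
#' @export
chance_level <- function(n = 3000, n_classes = 3, reps = 1000, seed = 1) {
  labels <- rep(seq_len(n_classes), length.out = n)
  acc <- with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      mean(sample.int(n_classes, n, replace = TRUE) == labels)
    }, numeric(1))
  })
  list(mean = mean(acc), sd = stats::sd(acc), accuracies = acc)
}

#' Iterated embedding/clustering accuracy search
#'
#' For each parameter configuration, repeats the random-hidden-layer
#' embedding and clustering `n_iter` times and records Rand and agreement
#' accuracy against the reference labels; reports per-configuration
#' distributions, the best configuration, and a one-sample test of the best
#' configuration's agreement accuracy against chance (1 / n_classes).
#'
#' @param x feature matrix or `feature_table` (already reduced, e.g. to the
#'   mRMR top-k).
#' @param labels reference class labels.
#' @param grid `data.frame` of configurations with columns `n_dim`,
#'   `k_neighbors`, `lambda`; default: the package defaults as one row.
#' @param n_iter iterations per configuration.
#' @param method clustering method, `"gmm"` or `"kmeans"`.
#' @param n_classes clusters to fit.
#' @param seed integer seed.
#' @return a `param_search` list: `results` (one row per iteration),
#'   `summary`, `best`, `chance`, `test`.
#' @export
parameter_search <- function(x, labels, grid = NULL, n_iter = 100,
                             method = "gmm", n_classes = 3, seed = 1) {
  if (inherits(x, "feature_table")) {
    if (is.null(labels)) labels <- x$class
    x <- feature_matrix(x)
  }
  if (is.null(grid)) grid <- data.frame(n_dim = 2, k_neighbors = 7, lambda = 1)
  if (!nrow(grid)) stop("empty parameter grid")
  rows <- list()
  z <- zscore_cols(as.matrix(x))
  for (g in seq_len(nrow(grid))) {
    graph <- uselm_graph(z, grid$k_neighbors[g])
    for (it in seq_len(n_iter)) {
      s <- child_seed(seed, g * 100000 + it)
      emb <- uselm_embed(x, n_dim = grid$n_dim[g],
                         k_neighbors = grid$k_neighbors[g],
                         lambda = grid$lambda[g], seed = s, graph = graph)
      cl <- cluster_embedding(emb, method = method, n_classes = n_classes,
                              seed = s)
      rows[[length(rows) + 1]] <- data.frame(
        config = g, iter = it, n_dim = grid$n_dim[g],
        k_neighbors = grid$k_neighbors[g], lambda = grid$lambda[g],
        rand = rand_accuracy(cl$assignment, labels),
        agreement = agreement_accuracy(cl$assignment, labels))
    }
  }
  res <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(res, res$config), function(d) {
    data.frame(config = d$config[1], n_dim = d$n_dim[1],
               k_neighbors = d$k_neighbors[1], lambda = d$lambda[1],
               mean_rand = mean(d$rand), sd_rand = stats::sd(d$rand),
               mean_agreement = mean(d$agreement),
               sd_agreement = stats::sd(d$agreement))
  }))
  best <- summ[which.max(summ$mean_rand), ]
  chance <- 1 / n_classes
  bestacc <- res$agreement[res$config == best$config]
  # signed-rank test tolerates the zero-variance case (perfect recovery
  # in every iteration)
  test <- suppressWarnings(
    stats::wilcox.test(bestacc, mu = chance, alternative = "greater"))
  structure(list(results = res, summary = summ, best = best,
                 chance = chance, test = test), class = "param_search")
}

#' Hierarchical clustergram of subjects
#'
#' Aggregates each subject's standardized features (mean over segments),
#' z-scores per feature across subjects, builds an average-linkage tree and
#' reports the first two-group cut.
#'
#' @param tables a list of per-subject `feature_table`s, or a numeric
#'   matrix subjects x features with rownames.
#' @return list with `tree` (hclust), `groups` (named 2-level cut) and the
#'   subject-by-feature matrix used.
#' @export
subject_clustergram <- function(tables) {
  if (is.list(tables) && !is.matrix(tables)) {
    m <- do.call(rbind, lapply(tables, function(tb) {
      colMeans(feature_matrix(tb))
    }))
    rownames(m) <- vapply(tables, function(tb) as.character(tb$subject[1]),
                          character(1))
  } else {
    m <- as.matrix(tables)
  }
  if (nrow(m) < 4) stop("need at least 4 subjects")
  z <- zscore_cols(m)
  tree <- stats::hclust(stats::dist(z), method = "average")
  groups <- stats::cutree(tree, k = 2)
  list(tree = tree, groups = groups, matrix = m)
}
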