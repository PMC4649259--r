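# independent oracle: greedy mRMR with entropy-based mutual information,
# written with no shared code with the package implementation
oracle_mrmr <- function(x, labels, k) {
  disc <- apply(x, 2, function(v) {
    m <- mean(v); s <- sd(v)
    if (s == 0) return(rep(1L, length(v)))
    findInterval(v, c(m - s, m + s)) + 1L
  })
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  mi <- function(a, b) {
    pj <- table(a, b) / length(a)
    ent(rowSums(pj)) + ent(colSums(pj)) - ent(as.vector(pj))
  }
  rel <- apply(disc, 2, mi, b = labels)
  sel <- integer(0)
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(ncol(x)), sel)
    score <- vapply(cand, function(j) {
      red <- if (length(sel)) mean(vapply(sel, function(s2) {
        mi(disc[, s2], disc[, j])
      }, numeric(1))) else 0
      rel[j] - red
    }, numeric(1))
    sel <- c(sel, cand[which.max(score)])
  }
  colnames(x)[sel]
}

test_that("mRMR matches an exhaustive mutual-information oracle", {
  withr::with_seed(10, {
    n <- 120
    labels <- rep(c("a", "b", "c"), length.out = n)
    eff <- as.numeric(factor(labels))
    x <- cbind(eff * 2 + rnorm(n, sd = 0.5),
               eff * -1.5 + rnorm(n, sd = 0.8),
               matrix(rnorm(n * 8), n, 8))
    x <- cbind(x, x[, 1])   # exact duplicate of col 1
    colnames(x) <- paste0("f", 1:11)
  })
  rk <- mrmr_select(x, labels, k = 11)
  expect_identical(rk$feature, oracle_mrmr(x, labels, 11))
  # informative features rank first; the duplicate is pushed back
  expect_true(all(c("f1", "f2") %in% rk$feature[1:3]))
  expect_gt(match("f11", rk$feature), 3)
  expect_setequal(rk$feature, colnames(x))
})

test_that("mRMR surfaces informative features above noise", {
  withr::with_seed(11, {
    n <- 150
    labels <- rep(1:3, each = 50)
    inf <- vapply(1:10, function(j) labels * runif(1, 1, 2) + rnorm(n),
                  numeric(n))
    noise <- matrix(rnorm(n * 90), n, 90)
    x <- cbind(inf, noise)
    colnames(x) <- c(paste0("inf", 1:10), paste0("noise", 1:90))
  })
  rk <- mrmr_select(x, labels, k = 10)
  expect_gte(sum(startsWith(rk$feature[1:10], "inf")), 8)
  const <- cbind(x, constant = rep(1, nrow(x)))
  rk2 <- mrmr_select(const, labels, k = ncol(const))
  expect_gt(match("constant", rk2$feature), 10)
})

test_that("Rand and agreement accuracies follow pair-counting arithmetic", {
  expect_equal(rand_accuracy(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  # labels {a,a,b,b} vs {x,y,x,y}: only 2 of 6 pairs agree
  expect_equal(rand_accuracy(c("x", "y", "x", "y"), c("a", "a", "b", "b")),
               1 / 3)
  withr::with_seed(12, {
    labs <- sample(1:3, 60, replace = TRUE)
    asg <- sample(1:3, 60, replace = TRUE)
  })
  perm <- c(3, 1, 2)[asg]
  expect_equal(rand_accuracy(asg, labs), rand_accuracy(perm, labs))
  expect_equal(agreement_accuracy(asg, labs), agreement_accuracy(perm, labs))
  expect_equal(agreement_accuracy(c(2, 2, 3, 3, 1), c(1, 1, 2, 2, 3)), 1)
  expect_error(rand_accuracy(1, 1), "two observations")
})

test_that("US-ELM separates Gaussian blobs with orthonormal hidden weights", {
  b <- make_blobs(seed = 21)
  emb <- suppressWarnings(uselm_embed(b$x, n_dim = 2, n_hidden = 100,
                                      seed = 5))
  expect_equal(emb$W %*% t(emb$W), diag(nrow(emb$W)), tolerance = 1e-8)
  p <- emb$points
  gm <- colMeans(p)
  sw <- sum(vapply(1:3, function(g) {
    sum(scale(p[b$labels == g, ], scale = FALSE)^2)
  }, numeric(1)))
  sb <- sum(vapply(1:3, function(g) {
    50 * sum((colMeans(p[b$labels == g, ]) - gm)^2)
  }, numeric(1)))
  expect_gt(sb / sw, 5)
  # duplicated observations embed identically
  dup <- rbind(b$x, b$x[1:5, ])
  embd <- suppressWarnings(uselm_embed(dup, n_dim = 2, n_hidden = 100,
                                       seed = 5))
  expect_equal(embd$points[151:155, ], embd$points[1:5, ], tolerance = 1e-10)
  # boundary: n_dim = observations - 1 on a small set
  small <- b$x[c(1:4, 51:54, 101:104), ]
  embs <- suppressWarnings(uselm_embed(small, n_dim = 11, n_hidden = 50,
                                       seed = 2))
  expect_equal(dim(embs$points), c(12, 11))
})

test_that("clustering the embedding recovers blob structure deterministically", {
  b <- make_blobs(seed = 22)
  emb <- suppressWarnings(uselm_embed(b$x, n_dim = 2, n_hidden = 100,
                                      seed = 7))
  for (method in c("gmm", "kmeans")) {
    cl <- cluster_embedding(emb, method, seed = 3)
    expect_gte(rand_accuracy(cl$assignment, b$labels), 0.95)
    cl2 <- cluster_embedding(emb, method, seed = 3)
    expect_identical(cl$assignment, cl2$assignment)
  }
  one <- cluster_embedding(emb, "kmeans", n_classes = 1)
  expect_true(all(one$assignment == 1))
})

test_that("chance level converges to one third", {
  ch <- chance_level(n = 3000, reps = 200, seed = 4)
  expect_equal(ch$mean, 1 / 3, tolerance = 0.01)
})

test_that("parameter search beats chance on separable data, not on shuffled", {
  b <- make_blobs(n_per = 40, seed = 23)
  ps <- suppressWarnings(parameter_search(b$x, b$labels, n_iter = 8,
                                          method = "kmeans", seed = 6))
  expect_gt(ps$best$mean_agreement, 0.8)
  expect_lt(ps$test$p.value, 0.01)
  shuffled <- withr::with_seed(9, sample(b$labels))
  ps0 <- suppressWarnings(parameter_search(b$x, shuffled, n_iter = 8,
                                           method = "kmeans", seed = 6))
  expect_lt(ps0$best$mean_agreement, 0.45)
  ps1 <- suppressWarnings(parameter_search(b$x, b$labels, n_iter = 1,
                                           method = "kmeans", seed = 6))
  expect_equal(nrow(ps1$results), 1)
})

test_that("importance summaries are percentages over channels and bands", {
  sess <- generate_session(tiny_session_spec(seed = 41))
  pp <- preprocess(sess$recording)
  ft <- build_feature_table(pp$epochs, domain = "time",
                            classes = c(piece_1 = "complex",
                                        piece_2 = "moderate",
                                        piece_3 = "moderate"))
  rk <- mrmr_select(ft, k = 50)
  imp <- importance_summary(rk)
  expect_equal(sum(imp$channel_pct), 100)
  expect_equal(sum(imp$band_pct), 100)
  expect_length(imp$channel_pct, 20)
})

test_that("subject clustergram recovers planted groups", {
  withr::with_seed(30, {
    m <- rbind(matrix(rnorm(5 * 30, 0), 5, 30),
               matrix(rnorm(5 * 30, 3), 5, 30))
    rownames(m) <- paste0("sub", 1:10)
  })
  cg <- subject_clustergram(m)
  grp <- cg$groups
  expect_equal(length(unique(grp[1:5])), 1)
  expect_equal(length(unique(grp[6:10])), 1)
  expect_true(grp[1] != grp[6])
  # duplicated subject sits at distance zero; permutation keeps the split
  md <- rbind(m, sub11 = m[1, ])
  cgd <- subject_clustergram(md)
  expect_equal(cgd$groups[["sub11"]], cgd$groups[["sub1"]])
  perm <- withr::with_seed(31, sample(10))
  cgp <- subject_clustergram(m[perm, ])
  expect_equal(cgp$groups[rownames(m)], cg$groups[rownames(m)])
  expect_error(subject_clustergram(m[1:3, ]), "4 subjects")
})
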