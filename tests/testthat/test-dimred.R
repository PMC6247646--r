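# PCA, perplexity calibration, KL cost, t-SNE and Sammon's mapping.

test_that("PCA satisfies its variance and reconstruction contracts", {
  set.seed(41)
  # rank-1: points on a line in 5-D
  line <- outer(rnorm(30), c(1, 2, -1, 0.5, 3))
  pl <- pca_project(line, 1)
  expect_warning(pca_project(line, 3), "rank")
  expect_equal(pl$explained[1], 1, tolerance = 1e-9)

  # isotropic Gaussian: every component explains about a quarter
  iso <- matrix(rnorm(800), 200, 4)
  pi_ <- pca_project(iso, 4)
  expect_true(all(abs(pi_$explained - 0.25) < 0.05))
  expect_true(all(diff(pi_$explained) <= 1e-12))
  # orthonormal loadings, scores = centered data times loadings
  expect_equal(crossprod(pi_$loadings), diag(4), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(pi_$scores, sweep(iso, 2, pi_$center) %*% pi_$loadings,
               tolerance = 1e-9)
  # full reconstruction
  rec <- pi_$scores %*% t(pi_$loadings)
  expect_equal(sweep(rec, 2, pi_$center, "+"), iso, tolerance = 1e-6)
  # deterministic sign: largest-magnitude loading entry positive
  for (j in 1:4)
    expect_gt(pi_$loadings[which.max(abs(pi_$loadings[, j])), j], 0)
})

test_that("perplexity calibration hits its target and degenerates safely", {
  # two points: the single neighbor takes all mass
  expect_warning(am2 <- perplexity_calibration(
    as.matrix(dist(matrix(c(0, 1), 2, 1)))^2, 1.5), "closest attainable")
  expect_equal(am2$p_cond[1, 2], 1)

  # equidistant points (regular simplex): uniform rows whatever epsilon
  # (the uniform row has perplexity n - 1, so the target is flagged)
  simplex <- diag(4)
  expect_warning(
    am <- perplexity_calibration(as.matrix(dist(simplex))^2, 2),
    "closest attainable")
  expect_equal(am$p_cond[1, -1], rep(1 / 3, 3), tolerance = 1e-9)

  set.seed(42)
  X <- matrix(rnorm(100), 10)
  am10 <- perplexity_calibration(as.matrix(dist(X))^2, 5)
  for (i in 1:10)
    expect_lt(abs(row_perplexity(am10$p_cond[i, ]) - 5), 1e-3)
  # affinity-model invariants
  expect_equal(rowSums(am10$p_cond), rep(1, 10), tolerance = 1e-8)
  expect_equal(sum(am10$P), 1, tolerance = 1e-9)
  expect_equal(am10$P, t(am10$P))
  expect_true(all(diag(am10$P) == 0))
  expect_true(all(am10$P >= 0))
})

test_that("the KL cost matches hand arithmetic and a brute-force sum", {
  p <- c(0.2, 0.5, 0.3)
  expect_equal(kl_cost(p, p), 0)
  expect_equal(kl_cost(c(1, 0), c(0.5, 0.5)), log(2))
  set.seed(43)
  P <- matrix(runif(25), 5); P <- P / sum(P)
  Q <- matrix(runif(25), 5); Q <- Q / sum(Q)
  expect_equal(kl_cost(P, Q), kl_brute(as.numeric(P), as.numeric(Q)),
               tolerance = 1e-12)
  expect_error(kl_cost(c(0.5, 0.5), c(1, 0)), "degenerate")
})

test_that("the t-SNE gradient agrees with central differences", {
  set.seed(44)
  X <- matrix(rnorm(7 * 4), 7)
  P <- perplexity_calibration(as.matrix(dist(X))^2, 3)$P
  Y <- matrix(rnorm(14), 7)
  g <- pdembed:::.tsne_gradient(P, Y)
  num <- matrix(0, 7, 2)
  h <- 1e-6
  for (i in 1:7) for (q in 1:2) {
    Yp <- Y; Yp[i, q] <- Y[i, q] + h
    Ym <- Y; Ym[i, q] <- Y[i, q] - h
    num[i, q] <- (kl_cost(P, pdembed:::.tsne_q(Yp)$Q) -
                    kl_cost(P, pdembed:::.tsne_q(Ym)$Q)) / (2 * h)
  }
  expect_lt(max(abs(g - num)) / max(abs(num)), 1e-5)
})

test_that("t-SNE separates well-separated clusters and descends stably", {
  set.seed(45)
  X <- rbind(matrix(rnorm(200, 0), 20), matrix(rnorm(200, 6), 20),
             matrix(rnorm(200, -6), 20))
  lab <- rep(1:3, each = 20)
  emb <- tsne_map(X, iterations = 1000, learning_rate = 0.5,
                  perplexity = 15, seed = 3)
  expect_equal(dim(emb$coordinates), c(60, 2))
  expect_true(all(is.finite(emb$coordinates)))
  D <- as.matrix(dist(emb$coordinates)); diag(D) <- Inf
  expect_equal(mean(lab[apply(D, 1, which.min)] == lab), 1)
  # cost non-increasing over the last 100 iterations (1e-6 uptick allowed)
  tail_costs <- emb$cost_history[901:1000]
  expect_lt(max(diff(tail_costs)), 1e-6)
  expect_gte(emb$final_cost, 0)
  # reproducibility under identical (seed, l, eta, epsilon)
  emb2 <- tsne_map(X, iterations = 1000, learning_rate = 0.5,
                   perplexity = 15, seed = 3)
  expect_identical(emb$coordinates, emb2$coordinates)
})

test_that("Sammon's mapping reaches zero stress on embeddable inputs", {
  set.seed(46)
  # already two-dimensional: PCA initialization is an isometry
  flat <- matrix(rnorm(40), 20, 2)
  sf <- sammon_map(flat, iterations = 50)
  expect_lte(sf$final_cost, 1e-6)
  # a planar square living in 3-D
  square <- cbind(c(0, 0, 1, 1), c(0, 1, 0, 1), c(0, 0, 0, 0))
  square <- square %*% qr.Q(qr(matrix(rnorm(9), 3)))   # rotate into 3-D
  ss <- sammon_map(square, iterations = 100)
  expect_lte(ss$final_cost, 1e-6)
})

test_that("accepted Sammon steps never increase stress and match MASS", {
  set.seed(47)
  X <- matrix(rnorm(150), 30, 5)
  sm <- sammon_map(X, iterations = 300, learning_rate = 0.35)
  expect_true(all(diff(sm$cost_history) <= 0))
  ms <- MASS::sammon(dist(X), y = pca_project(X, 2)$scores, trace = FALSE,
                     niter = 300)
  expect_equal(sm$final_cost, ms$stress, tolerance = 1e-3)
  # duplicates are jittered rather than fatal
  Xd <- rbind(X, X[1, , drop = FALSE])
  sd_ <- sammon_map(Xd, iterations = 20)
  expect_true(all(is.finite(sd_$coordinates)))
})

test_that("t-SNE resolves structure that a 2-D PCA projection cannot", {
  set.seed(48)
  n <- 40
  th1 <- runif(n, 0, 2 * pi); th2 <- runif(n, 0, 2 * pi)
  rings <- rbind(cbind(cos(th1), sin(th1)) * (1 + rnorm(n, 0, 0.03)),
                 cbind(cos(th2), sin(th2)) * (2.2 + rnorm(n, 0, 0.03)))
  lab <- rep(1:2, each = n)
  # nonlinear lift into 20-D, unit-variance columns
  lift <- cbind(rings, rings^2, rings^3, abs(rings), sqrt(abs(rings)),
                sin(2 * rings), cos(3 * rings), exp(rings / 3),
                rings[, 1] * rings[, 2],
                rings[, 1]^2 - rings[, 2]^2,
                rings[, 1] * abs(rings[, 2]),
                rings[, 2] * abs(rings[, 1]))
  stopifnot(ncol(lift) == 20)
  lift <- scale(lift) %*% qr.Q(qr(matrix(rnorm(400), 20)))
  acc_tsne <- nn1_loocv(
    tsne_map(lift, iterations = 800, learning_rate = 0.5, perplexity = 10,
             seed = 9)$coordinates, lab)
  acc_pca <- nn1_loocv(pca_map(lift)$coordinates, lab)
  expect_gt(acc_tsne, acc_pca)
})
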