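# SVM, LOOCV, the performance indices, ROC/AUC bootstrap, and KS tests.

three_clusters <- function(n = 20, sep = 3, sd = 0.3, seed = 61) {
  set.seed(seed)
  pts <- rbind(cbind(rnorm(n, 0, sd), rnorm(n, 0, sd)),
               cbind(rnorm(n, sep, sd), rnorm(n, 0, sd)),
               cbind(rnorm(n, 0, sd), rnorm(n, sep, sd)))
  list(x = pts, y = factor(rep(c("S_H", "S_PD", "S_DBS"), each = n),
                           levels = c("S_H", "S_PD", "S_DBS")))
}

test_that("the one-vs-all SVM separates clusters and is deterministic", {
  d <- three_clusters()
  fit <- svm_ova(d$x, d$y)
  expect_equal(mean(predict(fit, d$x) == d$y), 1)
  dec <- predict(fit, d$x, type = "decision")
  expect_equal(colnames(dec), c("S_H", "S_PD", "S_DBS"))
  # permuting the training order leaves predictions unchanged
  set.seed(62)
  perm <- sample(length(d$y))
  fit_p <- svm_ova(d$x[perm, ], d$y[perm])
  expect_equal(predict(fit_p, d$x), predict(fit, d$x))
  expect_error(svm_ova(d$x, rep("S_H", nrow(d$x))), "2 classes")
})

test_that("the Gaussian kernel solves an XOR layout", {
  set.seed(63)
  xo <- rbind(cbind(rnorm(15, 0, 0.2), rnorm(15, 0, 0.2)),
              cbind(rnorm(15, 2, 0.2), rnorm(15, 2, 0.2)),
              cbind(rnorm(15, 0, 0.2), rnorm(15, 2, 0.2)),
              cbind(rnorm(15, 2, 0.2), rnorm(15, 0, 0.2)))
  yx <- rep(c("A", "A", "B", "B"), each = 15)
  expect_equal(mean(predict(svm_ova(xo, yx), xo) == yx), 1)
})

test_that("LOOCV matches manual enumeration of the refits", {
  pts <- matrix(c(0, 0, 0.2, 0, 5, 0, 5.2, 0.1, 0.1, 5), 5, 2,
                byrow = TRUE)
  y <- c("A", "A", "B", "B", "A")
  cv <- loocv(pts, y)
  manual <- vapply(1:5, function(i) {
    fit <- svm_ova(pts[-i, , drop = FALSE], droplevels(factor(y[-i])))
    unname(predict(fit, pts[i, , drop = FALSE]))
  }, "")
  expect_equal(cv$predictions, manual)
  expect_equal(sum(cv$confusion), 5)

  d <- three_clusters()
  cvs <- loocv(d$x, d$y)
  expect_equal(cvs$osr, 100)
  expect_equal(unname(cvs$r_tp), c(1, 1, 1))
  expect_equal(sum(diag(as.matrix(cvs$confusion))), length(d$y))
})

test_that("shuffled labels drive LOOCV to chance", {
  d <- three_clusters(n = 20)
  set.seed(64)
  y_shuf <- sample(d$y)
  cv <- loocv(d$x, y_shuf)
  expect_lt(abs(cv$osr / 100 - 1 / 3), 0.15)
})

test_that("confusion-matrix identities and the indices check out", {
  set.seed(65)
  pred <- sample(c("S_H", "S_PD", "S_DBS"), 120, replace = TRUE)
  targ <- sample(c("S_H", "S_PD", "S_DBS"), 120, replace = TRUE)
  cm <- confusion_matrix(pred, targ)
  expect_equal(sum(cm), 120)
  for (cl in rownames(cm)) {
    k <- class_counts(cm, cl)
    expect_equal(sum(k), 120)
    expect_equal(unname(accuracy(cm, cl)),
                 unname((k["TP"] + k["TN"]) / 120))
  }
  expect_true(all(abs(colSums(normalize_confusion(cm)) - 1) < 1e-9))
  ga <- grand_average_confusion(list(cm, cm))
  expect_equal(ga, normalize_confusion(cm))

  # hand arithmetic: TP=45, TN=100, FP=10, FN=16 at TNS=171
  cm_hand <- structure(matrix(c(45, 16, 10, 100), 2,
                              dimnames = list(c("A", "B"), c("A", "B"))),
                       class = "confusion_matrix")
  expect_equal(unname(accuracy(cm_hand, "A")), 145 / 171)
  diag_cm <- structure(diag(c(44, 71, 51)), class = "confusion_matrix")
  expect_equal(osr(diag_cm), 100)
  offd <- matrix(1, 3, 3) - diag(1, 3)
  expect_equal(osr(structure(offd, class = "confusion_matrix")), 0)
  # diagonal (44, 71, 51) over TNS = 171
  cm3 <- structure(matrix(c(44, 0, 1, 1, 71, 1, 0, 2, 51), 3,
                          byrow = TRUE), class = "confusion_matrix")
  expect_equal(sum(cm3), 171)
  expect_equal(osr(cm3), 100 * 166 / 171, tolerance = 1e-9)
})

test_that("success rate and quality ratio are the stated means", {
  expect_equal(success_rate(rep(1, 28)), 1)
  expect_equal(success_rate(rep(c(1, 0), 14)), 0.5)
  set.seed(66)
  r <- runif(28)
  expect_equal(success_rate(r), mean(r))

  expect_equal(quality_ratio(100, 100), 100)
  expect_equal(quality_ratio(0, 0), 0)
  expect_equal(quality_ratio(96.9, 76.6), 86.75)
  expect_equal(quality_ratio(20, 80), quality_ratio(80, 20))
  expect_error(quality_ratio(120, 50))
})

test_that("AUC equals the concordance count and bootstrap is calibrated", {
  # perfect separation
  s <- c(rnorm(20, 5, 0.1), rnorm(20, 0, 0.1))
  lab <- rep(c(TRUE, FALSE), each = 20)
  r <- roc_auc_bootstrap(s, lab, replicas = 200, seed = 1)
  expect_equal(r$auc, 1)

  set.seed(67)
  s30 <- rnorm(30); l30 <- rep(c(TRUE, FALSE), 15)
  r30 <- roc_auc_bootstrap(s30, l30, replicas = 300, seed = 2)
  expect_equal(r30$auc, auc_brute(s30, l30), tolerance = 1e-12)
  expect_true(r30$ci["lower"] <= r30$auc && r30$auc <= r30$ci["upper"])

  # null scores: AUC near one half
  set.seed(68)
  s500 <- rnorm(500); l500 <- rep(c(TRUE, FALSE), 250)
  expect_lt(abs(roc_auc_bootstrap(s500, l500, replicas = 100,
                                  seed = 3)$auc - 0.5), 0.05)

  expect_warning(rd <- roc_auc_bootstrap(rep(1, 20),
                                         rep(c(TRUE, FALSE), 10)),
                 "degenerate")
  expect_equal(rd$auc, 0.5)
  # bootstrap is reproducible under the seed
  expect_equal(roc_auc_bootstrap(s30, l30, replicas = 100, seed = 5)$ci,
               roc_auc_bootstrap(s30, l30, replicas = 100, seed = 5)$ci)
})

test_that("KS comparisons match the ECDF gap and detect separation", {
  x <- rnorm(30)
  same <- ks_compare(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  a <- runif(50, 0, 1); b <- runif(50, 2, 3)
  expect_lt(ks_compare(a, b)$p_value, 1e-6)
  expect_equal(ks_compare(a, b)$statistic, 1)

  set.seed(69)
  u <- rnorm(20); v <- rnorm(20, 0.5)
  expect_equal(ks_compare(u, v)$statistic, ks_brute(u, v),
               tolerance = 1e-12)
  nc <- normality_check(rnorm(50))
  expect_true(nc$p_value > 0 && nc$p_value <= 1)
})
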