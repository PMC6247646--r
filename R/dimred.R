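# Two-dimensional projections: PCA, Sammon's mapping, and t-SNE written from
# their defining objectives (KL divergence with a Student-t low-dimensional
# kernel; Sammon stress with the diagonal-Newton update).

#' Principal component projection
#'
#' Centered PCA via the singular value decomposition (stats::prcomp). The
#' sign of each loading vector is fixed by forcing its largest-magnitude
#' element positive, so plots are reproducible.
#'
#' @param X Numeric matrix (samples x features), typically standardized.
#' @param k Number of components; truncated to the matrix rank with a warning
#'   if larger.
#' @return List of class `pca_projection`: `scores` (n x k), `loadings`
#'   (orthonormal columns), `explained` (variance fractions, non-increasing),
#'   `center`.
#' @export
pca_project <- function(X, k = 2L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) > k, k >= 1)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-12)
  if (k > rank) {
    warning("k = ", k, " exceeds rank ", rank, "; truncated")
    k <- rank
  }
  flip <- apply(pc$rotation[, seq_len(k), drop = FALSE], 2, function(v)
    sign(v[which.max(abs(v))]))
  loadings <- sweep(pc$rotation[, seq_len(k), drop = FALSE], 2, flip, "*")
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, "*")
  structure(list(scores = scores, loadings = loadings,
                 explained = pc$sdev^2 / sum(pc$sdev^2),
                 center = pc$center, k = k),
            class = "pca_projection")
}

#' Calibrate Gaussian affinities to a target perplexity
#'
#' Converts squared Euclidean distances into conditional probabilities
#' p(j|i) with per-point bandwidths sigma_i found by bisection so that the
#' perplexity 2^H(p(.|i)) (H in bits) matches the target within `tol`. The
#' joint affinity is the symmetrization P = (p(j|i) + p(i|j)) / 2n.
#'
#' @param D2 n x n matrix of squared pairwise distances.
#' @param perplexity Target perplexity (smooth effective neighbor count),
#'   must be < n.
#' @param tol Tolerance on the achieved perplexity.
#' @param max_iter Maximum bisection iterations per point.
#' @return List of class `affinity_model`: `p_cond` (row-stochastic), `P`
#'   (symmetric joint, sums to 1, zero diagonal), `sigma`, `perplexity`,
#'   `achieved` (per-row perplexities), `flagged` (rows where the target was
#'   unattainable and the closest value was used).
#' @export
perplexity_calibration <- function(D2, perplexity, tol = 1e-4,
                                   max_iter = 200L) {
  D2 <- as.matrix(D2)
  n <- nrow(D2)
  stopifnot(n >= 2, ncol(D2) == n, perplexity > 0)
  if (n > 2 && perplexity >= n)
    stop("perplexity must be smaller than the number of points")
  target_h <- log2(perplexity)
  p_cond <- matrix(0, n, n)
  sigma <- numeric(n)
  achieved <- numeric(n)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    d2 <- D2[i, -i]
    row_entropy <- function(beta) {
      w <- exp(-beta * (d2 - min(d2)))
      p <- w / sum(w)
      h <- -sum(ifelse(p > 0, p * log2(p), 0))
      list(h = h, p = p)
    }
    beta <- 1
    lo <- -Inf; hi <- Inf
    res <- row_entropy(beta)
    iter <- 0L
    while (abs(2^res$h - perplexity) > tol && iter < max_iter) {
      if (res$h > target_h) {       # too many neighbors: sharpen
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
      res <- row_entropy(beta)
      iter <- iter + 1L
    }
    if (abs(2^res$h - perplexity) > tol) flagged[i] <- TRUE
    p_cond[i, -i] <- res$p
    sigma[i] <- 1 / sqrt(2 * beta)
    achieved[i] <- 2^res$h
  }
  if (any(flagged))
    warning(sum(flagged), " row(s) could not attain the target perplexity; ",
            "closest attainable used")
  P <- (p_cond + t(p_cond)) / (2 * n)
  structure(list(p_cond = p_cond, P = P, sigma = sigma,
                 perplexity = perplexity, achieved = achieved,
                 flagged = flagged),
            class = "affinity_model")
}

#' Kullback-Leibler embedding cost
#'
#' E = sum p log(p / q) (natural log) over all entries with p > 0; zero iff
#' P equals Q on the support of P. A zero q at positive p signals a
#' degenerate embedding and is an error.
#'
#' @param P,Q Non-negative arrays of matched shape (joint affinities).
#' @return Non-negative scalar.
#' @export
kl_cost <- function(P, Q) {
  stopifnot(length(P) == length(Q))
  p <- as.numeric(P); q <- as.numeric(Q)
  pos <- p > 0
  if (any(q[pos] == 0))
    stop("q = 0 where p > 0: degenerate embedding, KL divergence infinite")
  sum(p[pos] * log(p[pos] / q[pos]))
}

# Student-t (1 dof) affinities of a 2-D configuration
.tsne_q <- function(Y) {
  num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
  diag(num) <- 0
  list(num = num, Q = num / sum(num))
}

# analytic gradient of the KL cost wrt the map points
.tsne_gradient <- function(P, Y) {
  qq <- .tsne_q(Y)
  L <- (P - qq$Q) * qq$num
  4 * (diag(rowSums(L)) - L) %*% Y
}

#' t-distributed stochastic neighbor embedding
#'
#' Minimizes the KL divergence between Gaussian input affinities (calibrated
#' to the target perplexity) and Student-t (1 d.o.f.) map affinities by
#' gradient descent with momentum (0.5, switching to 0.8 at iteration 250),
#' per-dimension adaptive gains, and early exaggeration (P x 4 for the first
#' 100 iterations), following the original reference implementation. The map
#' is initialized from a seeded Gaussian with sd 1e-4.
#'
#' @param X Numeric matrix (samples x features), n >= 5.
#' @param iterations Gradient-descent iterations `l`.
#' @param learning_rate Step size eta.
#' @param perplexity Target perplexity epsilon.
#' @param seed Integer seed for the initialization.
#' @param momentum Initial and final momentum.
#' @param momentum_switch Iteration at which the final momentum starts.
#' @param exaggeration,exaggeration_iter Early-exaggeration factor and
#'   duration.
#' @param min_gain Lower bound of the adaptive gains.
#' @return An object of class `embedding` with fields `coordinates` (n x 2),
#'   `method`, `iterations`, `learning_rate`, `perplexity`, `final_cost`
#'   (KL divergence), `cost_history`, and the `affinity` model.
#' @export
tsne_map <- function(X, iterations = 1000L, learning_rate = 0.5,
                     perplexity = 30, seed = 1L,
                     momentum = c(0.5, 0.8), momentum_switch = 250L,
                     exaggeration = 4, exaggeration_iter = 100L,
                     min_gain = 0.01) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 5)
  aff <- perplexity_calibration(as.matrix(stats::dist(X))^2, perplexity)
  P <- aff$P
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  inc <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  costs <- numeric(iterations)
  for (it in seq_len(iterations)) {
    Pe <- if (it <= exaggeration_iter) P * exaggeration else P
    qq <- .tsne_q(Y)
    L <- (Pe - qq$Q) * qq$num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    if (!all(is.finite(grad)))
      stop("non-finite t-SNE gradient at iteration ", it,
           ": step exploded, reduce the learning rate")
    same <- sign(grad) == sign(inc)
    gains <- pmax(ifelse(same, gains * 0.8, gains + 0.2), min_gain)
    mom <- if (it < momentum_switch) momentum[1] else momentum[2]
    inc <- mom * inc - learning_rate * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
    # cost of the configuration entering this iteration (true P, no
    # exaggeration); the final cost below is evaluated after the last step
    costs[it] <- kl_cost(P, pmax(qq$Q, 1e-300))
    if (!is.finite(costs[it]))
      stop("non-finite t-SNE cost at iteration ", it)
  }
  final_cost <- kl_cost(P, pmax(.tsne_q(Y)$Q, 1e-300))
  costs <- c(costs[-1], final_cost)
  structure(list(coordinates = Y, method = "t-SNE",
                 iterations = as.integer(iterations),
                 learning_rate = learning_rate, perplexity = perplexity,
                 seed = as.integer(seed),
                 final_cost = final_cost,
                 cost_history = costs, affinity = aff),
            class = "embedding")
}

#' Sammon's nonlinear mapping
#'
#' Minimizes Sammon stress, the distance-preservation error weighted by the
#' inverse original distance, starting from the two-dimensional PCA scores
#' and iterating the classical diagonal-Newton update with step factor
#' `learning_rate` and step-halving whenever a step would increase the
#' stress (accepted steps are therefore non-increasing).
#'
#' @param X Numeric matrix (samples x features). Duplicate rows are jittered
#'   by 1e-10; exact duplicates remaining afterwards are an error.
#' @param iterations Maximum accepted iterations `l`.
#' @param learning_rate Step ("magic") factor eta.
#' @param tol Relative stress-improvement threshold for early stopping.
#' @return An `embedding` with `final_cost` = Sammon stress and the accepted
#'   `cost_history`.
#' @export
sammon_map <- function(X, iterations = 500L, learning_rate = 0.35,
                       tol = 1e-12) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 3)
  if (anyDuplicated(X)) {
    old <- .Random.seed_guard(1L)
    on.exit(old(), add = TRUE)
    X <- X + matrix(stats::rnorm(length(X), sd = 1e-10), n)
  }
  Dstar <- as.matrix(stats::dist(X))
  if (any(Dstar[upper.tri(Dstar)] == 0))
    stop("duplicate rows remain after jitter: pairwise distances must be > 0")
  csum <- sum(Dstar[upper.tri(Dstar)])
  Y <- pca_project(X, 2)$scores
  eps <- 1e-12

  stress <- function(Y) {
    D <- as.matrix(stats::dist(Y))
    sum(((Dstar - D)^2 / pmax(Dstar, eps))[upper.tri(D)]) / csum
  }
  cur <- stress(Y)
  history <- cur
  for (it in seq_len(iterations)) {
    D <- pmax(as.matrix(stats::dist(Y)), eps)
    diag(D) <- 1
    Dst <- Dstar; diag(Dst) <- 1
    B <- (Dst - D) / (Dst * D); diag(B) <- 0
    A <- 1 / (Dst * D); diag(A) <- 0
    rB <- rowSums(B)
    grad <- matrix(0, n, 2)
    hess <- matrix(0, n, 2)
    for (q in 1:2) {
      dy <- outer(Y[, q], Y[, q], "-")
      grad[, q] <- (-2 / csum) * (rB * Y[, q] - B %*% Y[, q])
      hess[, q] <- (-2 / csum) *
        rowSums(A * ((Dst - D) - dy^2 / D * (1 + (Dst - D) / D)))
    }
    step <- learning_rate * grad / pmax(abs(hess), eps)
    accepted <- FALSE
    for (h in 0:20) {
      Y_new <- Y - step / 2^h
      s_new <- stress(Y_new)
      if (s_new <= cur) { accepted <- TRUE; break }
    }
    if (!accepted) break
    improve <- cur - s_new
    Y <- Y_new
    cur <- s_new
    history <- c(history, cur)
    if (improve < tol * max(cur, eps)) break
  }
  structure(list(coordinates = Y, method = "Sammon",
                 iterations = as.integer(iterations),
                 learning_rate = learning_rate, perplexity = NA_real_,
                 final_cost = cur, cost_history = history),
            class = "embedding")
}

#' Two-dimensional PCA embedding
#'
#' Wraps [pca_project()] into the common `embedding` container; the cost slot
#' holds the variance fraction retained by the two components.
#'
#' @param X Numeric matrix.
#' @return An `embedding` with `method = "PCA"`.
#' @export
pca_map <- function(X) {
  pp <- pca_project(X, 2)
  structure(list(coordinates = pp$scores, method = "PCA",
                 iterations = NA_integer_, learning_rate = NA_real_,
                 perplexity = NA_real_,
                 final_cost = sum(pp$explained[1:2]),
                 projection = pp),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cost_name <- switch(x$method, "t-SNE" = "KL divergence",
                      Sammon = "stress", PCA = "retained variance")
  cat(sprintf("%s embedding of %d points (%s = %.6g)\n", x$method,
              nrow(x$coordinates), cost_name, x$final_cost))
  invisible(x)
}

#' Scatter plot of an embedding
#'
#' @param x An `embedding`.
#' @param labels Optional group factor for coloring.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.embedding <- function(x, labels = NULL, ...) {
  col <- if (is.null(labels)) 1 else as.integer(factor(labels))
  pch <- if (is.null(labels)) 1 else c(2, 8, 1)[as.integer(factor(labels))]
  graphics::plot(x$coordinates, col = col, pch = pch,
                 xlab = "dimension 1", ylab = "dimension 2",
                 main = paste(x$method, "map"), ...)
  if (!is.null(labels))
    graphics::legend("topright", legend = levels(factor(labels)),
                     col = seq_along(levels(factor(labels))),
                     pch = c(2, 8, 1), bty = "n")
  invisible(x)
}

#' Serialize an embedding as CSV plus a JSON sidecar
#'
#' @param emb An `embedding`.
#' @param path CSV path; the sidecar gets the same path with `.json`.
#' @param labels Optional labels column.
#' @export
write_embedding <- function(emb, path, labels = NULL) {
  df <- data.frame(id = seq_len(nrow(emb$coordinates)),
                   x = emb$coordinates[, 1], y = emb$coordinates[, 2])
  if (!is.null(labels)) df$label <- as.character(labels)
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(method = emb$method, iterations = emb$iterations,
               learning_rate = emb$learning_rate,
               perplexity = emb$perplexity, final_cost = emb$final_cost,
               seed = emb$seed)
  jsonlite::write_json(side[!vapply(side, is.null, TRUE)],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
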