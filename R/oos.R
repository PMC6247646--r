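# Parametric out-of-sample extension: project the high-dimensional features
# onto the principal subspace retaining >= 90% of the variance, then fit a
# small feedforward regression network (tanh hidden layer, linear output)
# mapping projected features to the 2-D embedding coordinates. Training is
# L2-regularized least squares with evidence-based (MacKay) re-estimation of
# the regularization weights, the behavior of Bayesian regularization
# backpropagation.

# ---- network plumbing -------------------------------------------------------

.nn_init <- function(p, hidden, seed) {
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  if (hidden > 0) {
    list(W1 = matrix(stats::runif(hidden * p, -1, 1) / sqrt(p), hidden, p),
         b1 = numeric(hidden),
         W2 = matrix(stats::runif(2 * hidden, -1, 1) / sqrt(hidden), 2, hidden),
         b2 = numeric(2))
  } else {
    list(W = matrix(stats::runif(2 * p, -1, 1) / sqrt(p), 2, p),
         b = numeric(2))
  }
}

.nn_pack <- function(w) unlist(w, use.names = FALSE)

.nn_unpack <- function(theta, p, hidden) {
  if (hidden > 0) {
    i <- 0
    W1 <- matrix(theta[i + seq_len(hidden * p)], hidden, p); i <- i + hidden * p
    b1 <- theta[i + seq_len(hidden)]; i <- i + hidden
    W2 <- matrix(theta[i + seq_len(2 * hidden)], 2, hidden); i <- i + 2 * hidden
    b2 <- theta[i + seq_len(2)]
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  } else {
    W <- matrix(theta[seq_len(2 * p)], 2, p)
    list(W = W, b = theta[2 * p + seq_len(2)])
  }
}

# indicator of regularized (non-bias) coordinates in the packed vector
.nn_weight_mask <- function(p, hidden) {
  if (hidden > 0)
    c(rep(TRUE, hidden * p), rep(FALSE, hidden),
      rep(TRUE, 2 * hidden), rep(FALSE, 2))
  else c(rep(TRUE, 2 * p), rep(FALSE, 2))
}

.nn_forward <- function(w, X) {
  if (!is.null(w$W1)) {
    Z <- tanh(sweep(X %*% t(w$W1), 2, w$b1, "+"))
    list(Z = Z, Yhat = sweep(Z %*% t(w$W2), 2, w$b2, "+"))
  } else {
    list(Z = NULL, Yhat = sweep(X %*% t(w$W), 2, w$b, "+"))
  }
}

# objective beta*E_D + alpha*E_W and its analytic gradient (backprop)
.nn_obj <- function(theta, X, Y, pdim, hidden, alpha, beta, mask) {
  w <- .nn_unpack(theta, pdim, hidden)
  fw <- .nn_forward(w, X)
  R <- fw$Yhat - Y
  0.5 * beta * sum(R^2) + 0.5 * alpha * sum(theta[mask]^2)
}

.nn_grad <- function(theta, X, Y, pdim, hidden, alpha, beta, mask) {
  w <- .nn_unpack(theta, pdim, hidden)
  fw <- .nn_forward(w, X)
  R <- fw$Yhat - Y
  if (hidden > 0) {
    dW2 <- t(R) %*% fw$Z
    db2 <- colSums(R)
    dZ <- (R %*% w$W2) * (1 - fw$Z^2)
    dW1 <- t(dZ) %*% X
    db1 <- colSums(dZ)
    g <- c(as.numeric(dW1), db1, as.numeric(dW2), db2)
  } else {
    g <- c(as.numeric(t(R) %*% X), colSums(R))
  }
  g <- beta * g
  g[mask] <- g[mask] + alpha * theta[mask]
  g
}

# Jacobian of the residual vector (2n, outputs stacked) wrt packed params
.nn_jacobian <- function(theta, X, p, hidden) {
  n <- nrow(X)
  w <- .nn_unpack(theta, p, hidden)
  fw <- .nn_forward(w, X)
  if (hidden > 0) {
    Dz <- 1 - fw$Z^2                       # n x hidden
    blocks <- lapply(1:2, function(o) {
      A <- Dz * matrix(w$W2[o, ], n, hidden, byrow = TRUE)  # n x hidden
      JW1 <- matrix(0, n, hidden * p)
      for (j in seq_len(p)) JW1[, (j - 1) * hidden + seq_len(hidden)] <-
          A * X[, j]
      JW2 <- matrix(0, n, 2 * hidden)
      JW2[, (seq_len(hidden) - 1) * 2 + o] <- fw$Z
      Jb2 <- matrix(0, n, 2); Jb2[, o] <- 1
      cbind(JW1, A, JW2, Jb2)
    })
    rbind(blocks[[1]], blocks[[2]])
  } else {
    blocks <- lapply(1:2, function(o) {
      JW <- matrix(0, n, 2 * p)
      JW[, (seq_len(p) - 1) * 2 + o] <- X
      Jb <- matrix(0, n, 2); Jb[, o] <- 1
      cbind(JW, Jb)
    })
    rbind(blocks[[1]], blocks[[2]])
  }
}

# ---- fitting ----------------------------------------------------------------

#' Fit the out-of-sample mapper
#'
#' Learns the mapping f: x -> y from standardized high-dimensional training
#' features to their 2-D embedding coordinates. The features first pass
#' through a PCA retaining at least `variance` (default 90%) of the total
#' variance; a feedforward network (default one hidden layer of 20 tanh
#' units, linear output) is then trained by penalized least squares. When
#' `evidence = TRUE` the regularization weight alpha and noise weight beta
#' are re-estimated by the MacKay evidence update using the Gauss-Newton
#' Hessian; otherwise they stay fixed (plain ridge-flavored training).
#'
#' @param X_train Standardized feature matrix (n x D), n >= 10.
#' @param Y_train Matrix of embedding coordinates (n x 2), or an `embedding`.
#' @param hidden Hidden-layer width; 0 gives a purely linear network.
#' @param variance Minimum retained variance fraction of the projection.
#' @param evidence Re-estimate alpha/beta by the evidence framework.
#' @param alpha,beta Initial regularization and noise precision weights.
#' @param evidence_iters Maximum evidence re-estimation cycles. Short inner
#'   optimizations interleaved with frequent re-estimation (the default)
#'   track the named scheme's behavior; a single long cycle can interpolate
#'   noise before the regularizer adapts.
#' @param maxit BFGS iterations per cycle.
#' @param tol Convergence threshold on the change of log(alpha), log(beta).
#' @param seed Seed for the weight initialization (uniform +-1/sqrt(fan-in)).
#' @return An object of class `oos_mapper` with the projection, network
#'   weights, and training diagnostics `mse` and `R` (correlation between
#'   fitted and target coordinates).
#' @export
fit_oos_mapper <- function(X_train, Y_train, hidden = 20L, variance = 0.90,
                           evidence = TRUE, alpha = 0.01, beta = 1,
                           evidence_iters = 10L, maxit = 50L, tol = 1e-6,
                           seed = 1L) {
  X_train <- as.matrix(X_train)
  if (inherits(Y_train, "embedding")) Y_train <- Y_train$coordinates
  Y_train <- as.matrix(Y_train)
  stopifnot(nrow(X_train) == nrow(Y_train), ncol(Y_train) == 2)
  if (nrow(X_train) < 10) stop("need at least 10 training samples")
  if (!all(is.finite(Y_train))) stop("non-finite embedding targets")

  pp <- suppressWarnings(
    pca_project(X_train, k = max(1L, nrow(X_train) - 1L)))
  cum <- cumsum(pp$explained)
  k <- which(cum >= variance)[1]
  if (is.na(k)) k <- length(cum)
  proj <- list(center = pp$center,
               loadings = pp$loadings[, seq_len(k), drop = FALSE],
               retained = cum[k])
  stopifnot(proj$retained >= variance - 1e-9)
  Xp <- sweep(X_train, 2, proj$center) %*% proj$loadings
  in_scale <- list(mu = colMeans(Xp), sd = pmax(apply(Xp, 2, stats::sd),
                                                .Machine$double.eps))
  Xs <- sweep(sweep(Xp, 2, in_scale$mu), 2, in_scale$sd, "/")

  p <- ncol(Xs)
  mask <- .nn_weight_mask(p, hidden)
  theta <- .nn_pack(.nn_init(p, hidden, seed))
  n_data <- 2 * nrow(Xs)
  for (cycle in seq_len(max(1L, if (evidence) evidence_iters else 1L))) {
    fit <- stats::optim(theta, .nn_obj, .nn_grad, X = Xs, Y = Y_train,
                        pdim = p, hidden = hidden, alpha = alpha,
                        beta = beta, mask = mask, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-10))
    theta <- fit$par
    if (!evidence) break
    w <- .nn_unpack(theta, p, hidden)
    R <- .nn_forward(w, Xs)$Yhat - Y_train
    ed <- 0.5 * sum(R^2)
    ew <- 0.5 * sum(theta[mask]^2)
    J <- .nn_jacobian(theta, Xs, p, hidden)
    H <- beta * crossprod(J)
    diag(H) <- diag(H) + ifelse(mask, alpha, 1e-10)
    Hinv_diag <- diag(chol2inv(chol(H)))
    gamma_w <- sum(mask) - alpha * sum(Hinv_diag[mask])
    gamma_w <- min(max(gamma_w, 1e-6), sum(mask))
    alpha_new <- gamma_w / max(2 * ew, .Machine$double.eps)
    beta_new <- max(n_data - gamma_w - sum(!mask), 1) /
      max(2 * ed, .Machine$double.eps)
    delta <- abs(log(alpha_new) - log(alpha)) +
      abs(log(beta_new) - log(beta))
    alpha <- alpha_new; beta <- beta_new
    if (delta < tol) break
  }
  w <- .nn_unpack(theta, p, hidden)
  Yhat <- .nn_forward(w, Xs)$Yhat
  structure(list(projection = proj, input_scale = in_scale, weights = w,
                 hidden = as.integer(hidden), alpha = alpha, beta = beta,
                 mse = mean((Yhat - Y_train)^2),
                 R = stats::cor(as.numeric(Yhat), as.numeric(Y_train)),
                 n_features = ncol(X_train)),
            class = "oos_mapper")
}

#' @export
print.oos_mapper <- function(x, ...) {
  cat(sprintf(
    "Out-of-sample mapper: %d features -> %d PCs (%.1f%% variance) -> %d tanh units -> 2-D\n",
    x$n_features, ncol(x$projection$loadings), 100 * x$projection$retained,
    x$hidden))
  cat(sprintf("  training MSE %.4g, R %.4f\n", x$mse, x$R))
  invisible(x)
}

#' Map new samples into the embedding
#'
#' Deterministic composition projection -> network. `newdata` must be
#' standardized with the training standardization parameters.
#'
#' @param object An `oos_mapper`.
#' @param newdata Matrix of standardized feature rows (possibly 0 rows).
#' @param ... Unused.
#' @return Matrix of 2-D coordinates, one row per input row.
#' @export
predict.oos_mapper <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0)
    return(matrix(numeric(0), 0, 2))
  if (ncol(newdata) != object$n_features)
    stop("feature count mismatch: expected ", object$n_features,
         ", got ", ncol(newdata))
  Xp <- sweep(newdata, 2, object$projection$center) %*%
    object$projection$loadings
  Xs <- sweep(sweep(Xp, 2, object$input_scale$mu), 2,
              object$input_scale$sd, "/")
  .nn_forward(object$weights, Xs)$Yhat
}

#' Serialize / restore an out-of-sample mapper as JSON
#'
#' All arrays are stored as plain JSON numbers, so the bundle is text-only
#' and reusable across pipeline stages.
#'
#' @param mapper An `oos_mapper`.
#' @param path JSON path.
#' @export
write_oos_mapper <- function(mapper, path) {
  enc <- function(m) if (is.matrix(m)) list(dim = dim(m),
                                            data = as.numeric(m))
                     else list(dim = NULL, data = as.numeric(m))
  obj <- list(projection = list(center = as.numeric(mapper$projection$center),
                                loadings = enc(mapper$projection$loadings),
                                retained = mapper$projection$retained),
              input_scale = mapper$input_scale,
              weights = lapply(mapper$weights, enc),
              hidden = mapper$hidden, alpha = mapper$alpha,
              beta = mapper$beta, mse = mapper$mse, R = mapper$R,
              n_features = mapper$n_features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_oos_mapper
#' @export
read_oos_mapper <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec <- function(e) if (!is.null(e$dim) && length(e$dim))
    matrix(e$data, e$dim[1], e$dim[2]) else e$data
  structure(list(
    projection = list(center = obj$projection$center,
                      loadings = dec(obj$projection$loadings),
                      retained = obj$projection$retained),
    input_scale = obj$input_scale,
    weights = lapply(obj$weights, dec),
    hidden = as.integer(obj$hidden), alpha = obj$alpha, beta = obj$beta,
    mse = obj$mse, R = obj$R, n_features = as.integer(obj$n_features)),
    class = "oos_mapper")
}
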