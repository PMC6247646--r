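# One-vs-all soft-margin SVM with a Gaussian kernel, trained by sequential
# minimal optimization (SMO) on the dual. No SVM library is assumed; the
# solver is deterministic (second choice by largest |E_i - E_j|, with an
# ordered fallback scan), so refits on identical data give identical models.

.gauss_kernel <- function(A, B, scale) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  exp(-pmax(d2, 0) / scale^2)
}

# binary SMO on a precomputed kernel; y in {-1, +1}. Compiled inner loop
# (src/smo.cpp): maximal-violating-pair selection, m - M < tol stopping.
.smo_fit <- function(K, y, C = 1, tol = 1e-3, max_iter = 0L) {
  .smo_solve(K, as.numeric(y), C, tol, as.integer(max_iter))
}

#' One-vs-all Gaussian-kernel SVM
#'
#' Trains one binary soft-margin SVM per class against the rest, with kernel
#' K(x, z) = exp(-||x - z||^2 / scale^2) (default scale 0.35) and box
#' constraint `cost`. Prediction is by the largest decision value; exact ties
#' break to the lexicographically first class name.
#'
#' @param x Numeric matrix of points (typically 2-D embedding coordinates).
#' @param y Class labels (factor or character); at least 2 classes.
#' @param kernel_scale Gaussian kernel scale.
#' @param cost Box constraint C of the soft margin.
#' @param tol KKT tolerance of the SMO solver.
#' @return An object of class `svm_ova`.
#' @export
svm_ova <- function(x, y, kernel_scale = 0.35, cost = 1, tol = 1e-3) {
  x <- as.matrix(x)
  y <- factor(y)
  classes <- levels(droplevels(y))
  if (length(classes) < 2) stop("need at least 2 classes")
  K <- .gauss_kernel(x, x, kernel_scale)
  machines <- lapply(classes, function(cl) {
    yy <- ifelse(y == cl, 1, -1)
    .smo_fit(K, yy, C = cost, tol = tol)
  })
  names(machines) <- classes
  structure(list(x = x, y = y, classes = classes, machines = machines,
                 kernel_scale = kernel_scale, cost = cost),
            class = "svm_ova")
}

#' @export
print.svm_ova <- function(x, ...) {
  nsv <- vapply(x$machines, function(m) sum(m$alpha > 1e-8), 1L)
  cat(sprintf(
    "One-vs-all Gaussian SVM: %d classes, kernel scale %g, C = %g\n",
    length(x$classes), x$kernel_scale, x$cost))
  cat("  support vectors per class:",
      paste(sprintf("%s=%d", x$classes, nsv), collapse = ", "), "\n")
  invisible(x)
}

#' Predict classes or decision values
#'
#' @param object An `svm_ova`.
#' @param newdata Matrix of points.
#' @param type `"class"` for labels, `"decision"` for the per-class decision
#'   value matrix.
#' @param ... Unused.
#' @export
predict.svm_ova <- function(object, newdata,
                            type = c("class", "decision"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  Kn <- .gauss_kernel(newdata, object$x, object$kernel_scale)
  dec <- vapply(object$classes, function(cl) {
    m <- object$machines[[cl]]
    yy <- ifelse(object$y == cl, 1, -1)
    as.numeric(Kn %*% (m$alpha * yy) + m$b)
  }, numeric(nrow(newdata)))
  dec <- matrix(dec, nrow = nrow(newdata),
                dimnames = list(NULL, object$classes))
  if (type == "decision") return(dec)
  apply(dec, 1, function(d) {
    cand <- colnames(dec)[d == max(d)]
    sort(cand)[1]
  })
}
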