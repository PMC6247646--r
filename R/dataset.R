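# z-score standardization and the stratified 90/10 train/test split.

#' Standardize a feature matrix (z-score)
#'
#' Centers and scales every feature to mean 0 and unit sample sd (n-1
#' convention): z = (x - mu) / sigma with mu, sigma computed over all samples.
#' Zero-variance columns are set to 0 with a warning.
#'
#' @param fm A `feature_matrix` (or plain numeric matrix).
#' @return List with `matrix` (standardized `feature_matrix` or matrix) and
#'   `params` (class `standardization_params`: per-feature `mu`, `sigma`).
#' @export
zscore_fit_apply <- function(fm) {
  x <- if (inherits(fm, "feature_matrix")) fm$values else as.matrix(fm)
  if (nrow(x) < 2) stop("standardization needs at least 2 rows")
  mu <- colMeans(x)
  sigma <- apply(x, 2, stats::sd)
  zero <- sigma == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance feature(s) set to 0")
    sigma[zero] <- 1
  }
  z <- sweep(sweep(x, 2, mu), 2, sigma, "/")
  z[, zero] <- 0
  params <- structure(list(mu = mu, sigma = sigma, zero_variance = zero),
                      class = "standardization_params")
  if (inherits(fm, "feature_matrix")) {
    fm$values <- z
    list(matrix = fm, params = params)
  } else list(matrix = z, params = params)
}

#' Apply fitted standardization parameters to new data
#'
#' @param params A `standardization_params` from [zscore_fit_apply()].
#' @param x Numeric matrix with the same feature columns.
#' @return Standardized matrix.
#' @export
zscore_apply <- function(params, x) {
  stopifnot(inherits(params, "standardization_params"),
            ncol(x) == length(params$mu))
  z <- sweep(sweep(x, 2, params$mu), 2, params$sigma, "/")
  z[, params$zero_variance] <- 0
  z
}

#' Stratified random train/test split
#'
#' Splits samples into train and test sets per group: round(fraction * n)
#' samples of each group (round-half-to-even) go to training via a seeded
#' permutation, the remainder to test. With the default cohort (50/80/60
#' samples per group) the 90% split gives exactly 45/72/54 = 171 training and
#' 19 test samples.
#'
#' @param fm A `feature_matrix`.
#' @param train_fraction Fraction of each group assigned to training.
#' @param seed Integer seed for the permutation.
#' @return An object of class `split_dataset`: `train`, `test`
#'   (`feature_matrix`es), `split_seed`, and the row indices of each part.
#' @export
stratified_split <- function(fm, train_fraction = 0.9, seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"),
            train_fraction > 0, train_fraction <= 1)
  groups <- levels(droplevels(fm$labels))
  if (any(table(fm$labels)[groups] < 2))
    stop("every group needs at least 2 samples")
  old <- .Random.seed_guard(.substream(seed, 17L))
  on.exit(old(), add = TRUE)
  train_idx <- integer()
  for (g in groups) {
    idx <- which(fm$labels == g)
    n_tr <- round(train_fraction * length(idx))
    train_idx <- c(train_idx, sample(idx)[seq_len(n_tr)])
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(nrow(fm$values)), train_idx)
  if (!length(test_idx))
    stop("empty test set: lower train_fraction (a test set is required)")
  stopifnot(length(intersect(train_idx, test_idx)) == 0,
            length(train_idx) + length(test_idx) == nrow(fm$values))
  structure(list(train = .fm_subset(fm, train_idx),
                 test = .fm_subset(fm, test_idx),
                 split_seed = as.integer(seed),
                 train_indices = train_idx,
                 test_indices = test_idx),
            class = "split_dataset")
}

#' @export
print.split_dataset <- function(x, ...) {
  cat(sprintf("Stratified split (seed %d): %d train / %d test\n",
              x$split_seed, nrow(x$train$values), nrow(x$test$values)))
  print(rbind(train = table(x$train$labels), test = table(x$test$labels)))
  invisible(x)
}

#' Standardize and split in the study's order
#'
#' By default standardization is fitted on the full dataset before splitting
#' (the order the study uses; note it leaks test-set statistics into the
#' training transform). `split_first = TRUE` gives the leak-free alternative:
#' split first, fit the z-score on the training part only, and apply it to
#' the test part.
#'
#' @param fm A `feature_matrix`.
#' @param train_fraction,seed Passed to [stratified_split()].
#' @param split_first Standardize after splitting, on training rows only.
#' @return A `split_dataset` whose `train`/`test` are standardized; the
#'   fitted `standardization_params` are attached as `$standardization`.
#' @export
standardize_and_split <- function(fm, train_fraction = 0.9, seed = 1L,
                                  split_first = FALSE) {
  if (!split_first) {
    zs <- zscore_fit_apply(fm)
    sp <- stratified_split(zs$matrix, train_fraction, seed)
    sp$standardization <- zs$params
  } else {
    sp <- stratified_split(fm, train_fraction, seed)
    zs <- zscore_fit_apply(sp$train)
    sp$train <- zs$matrix
    sp$test$values <- zscore_apply(zs$params, sp$test$values)
    sp$standardization <- zs$params
  }
  sp
}

#' Write / read a split manifest (JSON) for exact reproduction
#'
#' @param split A `split_dataset`.
#' @param path JSON path.
#' @export
write_split_manifest <- function(split, path) {
  jsonlite::write_json(list(seed = split$split_seed,
                            train = split$train_indices,
                            test = split$test_indices),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split_manifest
#' @param fm The `feature_matrix` the manifest indexes into.
#' @export
read_split_manifest <- function(path, fm) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(train = .fm_subset(fm, m$train),
                 test = .fm_subset(fm, m$test),
                 split_seed = as.integer(m$seed),
                 train_indices = m$train, test_indices = m$test),
            class = "split_dataset")
}
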