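# Exhaustive experiment grid: every combination of preprocessing set (v),
# task (tau), and the method's free parameters (iterations l, learning rate
# eta, perplexity epsilon), each executed as DR -> out-of-sample -> SVM ->
# performance indices and scored by the quality ratio.

#' Grid of experiment parameter values
#'
#' Default value lists reproduce the study's cardinalities: 7 preprocessing
#' combinations x 4 tasks for PCA (28 experiments), x 5 iteration values x 5
#' learning rates for Sammon's mapping (700), and additionally x 5
#' perplexities for t-SNE (3,500).
#'
#' @param v Preprocessing combination names (see [preprocess_combinations()]).
#' @param tau Task names.
#' @param l_sammon,l_tsne Iteration counts per method.
#' @param eta Learning rates.
#' @param epsilon t-SNE perplexities.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(v = names(preprocess_combinations()),
                      tau = TASKS,
                      l_sammon = c(423, 575, 742, 1080, 5000),
                      l_tsne = c(1000, 2000, 3000, 4000, 5000),
                      eta = c(0.2, 0.3, 0.4, 0.5, 0.6),
                      epsilon = c(5, 10, 16, 21, 27)) {
  structure(list(v = v, tau = tau, l_sammon = l_sammon, l_tsne = l_tsne,
                 eta = eta, epsilon = epsilon),
            class = "grid_spec")
}

#' Enumerate experiment configurations for one method
#'
#' Full Cartesian product of the parameter lists relevant to the method, in
#' deterministic order and deduplicated ("experiments without repetition");
#' parameters a method does not use are NA.
#'
#' @param spec A [grid_spec()].
#' @param method `"PCA"`, `"Sammon"` or `"t-SNE"`.
#' @return Data frame with columns `method`, `v`, `tau`, `l`, `eta`,
#'   `epsilon`.
#' @export
enumerate_configs <- function(spec = grid_spec(),
                              method = c("PCA", "Sammon", "t-SNE")) {
  method <- match.arg(method)
  if (!length(spec$v) || !length(spec$tau))
    stop("empty value list for a required parameter")
  grid <- switch(method,
    PCA = expand.grid(v = spec$v, tau = spec$tau,
                      l = NA_real_, eta = NA_real_, epsilon = NA_real_,
                      stringsAsFactors = FALSE),
    Sammon = {
      if (!length(spec$l_sammon) || !length(spec$eta))
        stop("empty value list for a required parameter")
      expand.grid(v = spec$v, tau = spec$tau, l = spec$l_sammon,
                  eta = spec$eta, epsilon = NA_real_,
                  stringsAsFactors = FALSE)
    },
    `t-SNE` = {
      if (!length(spec$l_tsne) || !length(spec$eta) ||
            !length(spec$epsilon))
        stop("empty value list for a required parameter")
      expand.grid(v = spec$v, tau = spec$tau, l = spec$l_tsne,
                  eta = spec$eta, epsilon = spec$epsilon,
                  stringsAsFactors = FALSE)
    })
  grid <- unique(grid)
  out <- cbind(data.frame(method = method, stringsAsFactors = FALSE), grid)
  rownames(out) <- NULL
  out
}

# deterministic seed from a configuration's content (order-independent grid)
.config_hash <- function(config) {
  s <- paste(config$method, config$v, config$tau, config$l, config$eta,
             config$epsilon, sep = "|")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# select the columns of one preprocessing combination from a (standardized)
# feature matrix built with all three methods
.fm_select_methods <- function(fm, methods) {
  keep <- sub("\\..*$", "", colnames(fm$values)) %in% methods
  fm$values <- fm$values[, keep, drop = FALSE]
  fm$methods <- methods
  fm
}

#' Prepare standardized splits for every (combination, task) cell
#'
#' Builds the full FS-IA-IF feature matrix once per task, standardizes and
#' splits it (the per-combination matrices are column subsets, and z-scoring
#' is columnwise, so this is exact), and returns a list of `split_dataset`s
#' keyed `"v|tau"`.
#'
#' @param cohort A `motor_cohort`.
#' @param v Combination names.
#' @param tau Tasks.
#' @param train_fraction,seed,split_first Passed to
#'   [standardize_and_split()].
#' @param ... Passed to [build_feature_matrix()].
#' @return Named list of `split_dataset`s.
#' @export
prepare_splits <- function(cohort, v = names(preprocess_combinations()),
                           tau = TASKS, train_fraction = 0.9, seed = 1L,
                           split_first = FALSE, ...) {
  combos <- preprocess_combinations()
  stopifnot(all(v %in% names(combos)))
  out <- list()
  for (task in tau) {
    fm <- build_feature_matrix(cohort, methods = c("FS", "IA", "IF"),
                               task = task, ...)
    sp <- standardize_and_split(fm, train_fraction = train_fraction,
                                seed = seed, split_first = split_first)
    for (vv in v) {
      spv <- sp
      spv$train <- .fm_select_methods(sp$train, combos[[vv]])
      spv$test <- .fm_select_methods(sp$test, combos[[vv]])
      out[[paste(vv, task, sep = "|")]] <- spv
    }
  }
  out
}

#' Run one grid experiment
#'
#' Executes the four pipeline steps for one configuration: (1) reduce the
#' training features to 2-D with the configured method; (2) fit the
#' out-of-sample mapper and project the test features; (3) train the
#' one-vs-all SVM on the training map, with leave-one-out cross-validation;
#' (4) compute the performance indices (confusions, per-class R_TP, OSR for
#' LOOCV and test, QR).
#'
#' @param config One-row data frame from [enumerate_configs()] (or a list
#'   with the same fields).
#' @param split A `split_dataset` whose features match `config$v` and
#'   `config$tau`.
#' @param seed Seed for the stochastic stages (t-SNE init, OOS init).
#' @param oos_control List of overrides for [fit_oos_mapper()].
#' @param svm_control List of overrides for [svm_ova()]/[loocv()].
#' @return An object of class `experiment_result`.
#' @export
run_experiment <- function(config, split, seed = 1L,
                           oos_control = list(), svm_control = list()) {
  stopifnot(inherits(split, "split_dataset"))
  X_tr <- split$train$values
  y_tr <- droplevels(split$train$labels)
  X_te <- split$test$values
  y_te <- droplevels(split$test$labels)
  emb <- switch(as.character(config$method),
    PCA = pca_map(X_tr),
    Sammon = sammon_map(X_tr, iterations = config$l,
                        learning_rate = config$eta),
    `t-SNE` = tsne_map(X_tr, iterations = config$l,
                       learning_rate = config$eta,
                       perplexity = config$epsilon, seed = seed),
    stop("unknown method ", config$method))
  oos_args <- utils::modifyList(list(X_train = X_tr, Y_train = emb,
                                     seed = seed), oos_control)
  mapper <- do.call(fit_oos_mapper, oos_args)
  Y_te <- predict(mapper, X_te)

  ks <- if (!is.null(svm_control$kernel_scale)) svm_control$kernel_scale
        else 0.35
  cost <- if (!is.null(svm_control$cost)) svm_control$cost else 1
  # the kernel scale is relative to standardized map coordinates; embeddings
  # differ by orders of magnitude in raw spread across methods
  ctr <- colMeans(emb$coordinates)
  scl <- apply(emb$coordinates, 2, stats::sd)
  scl[scl == 0] <- 1
  Z_tr <- sweep(sweep(emb$coordinates, 2, ctr), 2, scl, "/")
  Z_te <- sweep(sweep(Y_te, 2, ctr), 2, scl, "/")
  cv <- loocv(Z_tr, y_tr, kernel_scale = ks, cost = cost)
  fit <- svm_ova(Z_tr, y_tr, kernel_scale = ks, cost = cost)
  pred_te <- predict(fit, Z_te)
  cm_te <- confusion_matrix(pred_te, y_te, levels = levels(y_tr))
  osr_ts <- osr(cm_te)
  structure(list(config = as.list(config),
                 embedding = emb,
                 mapper_R = mapper$R, mapper_mse = mapper$mse,
                 confusion_loocv = cv$confusion,
                 confusion_test = cm_te,
                 r_tp_loocv = cv$r_tp,
                 r_tp_test = true_positive_rates(cm_te),
                 decisions_loocv = cv$decisions,
                 osr_loocv = cv$osr,
                 osr_test = osr_ts,
                 qr = quality_ratio(cv$osr, osr_ts)),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf(
    "Experiment %s (v=%s, tau=%s, l=%s, eta=%s, eps=%s): OSR LOOCV %.2f%%, OSR test %.2f%%, QR %.2f%%\n",
    x$config$method, x$config$v, x$config$tau,
    format(x$config$l), format(x$config$eta), format(x$config$epsilon),
    x$osr_loocv, x$osr_test, x$qr))
  invisible(x)
}

#' Run a grid of experiments
#'
#' Runs every configuration against its prepared split. Per-configuration
#' seeds derive from the master seed and a hash of the configuration
#' content, so results do not depend on execution order. A failing
#' configuration is recorded (with its error message) and the grid
#' continues.
#'
#' @param configs Data frame of configurations ([enumerate_configs()] rows,
#'   possibly concatenated over methods).
#' @param splits Named list from [prepare_splits()] (keys `"v|tau"`), or a
#'   function `(v, tau)` returning a `split_dataset`.
#' @param master_seed Master seed.
#' @param oos_control,svm_control Passed to [run_experiment()].
#' @param verbose Print one line per configuration.
#' @return List of class `grid_result`: `results` (list of
#'   `experiment_result` or failure records) and `summary` (one row per
#'   configuration with OSRs, QR and an `ok` flag).
#' @export
run_grid <- function(configs, splits, master_seed = 1L,
                     oos_control = list(), svm_control = list(),
                     verbose = FALSE) {
  get_split <- if (is.function(splits)) splits
               else function(v, tau) splits[[paste(v, tau, sep = "|")]]
  results <- vector("list", nrow(configs))
  rows <- vector("list", nrow(configs))
  for (i in seq_len(nrow(configs))) {
    cfg <- configs[i, , drop = FALSE]
    seed_i <- .substream(master_seed, .config_hash(cfg))
    res <- tryCatch({
      sp <- get_split(cfg$v, cfg$tau)
      if (is.null(sp)) stop("no split for ", cfg$v, "|", cfg$tau)
      run_experiment(cfg, sp, seed = seed_i,
                     oos_control = oos_control,
                     svm_control = svm_control)
    }, error = function(e) {
      structure(list(config = as.list(cfg), error = conditionMessage(e)),
                class = "experiment_failure")
    })
    results[[i]] <- res
    ok <- inherits(res, "experiment_result")
    rows[[i]] <- data.frame(
      cfg, seed = seed_i, ok = ok,
      osr_loocv = if (ok) res$osr_loocv else NA_real_,
      osr_test = if (ok) res$osr_test else NA_real_,
      qr = if (ok) res$qr else NA_real_,
      oos_R = if (ok) res$mapper_R else NA_real_,
      stringsAsFactors = FALSE)
    if (verbose) {
      if (ok) print(res)
      else cat(sprintf("Experiment %s (v=%s, tau=%s) FAILED: %s\n",
                       cfg$method, cfg$v, cfg$tau, res$error))
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("Grid run: %d configurations (%d failed)\n",
              nrow(x$summary), sum(!x$summary$ok)))
  agg <- stats::aggregate(qr ~ method, data = x$summary[x$summary$ok, ],
                          FUN = mean)
  names(agg)[2] <- "mean_qr"
  print(agg)
  invisible(x)
}

#' Select the best configuration per cell
#'
#' Argmax of QR within each (task, method) cell (the selection behind the
#' best-scenario table); ties break to fewer iterations, then to
#' lexicographic configuration order.
#'
#' @param grid A `grid_result` (or its `summary` data frame).
#' @param group_by Columns defining the cells.
#' @return Data frame with one winning row per cell.
#' @export
select_best <- function(grid, group_by = c("tau", "method")) {
  df <- if (inherits(grid, "grid_result")) grid$summary else grid
  if ("ok" %in% names(df)) df <- df[df$ok, , drop = FALSE]
  df <- df[!is.na(df$qr), , drop = FALSE]
  if (!nrow(df)) stop("no successful results to select from")
  key <- interaction(df[group_by], drop = TRUE)
  picked <- lapply(split(df, key), function(d) {
    l_ord <- ifelse(is.na(d$l), 0, d$l)
    d[order(-d$qr, l_ord, d$v, d$eta, d$epsilon), , drop = FALSE][1, ]
  })
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  out[order(out$tau, out$method), ]
}
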