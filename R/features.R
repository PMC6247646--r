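# Preprocessing (filtered signal, instantaneous amplitude/frequency from the
# analytic signal) and the 12 time-domain features per channel.

PREPROCESS_METHODS <- c("FS", "IA", "IF")
FEATURE_NAMES <- c("MAV", "RMS", "PEAK", "MAVSDN", "MAVSD", "MAVFDN",
                   "MAVFD", "INTERQ_RANGE", "RANGE", "STD", "VAR", "ApEn")

#' Admissible preprocessing combinations
#'
#' The seven admissible sets of preprocessing methods: each of FS (filtered
#' signal), IA (instantaneous amplitude), IF (instantaneous frequency) alone
#' and all their combinations.
#'
#' @return Named list of character vectors.
#' @export
preprocess_combinations <- function() {
  list(FS = "FS", IA = "IA", IF = "IF",
       `FS-IA` = c("FS", "IA"), `FS-IF` = c("FS", "IF"),
       `IA-IF` = c("IA", "IF"), `FS-IA-IF` = c("FS", "IA", "IF"))
}

# analytic signal via the frequency-domain one-sided spectrum
.analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

.unwrap <- function(p) {
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  c(p[1], p[1] + cumsum(dp))
}

#' Instantaneous amplitude and frequency via the Hilbert transform
#'
#' Forms the analytic signal of `x` and returns its magnitude (IA) and the
#' scaled derivative of its unwrapped phase (IF, in Hz, by central differences
#' in the interior and one-sided differences at the ends).
#'
#' @param x Finite numeric series, length >= 8.
#' @param sample_rate Sampling rate in Hz.
#' @return List with elements `ia` (>= 0) and `if_hz`, both the length of `x`.
#' @export
hilbert_ia_if <- function(x, sample_rate) {
  stopifnot(length(x) >= 8, all(is.finite(x)), sample_rate > 0)
  if (stats::sd(x) == 0) {
    warning("constant series: IA = |offset|, IF defined as 0")
    return(list(ia = rep(abs(x[1]), length(x)),
                if_hz = rep(0, length(x))))
  }
  z <- .analytic(x)
  ia <- Mod(z)
  phase <- .unwrap(Arg(z))
  n <- length(x)
  dphi <- numeric(n)
  dphi[2:(n - 1)] <- (phase[3:n] - phase[1:(n - 2)]) / 2
  dphi[1] <- phase[2] - phase[1]
  dphi[n] <- phase[n] - phase[n - 1]
  list(ia = ia, if_hz = dphi * sample_rate / (2 * pi))
}

#' Euclidean resultant of three axis series
#'
#' @param x,y,z Equal-length numeric series.
#' @return Element-wise Euclidean norm.
#' @export
resultant <- function(x, y, z) {
  if (length(x) != length(y) || length(x) != length(z))
    stop("axis series must have equal lengths")
  sqrt(x^2 + y^2 + z^2)
}

#' Approximate entropy
#'
#' Pincus' ApEn(m, r) with self-matches counted: `Phi_m - Phi_(m+1)` where
#' `Phi_m` is the mean log fraction of length-`m` templates within Chebyshev
#' distance `r`. A regularity statistic: 0 for constant series, larger for
#' irregular ones.
#'
#' @param x Numeric series, length > m + 1.
#' @param m Embedding (template) length.
#' @param r Tolerance; default `0.2 * sd(x)`. A zero-variance series gets a
#'   tolerance floor and returns 0.
#' @return Non-negative scalar.
#' @export
approximate_entropy <- function(x, m = 2L, r = 0.2 * stats::sd(x)) {
  n <- length(x)
  stopifnot(n > m + 1, all(is.finite(x)))
  if (is.na(r) || r <= 0) {
    if (stats::sd(x) == 0) return(0)
    r <- .Machine$double.eps
  }
  max(.apen_core(as.numeric(x), as.integer(m), r), 0)
}

#' Twelve time-domain features of a window
#'
#' Ordered as MAV, RMS, PEAK (global maximum), MAVSDN, MAVSD, MAVFDN, MAVFD
#' (mean absolute second/first differences, the N variants on the z-scored
#' window), interquartile range, range, sample sd, sample variance, and
#' approximate entropy.
#'
#' @param w Finite numeric window, length >= 4.
#' @param apen_m,apen_r_factor ApEn embedding length and tolerance factor
#'   (r = factor * sd(w)).
#' @return Named numeric vector of length 12.
#' @export
extract_features <- function(w, apen_m = 2L, apen_r_factor = 0.2) {
  stopifnot(length(w) >= 4, all(is.finite(w)))
  s <- stats::sd(w)
  wn <- if (s > 0) (w - mean(w)) / s else w * 0
  c(MAV = mean(abs(w)),
    RMS = sqrt(mean(w^2)),
    PEAK = max(w),
    MAVSDN = mean(abs(diff(wn, differences = 2))),
    MAVSD = mean(abs(diff(w, differences = 2))),
    MAVFDN = mean(abs(diff(wn))),
    MAVFD = mean(abs(diff(w))),
    INTERQ_RANGE = unname(stats::IQR(w)),
    RANGE = max(w) - min(w),
    STD = s,
    VAR = stats::var(w),
    ApEn = approximate_entropy(w, m = apen_m, r = apen_r_factor * s))
}

#' Zero-phase low-pass used for the FS preprocessing
#'
#' FFT-domain zero-phase filter with the magnitude response of an
#' `order`-th Butterworth low-pass (|H| = (1 + (f/fc)^(2 order))^(-1/2)).
#' Applied to inertial channels only; EMG envelope channels pass through.
#'
#' @param x Numeric series.
#' @param sample_rate Sampling rate, Hz.
#' @param cutoff Cutoff frequency, Hz.
#' @param order Butterworth order.
#' @return Filtered series, same length.
#' @export
lowpass_fs <- function(x, sample_rate, cutoff = 15, order = 4) {
  n <- length(x)
  f <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1) * sample_rate / n
  g <- 1 / sqrt(1 + (abs(f) / cutoff)^(2 * order))
  Re(stats::fft(stats::fft(x) * g, inverse = TRUE) / n)
}

# preprocess one channel of one recording over one task window, returning the
# FS/IA/IF series (edge-trimmed) actually used for feature extraction
.preprocess_window <- function(rec, channel, task, methods,
                               cutoff = 15, trim = 0.5) {
  w <- rec$task_windows[[task]]
  if (is.null(w)) stop("task window ", task, " absent")
  x <- rec$channels[w["start"]:w["end"], channel]
  if (!length(x)) stop("empty task window ", task)
  fs <- if (grepl("^emg", channel)) x
        else lowpass_fs(x, rec$sample_rate, cutoff = cutoff)
  k <- round(trim * rec$sample_rate)
  keep <- if (2 * k + 4 <= length(fs)) (k + 1):(length(fs) - k)
          else seq_along(fs)
  out <- list()
  if (any(c("IA", "IF") %in% methods)) {
    h <- hilbert_ia_if(fs, rec$sample_rate)
    if ("IA" %in% methods) out$IA <- h$ia[keep]
    if ("IF" %in% methods) out$IF <- h$if_hz[keep]
  }
  if ("FS" %in% methods) out$FS <- fs[keep]
  out[intersect(methods, names(out))]
}

#' Build a feature matrix for one task
#'
#' For every recording, channel and preprocessing method in `methods`, the 12
#' time-domain features are extracted from the chosen task window (after
#' zero-phase filtering and 0.5 s edge trimming to suppress Hilbert end
#' effects), giving D = 12 x 34 x |methods| columns: 408, 816 or 1224.
#'
#' @param cohort A `motor_cohort` or list of `raw_recording`s.
#' @param methods Subset of `c("FS","IA","IF")` (see
#'   [preprocess_combinations()]).
#' @param task One of `"T1".."T4"`.
#' @param cutoff FS low-pass cutoff, Hz.
#' @param trim Edge trim in seconds applied after preprocessing.
#' @param apen_m,apen_r_factor Passed to [extract_features()].
#' @return An object of class `feature_matrix`: list with `values`
#'   (samples x D), `labels` (group factor), `subject`, `repetition`, `task`,
#'   `methods`.
#' @export
build_feature_matrix <- function(cohort, methods = "FS", task = "T1",
                                 cutoff = 15, trim = 0.5,
                                 apen_m = 2L, apen_r_factor = 0.2) {
  recs <- if (inherits(cohort, "motor_cohort")) cohort$recordings else cohort
  task <- match.arg(task, TASKS)
  methods <- PREPROCESS_METHODS[PREPROCESS_METHODS %in% methods]
  if (!length(methods)) stop("methods must contain at least one of FS/IA/IF")
  channels <- colnames(recs[[1]]$channels)
  if (!identical(channels, channel_layout()))
    stopifnot(length(channels) == 34)
  col_names <- as.vector(vapply(methods, function(m)
    as.vector(vapply(channels, function(ch)
      paste(m, ch, FEATURE_NAMES, sep = "."), character(12))),
    character(12 * length(channels))))
  rows <- lapply(recs, function(rec) {
    stopifnot(identical(colnames(rec$channels), channels))
    per_ch <- lapply(channels, function(chn) {
      ser <- .preprocess_window(rec, chn, task, methods,
                                cutoff = cutoff, trim = trim)
      lapply(ser, extract_features, apen_m = apen_m,
             apen_r_factor = apen_r_factor)
    })
    unlist(lapply(methods, function(m)
      unlist(lapply(per_ch, `[[`, m), use.names = FALSE)),
      use.names = FALSE)
  })
  values <- do.call(rbind, rows)
  colnames(values) <- col_names
  stopifnot(!anyNA(values))
  structure(list(
    values = values,
    labels = factor(vapply(recs, function(r) r$subject$group, ""),
                    levels = GROUPS),
    subject = vapply(recs, function(r) r$subject$subject_id, 1L),
    repetition = vapply(recs, function(r) r$repetition, 1L),
    task = task,
    methods = methods
  ), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d samples x %d features (%s, task %s)\n",
              nrow(x$values), ncol(x$values),
              paste(x$methods, collapse = "-"), x$task))
  print(table(x$labels))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

# subset rows of a feature matrix, keeping metadata aligned
.fm_subset <- function(fm, idx) {
  structure(list(values = fm$values[idx, , drop = FALSE],
                 labels = fm$labels[idx],
                 subject = fm$subject[idx],
                 repetition = fm$repetition[idx],
                 task = fm$task, methods = fm$methods),
            class = "feature_matrix")
}

#' Write / read a feature matrix as CSV
#'
#' Columns are the feature identifiers plus `label`, `task`, `subject`,
#' `repetition` metadata columns.
#'
#' @param fm A `feature_matrix`.
#' @param path CSV path.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(label = fm$labels, task = fm$task, subject = fm$subject,
                   repetition = fm$repetition, check.names = FALSE)
  df <- cbind(df, as.data.frame(fm$values, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- c("label", "task", "subject", "repetition")
  vals <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  methods <- unique(sub("\\..*$", "", colnames(vals)))
  structure(list(values = vals,
                 labels = factor(df$label, levels = GROUPS),
                 subject = df$subject, repetition = df$repetition,
                 task = df$task[1],
                 methods = methods[methods %in% PREPROCESS_METHODS]),
            class = "feature_matrix")
}

#' Import a precomputed feature table
#'
#' Reads a deposited table of feature vectors with group labels (CSV, or XLSX
#' when the readxl package is available) into a `feature_matrix`. All
#' non-metadata numeric columns are taken as features.
#'
#' @param path File path (`.csv` or `.xlsx`).
#' @param label_col Name of the group-label column.
#' @param task Task tag for the resulting matrix.
#' @param sheet Sheet index or name for XLSX input.
#' @return A `feature_matrix`.
#' @export
read_supplementary_features <- function(path, label_col = "label",
                                        task = "T1", sheet = 1) {
  df <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("XLSX import requires the readxl package; convert to CSV instead")
    as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else utils::read.csv(path, check.names = FALSE)
  if (!label_col %in% names(df)) stop("label column '", label_col,
                                      "' not found")
  labels <- factor(df[[label_col]], levels = GROUPS)
  if (anyNA(labels)) stop("labels must be among ",
                          paste(GROUPS, collapse = ", "))
  meta <- intersect(c(label_col, "task", "subject", "repetition"), names(df))
  vals <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  storage.mode(vals) <- "double"
  if (anyNA(vals)) stop("feature table contains missing values")
  structure(list(values = vals, labels = labels,
                 subject = if ("subject" %in% names(df)) df$subject
                           else seq_len(nrow(vals)),
                 repetition = if ("repetition" %in% names(df)) df$repetition
                              else rep(1L, nrow(vals)),
                 task = task, methods = character()),
            class = "feature_matrix")
}
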