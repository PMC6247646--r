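# Shared fixtures, built once per test run and memoized (the default cohort
# and its feature splits are the expensive pieces).

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# the default calibrated cohort: 38 subjects x 5 repetitions, seed 1
default_cohort <- function() {
  fixture("cohort", function() generate_cohort(cohort_spec(seed = 1L)))
}

# tiny cohort (one subject per group, one repetition) for structural tests
tiny_cohort <- function() {
  fixture("tiny_cohort", function() suppressWarnings(
    generate_cohort(cohort_spec(n_per_group = c(S_H = 1L, S_PD = 1L,
                                                S_DBS = 1L),
                                repetitions = 1L, seed = 4L))))
}

# standardized 90/10 splits of the default cohort for the reduced grid
grid_splits <- function() {
  fixture("splits", function() suppressWarnings(
    prepare_splits(default_cohort(), v = c("FS", "FS-IF"),
                   tau = c("T1", "T4"), seed = 1L)))
}

# reduced grid over both tasks and two preprocessing sets, all three methods
mini_grid <- function() {
  fixture("mini_grid", function() {
    configs <- rbind(
      expand.grid(method = "PCA", v = c("FS", "FS-IF"), tau = c("T1", "T4"),
                  l = NA_real_, eta = NA_real_, epsilon = NA_real_,
                  stringsAsFactors = FALSE),
      expand.grid(method = "Sammon", v = c("FS", "FS-IF"),
                  tau = c("T1", "T4"), l = 423, eta = 0.4,
                  epsilon = NA_real_, stringsAsFactors = FALSE),
      expand.grid(method = "t-SNE", v = c("FS", "FS-IF"),
                  tau = c("T1", "T4"), l = 1000, eta = 0.5, epsilon = 16,
                  stringsAsFactors = FALSE))
    run_grid(configs, grid_splits(), master_seed = 1L)
  })
}

# a labelled random feature matrix (no signal) for split/bookkeeping tests
synthetic_feature_matrix <- function(n_per_group = c(S_H = 50, S_PD = 80,
                                                     S_DBS = 60),
                                     d = 4, seed = 99) {
  set.seed(seed)
  n <- sum(n_per_group)
  structure(list(
    values = matrix(rnorm(n * d), n, d,
                    dimnames = list(NULL, paste0("FS.ch.f", seq_len(d)))),
    labels = factor(rep(names(n_per_group), n_per_group),
                    levels = c("S_H", "S_PD", "S_DBS")),
    subject = rep(seq_along(n_per_group), n_per_group),
    repetition = unlist(lapply(n_per_group, seq_len)),
    task = "T1", methods = "FS"), class = "feature_matrix")
}

# a minimal hand-built recording with constant channels (for CV arithmetic)
constant_recording <- function(value, subject_id, group, repetition,
                               n = 80, sample_rate = 50) {
  ch <- matrix(value, n, 34, dimnames = list(NULL, channel_layout()))
  prof <- structure(list(subject_id = as.integer(subject_id), group = group,
                         tremor_amplitude = 0, tremor_frequency = 6,
                         bradykinesia_factor = 1, baseline_emg_level = 0.3,
                         intra_subject_noise = 0),
                    class = "subject_profile")
  structure(list(subject = prof, repetition = as.integer(repetition),
                 sample_rate = sample_rate, channels = ch,
                 task_windows = list(T1 = c(start = 1L, end = n %/% 4),
                                     T2 = c(start = n %/% 4 + 1L,
                                            end = n %/% 2),
                                     T3 = c(start = n %/% 2 + 1L,
                                            end = 3L * (n %/% 4)),
                                     T4 = c(start = 3L * (n %/% 4) + 1L,
                                            end = n))),
            class = "raw_recording")
}
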