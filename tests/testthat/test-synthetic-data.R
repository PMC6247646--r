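# Synthetic cohort generator: structure, determinism, tremor content, and
# the coefficient-of-variation calibration.

test_that("default cohort has the study's size and group structure", {
  co <- default_cohort()
  expect_length(co$recordings, 190)
  sid <- vapply(co$recordings, function(r) r$subject$subject_id, 1L)
  expect_length(unique(sid), 38)
  grp <- vapply(co$recordings, function(r) r$subject$group, "")
  expect_equal(as.vector(table(factor(grp, levels = c("S_H", "S_PD",
                                                      "S_DBS")))),
               c(50, 80, 60))
})

test_that("generation is deterministic and minimal specs work", {
  # departing from the 5-repetition design is allowed but warned about
  expect_warning(
    spec <- cohort_spec(n_per_group = c(S_H = 2L, S_PD = 1L, S_DBS = 1L),
                        repetitions = 2L, seed = 7L),
    "5 repetitions")
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$recordings, b$recordings)

  one <- generate_cohort(suppressWarnings(
    cohort_spec(n_per_group = c(S_H = 1L, S_PD = 0L, S_DBS = 0L),
                repetitions = 1L, seed = 1L)))
  expect_length(one$recordings, 1)
  expect_equal(one$recordings[[1]]$subject$group, "S_H")
  expect_error(cohort_spec(n_per_group = c(S_H = 0L, S_PD = 0L,
                                           S_DBS = 0L)),
               "sum to at least 1")
})

test_that("recordings satisfy the channel and window invariants", {
  co <- tiny_cohort()
  for (rec in co$recordings) {
    expect_identical(colnames(rec$channels), channel_layout())
    expect_equal(ncol(rec$channels), 34)
    expect_true(all(rec$channels[, c("emg_flexor", "emg_extensor")] >= 0))
    # windows ordered T1..T4, non-overlapping, covering the recording
    w <- rec$task_windows
    expect_equal(w$T1[["start"]], 1L)
    expect_equal(w$T4[["end"]], nrow(rec$channels))
    for (k in 1:3)
      expect_equal(w[[k + 1]][["start"]], w[[k]][["end"]] + 1L)
    # resultant channels are the axis norms
    axes <- rec$channels[, paste0("hand_acc_", c("x", "y", "z"))]
    expect_equal(rec$channels[, "hand_acc_res"],
                 sqrt(rowSums(axes^2)), tolerance = 1e-12)
  }
})

test_that("rest-window spectra carry the tremor line only for PD groups", {
  spec <- cohort_spec(seed = 3L)
  peak_freq <- function(x, fs) {
    x <- x - mean(x)
    sp <- Mod(fft(x))[2:(length(x) %/% 2)]
    ((2:(length(x) %/% 2)) - 1)[which.max(sp)] * fs / length(x)
  }
  for (i in 1:3) {
    prof_pd <- subject_profile(spec, "S_PD", 10 + i)
    rec <- generate_task_sequence(prof_pd, 1, seed = 100 + i)
    w <- rec$task_windows$T4
    # strongest tremor-loaded accelerometer axis
    ax <- which.max(abs(prof_pd$axis_w[, 1]))
    x <- rec$channels[w["start"]:w["end"],
                      paste0("hand_acc_", c("x", "y", "z"))[ax]]
    expect_lt(abs(peak_freq(x, rec$sample_rate) - prof_pd$tremor_frequency),
              1)

    prof_h <- subject_profile(spec, "S_H", i)
    expect_equal(prof_h$tremor_amplitude, 0)
    rec_h <- generate_task_sequence(prof_h, 1, seed = 200 + i)
    xh <- rec_h$channels[w["start"]:w["end"],
                         paste0("hand_acc_", c("x", "y", "z"))[ax]]
    xh <- xh - mean(xh)
    sp <- Mod(fft(xh))[2:(length(xh) %/% 2)]^2
    fr <- ((2:(length(xh) %/% 2)) - 1) * rec_h$sample_rate / length(xh)
    band <- fr > 5 & fr < 7
    # no 6 Hz line above the noise floor at rest for healthy subjects
    expect_lt(max(sp[band]), 10 * median(sp))
  }
})

test_that("raising tremor amplitude raises rest-window variance", {
  spec <- cohort_spec()
  diffs <- vapply(1:20, function(s) {
    prof <- subject_profile(spec, "S_PD", 11)
    lo <- prof; lo$tremor_amplitude <- 0.4
    hi <- prof; hi$tremor_amplitude <- 1.2
    v <- vapply(list(lo, hi), function(p) {
      rec <- generate_task_sequence(p, 1, seed = s, task_duration = 4)
      w <- rec$task_windows$T4
      var(rec$channels[w["start"]:w["end"], "hand_acc_x"])
    }, 1.0)
    v[2] - v[1]
  }, 1.0)
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.9)
})

test_that("compute_cv matches direct arithmetic and handles edge cases", {
  # identical repetitions: sd = 0 so CV = 0
  recs <- lapply(1:2, function(r) constant_recording(2, 1, "S_H", r))
  cv0 <- compute_cv(recs)
  expect_equal(cv0$mean_cv, 0)

  # summaries (1,1,1,1,3): CV = sd/mean by the direct formula
  vals <- c(1, 1, 1, 1, 3)
  recs <- lapply(1:5, function(r) constant_recording(vals[r], 2, "S_PD", r))
  cv <- compute_cv(recs)
  expect_equal(cv$mean_cv, sd(vals) / mean(vals), tolerance = 1e-12)

  # zero-mean summary: flagged and excluded
  recs0 <- c(lapply(1:2, function(r) constant_recording(0, 3, "S_H", r)),
             lapply(1:2, function(r) constant_recording(1, 4, "S_H", r)))
  expect_warning(cvz <- compute_cv(recs0), "CV undefined")
  expect_equal(cvz$n_subjects, 1)

  # single repetition is an error
  expect_error(compute_cv(list(constant_recording(1, 5, "S_H", 1))),
               ">= 2 repetitions")
})

test_that("default calibration reproduces the reported per-group CVs", {
  cv <- compute_cv(default_cohort())
  expect_equal(cv$group, c("S_H", "S_PD", "S_DBS"))
  expect_true(all(abs(cv$mean_cv - c(0.21, 0.24, 0.30)) <= 0.05))
})

test_that("cohorts round-trip through CSV plus manifest", {
  dir <- withr::local_tempdir()
  co <- tiny_cohort()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_cohort(dir)
  expect_length(back$recordings, length(co$recordings))
  for (i in seq_along(co$recordings)) {
    expect_equal(back$recordings[[i]]$channels, co$recordings[[i]]$channels,
                 tolerance = 1e-12)
    expect_equal(back$recordings[[i]]$subject$group,
                 co$recordings[[i]]$subject$group)
    expect_equal(back$recordings[[i]]$task_windows,
                 co$recordings[[i]]$task_windows)
  }
})
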