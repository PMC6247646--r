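# Synthetic cohort simulator: seeded multichannel recordings of the four-task
# motor sequence (finger taps, finger-to-nose, pronation/supination, rest) for
# three groups: healthy (S_H), PD on levodopa (S_PD), PD on DBS (S_DBS).

GROUPS <- c("S_H", "S_PD", "S_DBS")
TASKS <- c("T1", "T2", "T3", "T4")

# unbiasing constant c4 for the sd of n samples; repetitions are 5 by design
.c4 <- function(n) sqrt(2 / (n - 1)) * gamma(n / 2) / gamma((n - 1) / 2)

#' Channel layout of a recording
#'
#' Names of the 34 channels of a synthetic recording: 18 inertial axis channels
#' (2 sensor units x 3 modalities x 3 axes), 6 per-modality resultants, 2 EMG
#' envelope channels, and 8 auxiliary derived channels (6 first-difference
#' "jerk" channels of the resultants plus EMG sum and difference).
#'
#' @return Character vector of length 34.
#' @export
channel_layout <- function() {
  units <- c("hand", "fore")
  mods <- c("acc", "gyr", "mag")
  axis_ch <- as.vector(t(outer(
    paste(rep(units, each = 3), rep(mods, 2), sep = "_"),
    c("x", "y", "z"), paste, sep = "_")))
  res_ch <- paste(rep(units, each = 3), rep(mods, 2), "res", sep = "_")
  jerk_ch <- paste(rep(units, each = 3), rep(mods, 2), "jerk", sep = "_")
  c(axis_ch, res_ch, c("emg_flexor", "emg_extensor"),
    jerk_ch, c("emg_sum", "emg_diff"))
}

#' Specification of a synthetic cohort
#'
#' Describes the cohort the simulator generates: group sizes (default 10
#' healthy, 16 levodopa-treated, 12 DBS-treated; 38 subjects in total), five
#' repetitions of the four-task sequence per subject (190 recordings), and the
#' group-level effect sizes for tremor, bradykinesia, muscle tone and
#' intra-subject variability.
#'
#' The per-repetition amplitude scale is lognormal; its dispersion is set per
#' group so that the coefficient of variation of a per-repetition RMS summary,
#' estimated from 5 repetitions, is centred on `cv_target` (0.21 / 0.24 /
#' 0.30). The small-sample bias of the sd estimator is corrected with the
#' c4(5) constant.
#'
#' @param n_per_group Named integer vector, subjects per group (S_H, S_PD, S_DBS).
#' @param repetitions Repetitions of the task sequence per subject; the study
#'   design uses 5 and other values raise a warning.
#' @param seed Integer master seed; every draw derives from it.
#' @param tremor_amplitude Group-level rest-tremor amplitude (signal units);
#'   0 for the healthy group.
#' @param tremor_frequency Centre of the tremor band in Hz (rest tremor is
#'   classically near 6 Hz).
#' @param bradykinesia Group-level slowing factor (>= 1): task rhythms are
#'   slowed and scaled down by this factor.
#' @param baseline_emg Group-level EMG envelope baseline (muscle tone).
#' @param cv_target Per-group target coefficient of variation of the
#'   repetition summary.
#' @param subject_jitter Lognormal sd of subject-level deviations from the
#'   group effect sizes.
#' @param noise_sd White measurement-noise sd (signal units).
#' @param task_duration Duration of each task window in seconds.
#' @param sample_rate Sampling rate in Hz (the study hardware digitized at 50).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(S_H = 10L, S_PD = 16L, S_DBS = 12L),
                        repetitions = 5L,
                        seed = 1L,
                        tremor_amplitude = c(S_H = 0, S_PD = 1.0, S_DBS = 0.45),
                        tremor_frequency = 6,
                        bradykinesia = c(S_H = 1, S_PD = 1.35, S_DBS = 1.15),
                        baseline_emg = c(S_H = 0.30, S_PD = 0.50, S_DBS = 0.40),
                        cv_target = c(S_H = 0.21, S_PD = 0.24, S_DBS = 0.30),
                        subject_jitter = 0.5,
                        noise_sd = 0.05,
                        task_duration = 10,
                        sample_rate = 50) {
  n_per_group <- as.integer(n_per_group)
  names(n_per_group) <- GROUPS
  if (any(n_per_group < 0) || sum(n_per_group) < 1)
    stop("group counts must be non-negative and sum to at least 1")
  if (repetitions < 1) stop("repetitions must be positive")
  if (repetitions != 5L)
    warning("the study design uses 5 repetitions per subject; got ",
            repetitions)
  stopifnot(all(tremor_amplitude >= 0), all(bradykinesia >= 1),
            all(cv_target >= 0), task_duration > 0, sample_rate > 0)
  structure(list(
    n_per_group = n_per_group,
    repetitions = as.integer(repetitions),
    seed = as.integer(seed),
    tremor_amplitude = tremor_amplitude,
    tremor_frequency = tremor_frequency,
    bradykinesia = bradykinesia,
    baseline_emg = baseline_emg,
    cv_target = cv_target,
    subject_jitter = subject_jitter,
    noise_sd = noise_sd,
    task_duration = task_duration,
    sample_rate = sample_rate
  ), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat(sprintf("  subjects: %s (total %d), %d repetitions each\n",
              paste(sprintf("%s=%d", GROUPS, x$n_per_group), collapse = ", "),
              sum(x$n_per_group), x$repetitions))
  cat(sprintf("  %d channels at %g Hz, 4 x %g s task windows, seed %d\n",
              length(channel_layout()), x$sample_rate, x$task_duration,
              x$seed))
  invisible(x)
}

# deterministic substream seed (kept below 2^31 - 1)
.substream <- function(seed, a, b = 0L) {
  as.integer((as.numeric(seed) %% 2147483647 * 31 +
                as.numeric(a) * 1000003 + as.numeric(b) * 7919) %% 2147483647)
}

#' Draw a subject profile
#'
#' Subject-level parameters are the group effect sizes perturbed by a
#' lognormal jitter, drawn from a per-subject substream of the cohort seed so
#' that adding a subject never shifts the draws of another.
#'
#' @param spec A [cohort_spec()].
#' @param group One of `"S_H"`, `"S_PD"`, `"S_DBS"`.
#' @param subject_id Integer subject identifier.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(spec, group, subject_id) {
  group <- match.arg(group, GROUPS)
  old <- .Random.seed_guard(.substream(spec$seed, subject_id))
  on.exit(old(), add = TRUE)
  jit <- function(s) exp(stats::rnorm(1, -s^2 / 2, s))
  j <- spec$subject_jitter
  amp <- spec$tremor_amplitude[[group]]
  cv <- spec$cv_target[[group]]
  structure(list(
    subject_id = as.integer(subject_id),
    group = group,
    tremor_amplitude = if (amp > 0) amp * jit(j) else 0,
    tremor_frequency = min(7.5, max(4.5,
      stats::rnorm(1, spec$tremor_frequency, 0.3))),
    bradykinesia_factor = 1 + (spec$bradykinesia[[group]] - 1) * jit(j),
    baseline_emg_level = spec$baseline_emg[[group]] * jit(0.1),
    # lognormal sigma giving E[cv-hat] ~ cv_target across 5 repetitions
    intra_subject_noise = sqrt(log(1 + (cv / .c4(5))^2)),
    movement_phase = stats::runif(3, 0, 2 * pi),
    # subject-stable signatures: individual task-rhythm rates, waveform
    # harmonic content, and sensor-frame orientations (donning variation);
    # these make repetitions of one subject local neighbors in feature space
    freq_jitter = exp(stats::rnorm(3, 0, 0.15)),
    harmonic = stats::runif(1, 0.2, 0.6),
    axis_w = apply(matrix(stats::rnorm(18), 3, 6), 2,
                   function(v) v / sqrt(sum(v^2))),
    gravity = {
      g <- stats::rnorm(3)
      g / sqrt(sum(g^2))
    }
  ), class = "subject_profile")
}

# save/restore .Random.seed while seeding a substream
.Random.seed_guard <- function(seed) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
}

# movement amplitude [modality x task] and rhythm frequency per task (Hz);
# rest (T4) has no voluntary movement
.MOVE_AMP <- matrix(c(
  1.2, 0.8, 0.6, 0,    # acc
  0.5, 0.7, 1.3, 0,    # gyr
  0.2, 0.5, 0.8, 0),   # mag
  nrow = 3, byrow = TRUE, dimnames = list(c("acc", "gyr", "mag"), TASKS))
.MOVE_FREQ <- c(T1 = 2.0, T2 = 0.5, T3 = 1.5, T4 = 0)
.UNIT_FACTOR <- matrix(c(
  1.0, 1.0, 1.0, 1.0,  # hand
  0.6, 0.7, 1.2, 1.0), # forearm
  nrow = 2, byrow = TRUE, dimnames = list(c("hand", "fore"), TASKS))
.EMG_BURST <- c(T1 = 0.8, T2 = 0.6, T3 = 0.7, T4 = 0)
# rest tremor is attenuated during voluntary action
.TREMOR_W <- c(T1 = 0.4, T2 = 0.4, T3 = 0.4, T4 = 1.0)
# accelerometer gravity magnitude (signal units); the per-subject direction
# lives in the profile. The constant offset keeps acc resultants oscillating
# near the tremor frequency rather than at its rectified double.
.GRAVITY_MAG <- 1.0

#' Generate one recording of the four-task sequence
#'
#' Simulates one repetition of the motor sequence for a subject: each task
#' window holds a task-specific rhythm whose period and amplitude are scaled
#' by the bradykinesia factor, a tremor sinusoid near the subject's tremor
#' frequency (full amplitude at rest, attenuated during action), white
#' measurement noise, and rectified burst-train EMG envelopes synchronized to
#' the rhythm. A lognormal per-repetition gain models run-to-run variability.
#'
#' @param profile A [subject_profile()].
#' @param repetition Repetition index (1-based).
#' @param seed Integer seed for this recording.
#' @param task_duration Seconds per task window.
#' @param sample_rate Sampling rate in Hz.
#' @param noise_sd Measurement noise sd.
#' @return An object of class `raw_recording` with a `samples x 34` channel
#'   matrix, task windows, and the generating profile.
#' @export
generate_task_sequence <- function(profile, repetition = 1L, seed = 1L,
                                   task_duration = 10, sample_rate = 50,
                                   noise_sd = 0.05) {
  stopifnot(inherits(profile, "subject_profile"))
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)

  n_task <- round(task_duration * sample_rate)
  n <- 4L * n_task
  t <- (seq_len(n) - 1) / sample_rate
  task_windows <- lapply(seq_along(TASKS), function(k)
    c(start = (k - 1L) * n_task + 1L, end = k * n_task))
  names(task_windows) <- TASKS
  task_of <- rep(TASKS, each = n_task)

  brady <- profile$bradykinesia_factor
  f_tr <- profile$tremor_frequency
  a_tr <- profile$tremor_amplitude
  rep_scale <- exp(stats::rnorm(1, -profile$intra_subject_noise^2 / 2,
                                profile$intra_subject_noise))
  psi <- stats::runif(1, 0, 2 * pi)           # tremor phase
  tremor_carrier <- sin(2 * pi * f_tr * t + psi)
  trem_w <- .TREMOR_W[task_of]

  ch <- matrix(0, n, 34, dimnames = list(NULL, channel_layout()))
  units <- c("hand", "fore")
  mods <- c("acc", "gyr", "mag")
  for (u in units) {
    for (m in mods) {
      # per-task movement rhythm (slowed and scaled down by bradykinesia),
      # with the subject's own rate and harmonic content
      move <- numeric(n)
      for (task in TASKS) {
        f <- .MOVE_FREQ[[task]] *
          profile$freq_jitter[min(match(task, TASKS), 3)] / brady
        if (f <= 0) next
        a <- .MOVE_AMP[m, task] * .UNIT_FACTOR[u, task] / brady
        idx <- task_of == task
        ph <- profile$movement_phase[match(m, mods)]
        move[idx] <- a * (sin(2 * pi * f * t[idx] + ph) +
                            profile$harmonic *
                              sin(4 * pi * f * t[idx] + 2 * ph))
      }
      trem_gain <- if (m == "mag") 0.3 else 1.0
      trem <- a_tr * trem_gain * trem_w * tremor_carrier
      w_dir <- profile$axis_w[, (match(u, units) - 1) * 3 + match(m, mods)]
      for (k in 1:3) {
        sig <- w_dir[k] * (move + trem) +
          stats::rnorm(n, 0, noise_sd)
        if (m == "acc") sig <- sig + .GRAVITY_MAG * profile$gravity[k]
        ch[, paste(u, m, c("x", "y", "z")[k], sep = "_")] <- sig
      }
    }
  }

  # EMG envelopes: baseline tone + rectified bursts locked to the rhythm +
  # tremor ripple; non-negative by construction
  burst <- numeric(n)
  burst_ext <- numeric(n)
  for (task in TASKS) {
    f <- .MOVE_FREQ[[task]] *
      profile$freq_jitter[min(match(task, TASKS), 3)] / brady
    if (f <= 0) next
    idx <- task_of == task
    ph <- profile$movement_phase[1]
    burst[idx] <- .EMG_BURST[[task]] / brady *
      pmax(sin(2 * pi * f * t[idx] + ph), 0)^2
    burst_ext[idx] <- .EMG_BURST[[task]] / brady *
      pmax(sin(2 * pi * f * t[idx] + ph + pi), 0)^2
  }
  ripple <- 0.3 * a_tr * trem_w * abs(tremor_carrier)
  b0 <- profile$baseline_emg_level
  ch[, "emg_flexor"] <- pmax(b0 + burst + ripple +
                               stats::rnorm(n, 0, noise_sd / 2), 0)
  ch[, "emg_extensor"] <- pmax(0.9 * b0 + burst_ext + ripple +
                                 stats::rnorm(n, 0, noise_sd / 2), 0)

  # derived channels
  for (u in units) for (m in mods) {
    xyz <- ch[, paste(u, m, c("x", "y", "z"), sep = "_")]
    res <- sqrt(rowSums(xyz^2))
    ch[, paste(u, m, "res", sep = "_")] <- res
    ch[, paste(u, m, "jerk", sep = "_")] <- c(0, diff(res)) * sample_rate
  }
  ch[, "emg_sum"] <- ch[, "emg_flexor"] + ch[, "emg_extensor"]
  ch[, "emg_diff"] <- ch[, "emg_flexor"] - ch[, "emg_extensor"]

  ch <- ch * rep_scale

  structure(list(
    subject = profile,
    repetition = as.integer(repetition),
    sample_rate = sample_rate,
    channels = ch,
    task_windows = task_windows
  ), class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf(
    "Recording: subject %d (%s), repetition %d, %d samples x %d channels @ %g Hz\n",
    x$subject$subject_id, x$subject$group, x$repetition,
    nrow(x$channels), ncol(x$channels), x$sample_rate))
  invisible(x)
}

#' Generate a full synthetic cohort
#'
#' Generates every recording of the cohort described by `spec`: for each
#' subject a profile is drawn from its own substream of the cohort seed, then
#' one recording per repetition. Identical specs (including the seed) give
#' bit-identical cohorts.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `motor_cohort`: a list with `recordings` (list
#'   of [generate_task_sequence()] outputs, subjects x repetitions) and the
#'   generating `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  recordings <- list()
  sid <- 0L
  for (g in GROUPS) {
    for (i in seq_len(spec$n_per_group[[g]])) {
      sid <- sid + 1L
      prof <- subject_profile(spec, g, sid)
      for (r in seq_len(spec$repetitions)) {
        rec <- generate_task_sequence(
          prof, repetition = r,
          seed = .substream(spec$seed, sid, r),
          task_duration = spec$task_duration,
          sample_rate = spec$sample_rate,
          noise_sd = spec$noise_sd)
        recordings[[length(recordings) + 1L]] <- rec
      }
    }
  }
  structure(list(recordings = recordings, spec = spec),
            class = "motor_cohort")
}

#' @export
print.motor_cohort <- function(x, ...) {
  groups <- vapply(x$recordings, function(r) r$subject$group, "")
  cat(sprintf("Synthetic motor cohort: %d recordings from %d subjects\n",
              length(x$recordings),
              length(unique(vapply(x$recordings,
                                   function(r) r$subject$subject_id, 1L)))))
  print(table(factor(groups, levels = GROUPS)))
  invisible(x)
}

#' Per-group coefficient of variation across repetitions
#'
#' For each subject, a scalar summary of each repetition is computed (by
#' default the RMS of the hand-accelerometer resultant over the whole
#' sequence) and the coefficient of variation sd/mean across that subject's
#' repetitions is taken; CVs are then averaged within group. This is the
#' reproducibility statistic used to calibrate the simulator (targets 0.21 /
#' 0.24 / 0.30).
#'
#' @param cohort A `motor_cohort` or plain list of `raw_recording`s.
#' @param summary_feature Channel whose whole-sequence RMS summarizes one
#'   repetition.
#' @return Data frame with one row per group: `group`, `mean_cv`, `sd_cv`,
#'   `n_subjects`; per-subject CVs attached as attribute `"per_subject"`.
#' @export
compute_cv <- function(cohort, summary_feature = "hand_acc_res") {
  recs <- if (inherits(cohort, "motor_cohort")) cohort$recordings else cohort
  stopifnot(length(recs) > 0)
  sid <- vapply(recs, function(r) r$subject$subject_id, 1L)
  grp <- vapply(recs, function(r) r$subject$group, "")
  summ <- vapply(recs, function(r) {
    x <- r$channels[, summary_feature]
    sqrt(mean(x^2))
  }, 1.0)
  per_subject <- do.call(rbind, lapply(unique(sid), function(s) {
    v <- summ[sid == s]
    if (length(v) < 2) stop("need >= 2 repetitions per subject")
    m <- mean(v)
    if (abs(m) < .Machine$double.eps^0.5) {
      warning("subject ", s, " has zero-mean summary; CV undefined, excluded")
      return(NULL)
    }
    data.frame(subject_id = s, group = grp[sid == s][1],
               cv = stats::sd(v) / m)
  }))
  out <- do.call(rbind, lapply(GROUPS, function(g) {
    v <- per_subject$cv[per_subject$group == g]
    if (!length(v)) return(NULL)
    data.frame(group = g, mean_cv = mean(v), sd_cv = stats::sd(v),
               n_subjects = length(v))
  }))
  attr(out, "per_subject") <- per_subject
  out
}

#' Write / read a cohort as tidy CSV plus a JSON manifest
#'
#' Each recording becomes one CSV (`time` plus the 34 channel columns); the
#' manifest records subject, group, repetition, file, task boundaries and the
#' subject profiles needed to rebuild the cohort object.
#'
#' @param cohort A `motor_cohort`.
#' @param dir Output directory (created if missing).
#' @return `write_cohort` invisibly returns the manifest path; `read_cohort`
#'   returns a `motor_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "motor_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(seq_along(cohort$recordings), function(i) {
    rec <- cohort$recordings[[i]]
    file <- sprintf("rec_%03d_s%02d_r%d.csv", i, rec$subject$subject_id,
                    rec$repetition)
    df <- data.frame(time = (seq_len(nrow(rec$channels)) - 1) /
                       rec$sample_rate)
    df <- cbind(df, as.data.frame(rec$channels))
    utils::write.csv(df, file.path(dir, file), row.names = FALSE)
    list(file = file, repetition = rec$repetition,
         sample_rate = rec$sample_rate,
         task_windows = rec$task_windows,
         subject = unclass(rec$subject))
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(entries, manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  recordings <- lapply(manifest, function(e) {
    df <- utils::read.csv(file.path(dir, e$file), check.names = FALSE)
    ch <- as.matrix(df[, setdiff(names(df), "time")])
    prof <- e$subject
    prof$movement_phase <- unlist(prof$movement_phase)
    prof$freq_jitter <- unlist(prof$freq_jitter)
    prof$axis_w <- matrix(unlist(prof$axis_w), 3, 6)
    prof$gravity <- unlist(prof$gravity)
    class(prof) <- "subject_profile"
    structure(list(
      subject = prof,
      repetition = as.integer(e$repetition),
      sample_rate = e$sample_rate,
      channels = ch,
      task_windows = lapply(e$task_windows, function(w) {
        w <- unlist(w)
        c(start = w[[1]], end = w[[2]])
      })
    ), class = "raw_recording")
  })
  structure(list(recordings = recordings, spec = NULL),
            class = "motor_cohort")
}
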