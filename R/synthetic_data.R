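#' Signal model for synthetic sway-like series
#'
#' Three generative families with controlled regularity:
#' * `mix`: the MIX(p) validation process — a deterministic sinusoid
#'   `sqrt(2) * sin(2 * pi * i / period)` in which each sample is
#'   independently replaced, with probability `p`, by uniform noise on
#'   `(-sqrt(3), sqrt(3))` (unit variance). `p = 0` is perfectly
#'   periodic, `p = 1` is i.i.d. noise; sample entropy increases with p.
#' * `template_noise`: `amplitude` times a periodic template plus
#'   additive Gaussian noise of standard deviation `noise_sd`.
#' * `gaussian_walk`: cumulative sum of Gaussian increments of standard
#'   deviation `noise_sd`.
#'
#' @param kind `"mix"`, `"template_noise"` or `"gaussian_walk"`.
#' @param p Irregularity fraction in \[0, 1\] (mix only).
#' @param template_period Template period in samples.
#' @param noise_sd Noise standard deviation (same units as the signal).
#' @param amplitude Template amplitude.
#' @param seed Integer seed; the same (model, n) is bit-reproducible.
#' @return An object of class `signal_model`.
#' @export
signal_model <- function(kind = c("mix", "template_noise", "gaussian_walk"),
                         p = 0.5, template_period = 12, noise_sd = 1,
                         amplitude = 1, seed = 1L) {
  kind <- match.arg(kind)
  if (p < 0 || p > 1) stop("p must lie in [0, 1]", call. = FALSE)
  if (noise_sd < 0 || amplitude < 0) {
    stop("noise_sd and amplitude must be nonnegative", call. = FALSE)
  }
  structure(list(kind = kind, p = p, template_period = template_period,
                 noise_sd = noise_sd, amplitude = amplitude,
                 seed = as.integer(seed)),
            class = "signal_model")
}

#' Generate a synthetic series from a signal model
#'
#' @param model A [signal_model()].
#' @param n Number of samples (>= 10).
#' @return Numeric series of length `n`.
#' @export
generate_signal <- function(model, n) {
  stopifnot(inherits(model, "signal_model"))
  if (n < 10L) stop("n must be >= 10", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(model$seed)
  i <- seq_len(n)
  switch(model$kind,
    mix = {
      base <- sqrt(2) * sin(2 * pi * i / model$template_period)
      z <- stats::runif(n) < model$p
      e <- stats::runif(n, -sqrt(3), sqrt(3))
      ifelse(z, e, base)
    },
    template_noise = {
      model$amplitude * sin(2 * pi * i / model$template_period) +
        stats::rnorm(n, 0, model$noise_sd)
    },
    gaussian_walk = cumsum(stats::rnorm(n, 0, model$noise_sd))
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# deterministic small-integer seed for one trial, derived from the design
# seed and the trial coordinates; stays below 2^31
.trial_seed <- function(seed, subj_idx, task_idx, rep_idx, direction_idx = 0L) {
  base <- (as.numeric(seed) %% 1e6) * 1931 +
    subj_idx * 403 + task_idx * 101 + rep_idx * 23 + direction_idx * 7
  as.integer(base %% 2147483647)
}

#' Default signal-level effect matrix (MIX irregularity p)
#'
#' Target MIX(p) irregularity per (group, task), chosen to mirror the
#' qualitative group-by-task pattern of expert-vs-novice sway regularity:
#' no group separation in quiet standing; in the shooting-position and
#' aiming tasks the control and beginner groups become markedly more
#' irregular than in QS while biathletes become slightly more regular,
#' ending well below the other two groups.
#'
#' @return A 3 x 3 numeric matrix, rows `control`, `beginner`,
#'   `biathlete`; columns `QS`, `SP`, `AT`.
#' @export
default_effect_matrix <- function() {
  m <- rbind(control = c(0.45, 0.68, 0.68),
             beginner = c(0.45, 0.68, 0.68),
             biathlete = c(0.42, 0.32, 0.28))
  colnames(m) <- .tasks
  m
}

#' Zero-effect matrix (null cohorts)
#'
#' All groups and tasks share the same irregularity; used for type-I
#' error calibration.
#'
#' @param p Common irregularity level.
#' @return A 3 x 3 numeric matrix.
#' @export
null_effect_matrix <- function(p = 0.5) {
  m <- matrix(p, 3, 3, dimnames = list(.groups, .tasks))
  m
}

#' Cohort design for synthetic force-plate data
#'
#' Defaults reproduce the study design exactly: groups of 15 controls,
#' 15 beginners and 8 biathletes; three tasks (QS, SP, AT) each repeated
#' three times; 30 s trials sampled at 50 Hz (1500 samples). Group mean
#' body masses (74.8, 73.9 and 58.9 kg, with subject-level SDs 9.5, 8.8
#' and 11.5 kg) drive the vertical-force channel.
#'
#' @param group_sizes Named integer vector (control, beginner, biathlete).
#' @param repeats Repeats per task.
#' @param trial_seconds Trial duration (s).
#' @param fs Sampling rate (Hz).
#' @param effect_matrix Group-by-task matrix of MIX irregularity targets.
#' @param between_subject_sd SD of the Gaussian random intercept added to
#'   each subject's irregularity level (clipped to \[0.02, 0.98\]).
#' @param increment_scale COP increment amplitude scale in metres; the
#'   unit-variance MIX increments are multiplied by this before
#'   integration into a COP path.
#' @param seed Integer master seed.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(group_sizes = c(control = 15L, beginner = 15L,
                                          biathlete = 8L),
                          repeats = 3L, trial_seconds = 30, fs = 50,
                          effect_matrix = default_effect_matrix(),
                          between_subject_sd = 0.05,
                          increment_scale = 5e-4, seed = 1L) {
  stopifnot(all(names(group_sizes) == .groups),
            all(group_sizes >= 1L),
            all(dim(effect_matrix) == c(3L, 3L)))
  structure(list(group_sizes = group_sizes, tasks = .tasks,
                 repeats = as.integer(repeats),
                 trial_seconds = trial_seconds, fs = fs,
                 effect_matrix = effect_matrix,
                 between_subject_sd = between_subject_sd,
                 increment_scale = increment_scale,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

.design_subjects <- function(design) {
  tag <- c(control = "C", beginner = "B", biathlete = "A")
  out <- do.call(rbind, lapply(.groups, function(g) {
    n <- design$group_sizes[[g]]
    data.frame(subject = sprintf("%s%02d", tag[[g]], seq_len(n)),
               group = g)
  }))
  out$subj_idx <- seq_len(nrow(out))
  out
}

# per-group body mass model (kg): mean and subject SD
.mass_model <- cbind(mean = c(control = 74.8, beginner = 73.9,
                              biathlete = 58.9),
                     sd = c(9.5, 8.8, 11.5))

.subject_profile <- function(design, subject) {
  subj <- .design_subjects(design)
  row <- subj[subj$subject == subject, , drop = FALSE]
  if (!nrow(row)) stop(sprintf("unknown subject %s in design", subject),
                       call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.trial_seed(design$seed, row$subj_idx, 0L, 0L))
  g <- row$group
  mass <- max(40, stats::rnorm(1, .mass_model[g, "mean"], .mass_model[g, "sd"]))
  p_shift <- stats::rnorm(1, 0, design$between_subject_sd)
  list(subject = subject, group = g, subj_idx = row$subj_idx,
       mass_kg = mass, p_shift = p_shift)
}

#' Generate one synthetic force-plate trial
#'
#' Synthesizes a COP path whose increment series is a MIX(p) process at
#' the subject's (group, task) irregularity level, then inverts the COP
#' relation to emit six plausible channels: `fz` from the subject's body
#' weight with 0.5 percent multiplicative noise, `mx = ap * fz`,
#' `my = -ml * fz`, and small-noise shear forces. Pushing the output back
#' through [compute_cop()] recovers the synthesized COP exactly (the
#' inversion is algebraic); the 7 Hz pipeline filter then smooths it
#' within filter tolerance.
#'
#' @param design A [cohort_design()].
#' @param subject Subject id (as in the design manifest).
#' @param task `"QS"`, `"SP"` or `"AT"`.
#' @param repeat_index Repeat number, 1..design$repeats.
#' @return A [force_plate_recording()] with attached [trial_meta()] and a
#'   `cop_true` attribute holding the synthesized pre-filter COP path and
#'   the realized irregularity level `p`.
#' @export
generate_trial <- function(design, subject, task, repeat_index = 1L) {
  stopifnot(inherits(design, "cohort_design"))
  task <- match.arg(task, .tasks)
  repeat_index <- as.integer(repeat_index)
  if (!repeat_index %in% seq_len(design$repeats)) {
    stop("repeat_index outside the design", call. = FALSE)
  }
  prof <- .subject_profile(design, subject)
  n <- round(design$fs * design$trial_seconds)
  task_idx <- match(task, .tasks)
  p_eff <- min(0.98, max(0.02,
    design$effect_matrix[prof$group, task] + prof$p_shift))

  cop <- lapply(c(ap = 1L, ml = 2L), function(dir_idx) {
    sd_trial <- .trial_seed(design$seed, prof$subj_idx, task_idx,
                            repeat_index, dir_idx)
    inc <- generate_signal(signal_model("mix", p = p_eff, seed = sd_trial),
                           n - 1L) * design$increment_scale
    cumsum(c(0, inc))
  })

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.trial_seed(design$seed, prof$subj_idx, task_idx,
                       repeat_index, 5L))
  fz <- prof$mass_kg * 9.81 * (1 + stats::rnorm(n, 0, 0.005))
  fx <- stats::rnorm(n, 0, 1)
  fy <- stats::rnorm(n, 0, 1)
  meta <- trial_meta(subject, prof$group, task, repeat_index)
  rec <- force_plate_recording(fx, fy, fz,
                               mx = cop$ap * fz, my = -cop$ml * fz,
                               mz = fx * 0,
                               fs = design$fs, meta = meta,
                               duration = design$trial_seconds)
  # the synthesized (pre-filter) COP, for inversion round-trip checks
  attr(rec, "cop_true") <- list(ap = cop$ap, ml = cop$ml, p = p_eff)
  rec
}

#' Generate a full synthetic cohort
#'
#' Every subject x task x repeat trial under the design (342 under the
#' defaults: 38 subjects, 3 tasks, 3 repeats), fully reproducible from
#' the design seed, with a manifest of trial metadata.
#'
#' @param design A [cohort_design()].
#' @return A list with `recordings` (list of [force_plate_recording()],
#'   named `subject/task/repeat`) and `manifest` (data frame with
#'   columns subject, group, task, repeat_index).
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  subj <- .design_subjects(design)
  manifest <- do.call(rbind, lapply(seq_len(nrow(subj)), function(i) {
    expand.grid(subject = subj$subject[i], group = subj$group[i],
                task = .tasks, repeat_index = seq_len(design$repeats),
                stringsAsFactors = FALSE)
  }))
  manifest <- manifest[order(manifest$subject, manifest$task,
                             manifest$repeat_index), ]
  rownames(manifest) <- NULL
  recordings <- lapply(seq_len(nrow(manifest)), function(i) {
    generate_trial(design, manifest$subject[i], manifest$task[i],
                   manifest$repeat_index[i])
  })
  names(recordings) <- sprintf("%s/%s/%d", manifest$subject, manifest$task,
                               manifest$repeat_index)
  list(recordings = recordings, manifest = manifest)
}

#' Default SampEn-level effect means
#'
#' Target mean SampEn (nats) per (group, task) for the cohort-level
#' response model, mirroring the same qualitative pattern as
#' [default_effect_matrix()] but expressed directly on the SampEn scale:
#' near-common values in QS, control and beginner rising in SP/AT,
#' biathletes dropping below their QS level.
#'
#' @return A 3 x 3 numeric matrix (nats).
#' @export
sampen_effect_means <- function() {
  m <- rbind(control = c(1.70, 2.05, 2.05),
             beginner = c(1.70, 2.05, 2.05),
             biathlete = c(1.60, 1.40, 1.35))
  colnames(m) <- .tasks
  m
}

#' Simulate a cohort of per-trial SampEn values directly
#'
#' The cohort-level response model behind the signal generator, sampled
#' without synthesizing signals: each trial's SampEn is the (group, task)
#' target mean plus a Gaussian subject random intercept
#' (`subject_sd`) plus independent repeat noise (`repeat_sd`). Used for
#' statistical calibration (type-I error, power), where only the
#' distribution of the dependent variable matters.
#'
#' @param means 3 x 3 matrix of target means (rows control, beginner,
#'   biathlete; columns QS, SP, AT); `matrix(c, 3, 3)` for a null cohort.
#' @param group_sizes Named integer vector of group sizes.
#' @param repeats Repeats per task.
#' @param subject_sd SD of the subject random intercept (nats).
#' @param repeat_sd SD of the within-subject repeat noise (nats).
#' @param direction Direction label stamped on the rows.
#' @param seed Integer seed.
#' @return Long-format trial table suitable for [average_repeats()].
#' @export
simulate_sampen_trials <- function(means = sampen_effect_means(),
                                   group_sizes = c(control = 15L,
                                                   beginner = 15L,
                                                   biathlete = 8L),
                                   repeats = 3L, subject_sd = 0.25,
                                   repeat_sd = 0.12, direction = "AP",
                                   seed = 1L) {
  stopifnot(all(dim(means) == c(3L, 3L)))
  dimnames(means) <- list(.groups, .tasks)
  seed <- as.integer(seed)  # force before saving the caller's RNG state
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tag <- c(control = "C", beginner = "B", biathlete = "A")
  rows <- list()
  for (g in .groups) {
    for (s in seq_len(group_sizes[[g]])) {
      intercept <- stats::rnorm(1, 0, subject_sd)
      for (t in .tasks) {
        y <- means[g, t] + intercept +
          stats::rnorm(repeats, 0, repeat_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = sprintf("%s%02d", tag[[g]], s), group = g, task = t,
          repeat_index = seq_len(repeats), direction = direction,
          sampen = y)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
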