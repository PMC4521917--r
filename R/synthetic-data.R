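# Synthetic lateral-sway cohort generator.
#
# Emulates skeleton tracking of a weight-shifting balance task: 15 body
# segments sampled irregularly at about 30 Hz while the subject sways the
# trunk repeatedly from the outermost left to the outermost right stance
# limit and back. Segment kinematics follow a planar chain: every landmark
# is an amplitude-scaled, phase-lagged copy of a single lower-back
# oscillator, with a pendulum-like vertical coupling (vertical dip
# proportional to 1 - cos of the lateral lean angle).

#' Names of the 15 tracked body segments
#'
#' Segment set of a consumer depth-camera skeleton: head, neck, trunk
#' (lower back) and paired shoulders, elbows, hands, hips, knees and feet.
#'
#' @return Character vector of length 15.
#' @export
kinect_segments <- function() {
  c("head", "neck", "left_shoulder", "right_shoulder",
    "left_elbow", "right_elbow", "left_hand", "right_hand",
    "lower_back", "left_hip", "right_hip",
    "left_knee", "right_knee", "left_foot", "right_foot")
}

#' Names of the 9 frontal-plane landmarks retained for analysis
#'
#' Hands, elbows and feet are dropped before analysis (they are tracked
#' poorly and are not required by the sway task), leaving 9 landmarks whose
#' frontal-plane (x, y) coordinates form the 18-dimensional posture vector.
#'
#' @return Character vector of length 9, in posture-vector order.
#' @export
frontal_landmarks <- function() {
  c("head", "neck", "left_shoulder", "right_shoulder",
    "lower_back", "left_hip", "right_hip", "left_knee", "right_knee")
}

#' Column names of the 18-dimensional posture vector
#'
#' All 9 medio-lateral (x) coordinates first, then all 9 vertical (y)
#' coordinates, matching the posture-vector layout used throughout.
#'
#' @return Character vector of length 18.
#' @export
posture_colnames <- function() {
  lm <- frontal_landmarks()
  c(paste0(lm, "_x"), paste0(lm, "_y"))
}

# Planar-chain geometry for a subject of stature_scale 1 (about 1.75 m).
# height: resting vertical position (m); x_offset: lateral offset from the
# midline (m, + = subject's right); gain: lateral excursion relative to the
# lower back; phase: phase offset in units of the upper-body lead `phase_lag`
# (positive = leads the lower back); vcoup: fraction of the pendulum vertical
# dip transmitted to the landmark.
segment_geometry <- function() {
  g <- rbind(
    head           = c(1.70,  0.00, 1.50,  1.0, 0.85),
    neck           = c(1.50,  0.00, 1.35,  1.0, 0.75),
    left_shoulder  = c(1.45, -0.20, 1.25,  1.0, 0.72),
    right_shoulder = c(1.45,  0.20, 1.25,  1.0, 0.72),
    left_elbow     = c(1.20, -0.33, 1.20,  0.5, 0.60),
    right_elbow    = c(1.20,  0.33, 1.20,  0.5, 0.60),
    left_hand      = c(0.95, -0.38, 1.15,  0.5, 0.50),
    right_hand     = c(0.95,  0.38, 1.15,  0.5, 0.50),
    lower_back     = c(1.00,  0.00, 1.00,  0.0, 0.50),
    left_hip       = c(0.95, -0.13, 0.85, -0.4, 0.45),
    right_hip      = c(0.95,  0.13, 0.85, -0.4, 0.45),
    left_knee      = c(0.50, -0.15, 0.45, -0.6, 0.25),
    right_knee     = c(0.50,  0.15, 0.45, -0.6, 0.25),
    left_foot      = c(0.05, -0.17, 0.05, -0.6, 0.02),
    right_foot     = c(0.05,  0.17, 0.05, -0.6, 0.02)
  )
  colnames(g) <- c("height", "x_offset", "gain", "phase", "vcoup")
  g
}

#' Default task conditions
#'
#' Five task conditions of increasing demand: (1) neutral self-selected
#' sway, (2) doubled in-game speed, (3) maximum sway frequency,
#' (4) contralateral leg lift during sway, (5) maximum sway amplitude.
#' Conditions 3 and 5, which push subjects towards their performance
#' limits, are flagged `complex`: these are the conditions under which the
#' aged archetype differs from the young one.
#'
#' @return Data frame with one row per condition: `condition_id`,
#'   `amplitude_multiplier`, `frequency_multiplier`, `leg_lift`, `complex`,
#'   `label`.
#' @export
default_conditions <- function() {
  data.frame(
    condition_id = 1:5,
    amplitude_multiplier = c(1.00, 1.00, 0.90, 1.00, 1.60),
    frequency_multiplier = c(1.00, 1.15, 1.80, 0.90, 0.90),
    leg_lift = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    complex = c(FALSE, FALSE, TRUE, FALSE, TRUE),
    label = c("neutral", "increased game speed", "maximum sway frequency",
              "leg lifted", "maximum sway amplitude"),
    stringsAsFactors = FALSE
  )
}

#' Default population parameters for subject sampling
#'
#' Group-level means and SDs of the per-subject sway parameters. Baselines
#' are identical for the young and the old archetype: age differences are
#' expressed only under the complex (performance-limit) conditions, where
#' the old archetype reaches a smaller amplitude (x 0.8), a lower maximum
#' frequency (x 0.8) and a higher cycle-to-cycle variability (x 1.5); see
#' [generate_trial()].
#'
#' Amplitude, frequency, variability and stature share one baseline for
#' both groups; the coordination trait `phase_lag` (upper-body phase lead
#' over the pelvis, radians) differs: the old archetype sways more en bloc
#' (smaller lead), with overlapping distributions so the groups form a
#' continuum rather than two clean clusters.
#'
#' @return Nested list with components `young` and `old`, each holding
#'   `amplitude` (m, lower-back ML half-excursion), `frequency` (Hz),
#'   `variability` (dimensionless, cycle-to-cycle SD as a fraction of the
#'   amplitude), `stature` (dimensionless multiplier) and `phase_lag`
#'   (radians), each a `c(mean, sd)` pair.
#' @export
default_population <- function() {
  base <- list(
    amplitude   = c(mean = 0.12, sd = 0.020),
    frequency   = c(mean = 0.45, sd = 0.070),
    variability = c(mean = 0.08, sd = 0.020),
    stature     = c(mean = 1.00, sd = 0.050)
  )
  young <- c(base, list(phase_lag = c(mean = 0.28, sd = 0.07)))
  old <- c(base, list(phase_lag = c(mean = 0.16, sd = 0.07)))
  list(young = young, old = old)
}

# Multipliers applied to old-group subjects under complex conditions only.
old_complex_factors <- function() {
  c(amplitude = 0.8, frequency = 0.8, variability = 1.5)
}

#' Draw per-subject sway parameters for a synthetic cohort
#'
#' @param n_young,n_old Number of subjects per group.
#' @param population Group-level parameter distributions, as returned by
#'   [default_population()].
#' @param seed Integer seed; the call is fully reproducible.
#'
#' @return Data frame with one row per subject: `subject_id`, `group`,
#'   `stature_scale`, `base_amplitude` (m), `base_frequency` (Hz),
#'   `variability_level`, `phase_lag` (rad), `seed`.
#' @export
generate_subject_specs <- function(n_young, n_old,
                                   population = default_population(),
                                   seed = 1L) {
  if (!is_count(n_young) || !is_count(n_old)) {
    abort_sway("n_young and n_old must be non-negative integers",
               "invalid_argument")
  }
  groups <- rep(c("young", "old"), times = c(n_young, n_old))
  n <- length(groups)
  if (n == 0L) {
    return(data.frame(subject_id = character(), group = character(),
                      stature_scale = numeric(), base_amplitude = numeric(),
                      base_frequency = numeric(), variability_level = numeric(),
                      phase_lag = numeric(), seed = integer(),
                      stringsAsFactors = FALSE))
  }
  withr::with_seed(seed, {
    draw <- function(par, grp) {
      p <- population[[grp]][[par]]
      rnorm(1L, p[["mean"]], p[["sd"]])
    }
    specs <- lapply(seq_len(n), function(i) {
      grp <- groups[i]
      data.frame(
        subject_id = sprintf("S%03d", i),
        group = grp,
        stature_scale = max(0.7, draw("stature", grp)),
        base_amplitude = max(0.03, draw("amplitude", grp)),
        base_frequency = max(0.15, draw("frequency", grp)),
        variability_level = max(0.005, draw("variability", grp)),
        phase_lag = max(0.02, draw("phase_lag", grp)),
        seed = derive_seed(seed, i),
        stringsAsFactors = FALSE
      )
    })
  })
  do.call(rbind, specs)
}

#' Generate one synthetic sway trial
#'
#' Simulates an irregularly sampled skeleton recording of repeated lateral
#' sway. The lower back follows `-A a(t) cos(2 pi u(t))`, where `u` is the
#' within-cycle phase (so every cycle starts and ends at the outermost left
#' position) and the per-cycle amplitude envelope `a(t)` and cycle periods
#' are perturbed with SD `variability_level`. All other landmarks are
#' gain-scaled, phase-lagged copies with a pendulum-like vertical coupling.
#' For an `old` subject under a `complex` condition the effective amplitude
#' and frequency are reduced (x 0.8) and the variability is increased
#' (x 1.5), mirroring age effects at the limits of performance.
#'
#' @param subject One row of [generate_subject_specs()] output (or an
#'   equivalent named list).
#' @param condition One row of [default_conditions()].
#' @param n_cycles Number of analyzable sway cycles the trial must support
#'   (`n_extra_cycles` additional cycles are generated so that discarding
#'   the first still leaves `n_cycles`).
#' @param seed Integer seed; defaults to the subject's own seed.
#' @param noise_sd Additive Gaussian sensor noise SD, meters.
#' @param jitter_ms Half-width of the uniform timestamp jitter around the
#'   nominal 1/30 s grid, milliseconds.
#' @param phase_lag Upper-body phase lead over the lower back, radians;
#'   a `phase_lag` field on the subject (the per-subject coordination
#'   trait drawn by [generate_subject_specs()]) takes precedence.
#' @param rate Nominal sampling rate, Hz.
#' @param n_extra_cycles Extra cycles generated beyond `n_cycles`.
#'
#' @return A `sway_raw_trial`: list with `trial_id`, `subject_id`,
#'   `condition_id`, `group`, `timestamps` (s, strictly increasing) and
#'   `positions` (frames x 45 matrix, columns `<segment>_<x|y|z>`).
#' @export
generate_trial <- function(subject, condition, n_cycles = 10L,
                           seed = NULL, noise_sd = 0.003, jitter_ms = 5,
                           phase_lag = 0.25, rate = 30,
                           n_extra_cycles = 3L) {
  subject <- as.list(as.data.frame(subject)[1L, ])
  condition <- as.list(as.data.frame(condition)[1L, ])
  if (!is_count(n_cycles, min = 1L)) {
    abort_sway("n_cycles must be a positive integer", "invalid_argument")
  }
  if (is.null(seed)) seed <- subject$seed
  if (!is.null(subject$phase_lag)) phase_lag <- subject$phase_lag
  old_complex <- identical(subject$group, "old") && isTRUE(condition$complex)
  fac <- old_complex_factors()
  amp <- subject$base_amplitude * condition$amplitude_multiplier *
    (if (old_complex) fac[["amplitude"]] else 1)
  freq <- subject$base_frequency * condition$frequency_multiplier *
    (if (old_complex) fac[["frequency"]] else 1)
  varl <- subject$variability_level *
    (if (old_complex) fac[["variability"]] else 1)
  stature <- if (is.null(subject$stature_scale)) 1 else subject$stature_scale

  n_gen <- n_cycles + n_extra_cycles
  geom <- segment_geometry()
  segs <- rownames(geom)

  withr::with_seed(seed, {
    # Per-cycle period and boundary-amplitude perturbations.
    periods <- (1 / freq) * pmax(0.3, 1 + varl * rnorm(n_gen))
    bounds <- c(0, cumsum(periods))
    amp_nodes <- pmax(0.2, 1 + varl * rnorm(n_gen + 1L))
    t_end <- bounds[n_gen + 1L]

    n_frames <- floor(t_end * rate)
    t <- (seq_len(n_frames) - 1L) / rate +
      runif(n_frames, -jitter_ms, jitter_ms) / 1000
    t <- pmin(pmax(t, 0), t_end - 1e-9)

    # Lower-back oscillator with a piecewise-linear amplitude envelope;
    # continuous across cycle boundaries by construction.
    base_at <- function(tt) {
      tt <- pmin(pmax(tt, 0), t_end - 1e-9)
      ci <- findInterval(tt, bounds, rightmost.closed = FALSE)
      u <- (tt - bounds[ci]) / periods[ci]
      a <- amp_nodes[ci] * (1 - u) + amp_nodes[ci + 1L] * u
      -amp * a * cos(2 * pi * u)
    }

    pend_len <- 0.9 * stature  # effective inverted-pendulum length, m
    pos <- matrix(0, nrow = n_frames, ncol = 3L * length(segs))
    colnames(pos) <- paste0(rep(segs, each = 3L), "_", c("x", "y", "z"))
    base_plain <- base_at(t)
    for (s in segs) {
      tshift <- geom[s, "phase"] * phase_lag / (2 * pi * freq)
      b <- base_at(t - tshift)
      xdisp <- geom[s, "gain"] * b
      theta <- xdisp / pend_len
      pos[, paste0(s, "_x")] <- geom[s, "x_offset"] * stature + xdisp
      pos[, paste0(s, "_y")] <- geom[s, "height"] * stature -
        geom[s, "vcoup"] * pend_len * (1 - cos(theta))
    }
    if (isTRUE(condition$leg_lift)) {
      # Lift the knee (and foot) contralateral to the sway direction.
      rel <- base_plain / amp
      pos[, "left_knee_y"] <- pos[, "left_knee_y"] + 0.12 * pmax(0, rel)
      pos[, "left_foot_y"] <- pos[, "left_foot_y"] + 0.10 * pmax(0, rel)
      pos[, "right_knee_y"] <- pos[, "right_knee_y"] + 0.12 * pmax(0, -rel)
      pos[, "right_foot_y"] <- pos[, "right_foot_y"] + 0.10 * pmax(0, -rel)
    }
    if (noise_sd > 0) {
      pos <- pos + rnorm(length(pos), sd = noise_sd)
    }
  })

  structure(list(
    trial_id = paste0(subject$subject_id, "_c", condition$condition_id),
    subject_id = subject$subject_id,
    condition_id = condition$condition_id,
    group = subject$group,
    timestamps = t,
    positions = pos,
    params = list(amplitude = amp, frequency = freq, variability = varl,
                  n_cycles_generated = n_gen, seed = seed)
  ), class = "sway_raw_trial")
}

#' @export
print.sway_raw_trial <- function(x, ...) {
  cat(sprintf("<sway_raw_trial> %s (%s, condition %d): %d frames, %.1f s\n",
              x$trial_id, x$group, x$condition_id, length(x$timestamps),
              diff(range(x$timestamps))))
  invisible(x)
}

#' Cohort configuration
#'
#' @param n_young,n_old Subjects per group.
#' @param conditions Condition table, see [default_conditions()].
#' @param condition_ids Conditions to include (default: all in `conditions`).
#' @param trials_per_condition Repetitions of each condition per subject.
#' @param n_cycles Analyzable cycles per trial.
#' @param corrupted Named vector `c(young = , old = )`: number of trials per
#'   group generated too short (fewer cycles than required), exercising the
#'   downstream discard rule.
#' @param population See [default_population()].
#' @param noise_sd,jitter_ms,phase_lag Passed to [generate_trial()].
#' @param seed Master seed for the whole cohort.
#'
#' @return A `sway_cohort_config` list.
#' @export
cohort_config <- function(n_young = 20L, n_old = 20L,
                          conditions = default_conditions(),
                          condition_ids = NULL,
                          trials_per_condition = 2L,
                          n_cycles = 10L,
                          corrupted = c(young = 0L, old = 0L),
                          population = default_population(),
                          noise_sd = 0.003, jitter_ms = 5, phase_lag = 0.25,
                          seed = 1L) {
  if (is.null(condition_ids)) condition_ids <- conditions$condition_id
  if (!all(condition_ids %in% conditions$condition_id)) {
    abort_sway(sprintf("unknown condition id(s): %s",
                       paste(setdiff(condition_ids, conditions$condition_id),
                             collapse = ", ")),
               "configuration")
  }
  structure(list(n_young = n_young, n_old = n_old, conditions = conditions,
                 condition_ids = condition_ids,
                 trials_per_condition = trials_per_condition,
                 n_cycles = n_cycles, corrupted = corrupted,
                 population = population, noise_sd = noise_sd,
                 jitter_ms = jitter_ms, phase_lag = phase_lag, seed = seed),
            class = "sway_cohort_config")
}

#' Generate a full synthetic cohort
#'
#' One trial per subject x condition x repetition. A configurable number of
#' trials per group is generated "corrupted" (too few sway cycles) so the
#' preprocessing discard rule has work to do; the manifest records which.
#'
#' @param config A [cohort_config()].
#'
#' @return A `sway_cohort`: list with `trials` (list of `sway_raw_trial`),
#'   `manifest` (data frame: trial_id, subject_id, group, condition_id,
#'   repetition, corrupted), `subjects` (the subject specs) and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "sway_cohort_config")) config <- do.call(cohort_config, config)
  subjects <- generate_subject_specs(config$n_young, config$n_old,
                                     config$population, config$seed)
  cond_tab <- config$conditions[config$conditions$condition_id %in%
                                  config$condition_ids, , drop = FALSE]
  reps <- seq_len(config$trials_per_condition)

  manifest <- expand.grid(repetition = reps,
                          condition_id = cond_tab$condition_id,
                          subject_id = subjects$subject_id,
                          stringsAsFactors = FALSE)
  manifest <- manifest[, c("subject_id", "condition_id", "repetition")]
  manifest$group <- subjects$group[match(manifest$subject_id, subjects$subject_id)]
  manifest$trial_id <- sprintf("%s_c%d_r%d", manifest$subject_id,
                               manifest$condition_id, manifest$repetition)

  # Mark trials to corrupt, per group, with a seeded draw.
  manifest$corrupted <- FALSE
  withr::with_seed(derive_seed(config$seed, 999L), {
    for (grp in c("young", "old")) {
      k <- config$corrupted[[grp]]
      if (is.null(k) || k == 0L) next
      idx <- which(manifest$group == grp)
      if (k > length(idx)) {
        abort_sway(sprintf("cannot corrupt %d %s trials: only %d exist",
                           k, grp, length(idx)), "configuration")
      }
      manifest$corrupted[sample(idx, k)] <- TRUE
    }
  })

  trials <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    subj <- subjects[subjects$subject_id == row$subject_id, ]
    cond <- cond_tab[cond_tab$condition_id == row$condition_id, ]
    tr_seed <- derive_seed(config$seed, match(row$subject_id, subjects$subject_id),
                           row$condition_id, row$repetition)
    # Corrupted trials get too few cycles to survive cycle selection.
    n_cyc <- if (row$corrupted) max(1L, config$n_cycles %/% 2L - 1L) else config$n_cycles
    n_extra <- if (row$corrupted) 1L else 3L
    tr <- generate_trial(subj, cond, n_cycles = n_cyc, seed = tr_seed,
                         noise_sd = config$noise_sd,
                         jitter_ms = config$jitter_ms,
                         phase_lag = config$phase_lag,
                         n_extra_cycles = n_extra)
    tr$trial_id <- row$trial_id
    trials[[i]] <- tr
  }
  names(trials) <- manifest$trial_id
  structure(list(trials = trials,
                 manifest = manifest[, c("trial_id", "subject_id", "group",
                                         "condition_id", "repetition",
                                         "corrupted")],
                 subjects = subjects, config = config),
            class = "sway_cohort")
}

#' @export
print.sway_cohort <- function(x, ...) {
  cat(sprintf("<sway_cohort> %d trials (%d subjects, %d conditions, %d corrupted)\n",
              nrow(x$manifest), nrow(x$subjects),
              length(unique(x$manifest$condition_id)), sum(x$manifest$corrupted)))
  invisible(x)
}

#' Write a cohort to disk as plain-text files
#'
#' One CSV per trial (`time_s` plus one column per segment coordinate), a
#' manifest CSV and a ground-truth JSON holding every generative parameter.
#'
#' @param cohort A `sway_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (tr in cohort$trials) {
    df <- data.frame(time_s = tr$timestamps, tr$positions, check.names = FALSE)
    p <- file.path(dir, paste0(tr$trial_id, ".csv"))
    write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  mp <- file.path(dir, "manifest.csv")
  write.csv(cohort$manifest, mp, row.names = FALSE)
  gt <- list(subjects = cohort$subjects,
             conditions = cohort$config$conditions,
             trial_params = lapply(cohort$trials, function(tr) tr$params))
  gp <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(gt, gp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, mp, gp))
}

#' Read a single trial CSV written by [write_cohort()]
#'
#' @param path CSV path with a `time_s` column and `<segment>_<axis>`
#'   coordinate columns.
#' @param trial_id,subject_id,condition_id,group Optional metadata.
#' @return A `sway_raw_trial`.
#' @export
read_trial_csv <- function(path, trial_id = NULL, subject_id = NA_character_,
                           condition_id = NA_integer_, group = NA_character_) {
  df <- read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df)) {
    abort_sway("trial CSV must contain a time_s column", "malformed_input")
  }
  pos <- as.matrix(df[, setdiff(names(df), "time_s"), drop = FALSE])
  structure(list(
    trial_id = if (is.null(trial_id)) sub("\\.csv$", "", basename(path)) else trial_id,
    subject_id = subject_id, condition_id = condition_id, group = group,
    timestamps = df$time_s, positions = pos, params = list()
  ), class = "sway_raw_trial")
}
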