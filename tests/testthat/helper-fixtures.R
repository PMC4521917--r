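# Fixtures built in code: archetype subjects and hand-crafted trials.

toy_subject <- function(amplitude = 0.12, frequency = 0.5, variability = 0,
                        phase_lag = 0.25, group = "young", seed = 1L,
                        id = "T01") {
  data.frame(subject_id = id, group = group, stature_scale = 1,
             base_amplitude = amplitude, base_frequency = frequency,
             variability_level = variability, phase_lag = phase_lag,
             seed = seed, stringsAsFactors = FALSE)
}

neutral_condition <- function() default_conditions()[1L, ]

# A uniform frontal-plane trial (18 labelled columns) whose medio-lateral
# coordinates follow ml_fun(t) (shoulders and lower back identically, with
# the fixed shoulder offsets); vertical coordinates are constant.
make_frontal_trial <- function(ml_fun, duration = 24, rate = 30,
                               trial_id = "toy") {
  t <- seq(0, duration, by = 1 / rate)
  ml <- ml_fun(t)
  coords <- matrix(0, nrow = length(t), ncol = 18L,
                   dimnames = list(NULL, posture_colnames()))
  for (lm in frontal_landmarks()) coords[, paste0(lm, "_y")] <- 1
  coords[, "lower_back_x"] <- ml
  coords[, "left_shoulder_x"] <- ml - 0.2
  coords[, "right_shoulder_x"] <- ml + 0.2
  coords[, "head_x"] <- ml
  coords[, "neck_x"] <- ml
  coords[, "left_hip_x"] <- ml - 0.1
  coords[, "right_hip_x"] <- ml + 0.1
  coords[, "left_knee_x"] <- ml - 0.1
  coords[, "right_knee_x"] <- ml + 0.1
  structure(list(trial_id = trial_id, subject_id = "toy", condition_id = 1L,
                 group = "young", rate = rate, time = t, coords = coords),
            class = "sway_uniform_trial")
}

# A raw 15-segment 3D trial whose every coordinate follows fun(t) plus a
# per-column offset; used for resampling / reduction contracts.
make_raw_trial <- function(t, fun = function(t) sin(2 * pi * 0.5 * t),
                           trial_id = "raw") {
  segs <- kinect_segments()
  cols <- paste0(rep(segs, each = 3L), "_", c("x", "y", "z"))
  pos <- vapply(seq_along(cols), function(j) fun(t) + j / 100, numeric(length(t)))
  colnames(pos) <- cols
  structure(list(trial_id = trial_id, subject_id = "toy", condition_id = 1L,
                 group = "young", timestamps = t, positions = pos,
                 params = list()),
            class = "sway_raw_trial")
}

# A synthetic lattice trajectory with 10 cycles of 30 phases.
make_trajectory <- function(nodes, trial_id = "traj") {
  structure(list(trial_id = trial_id, nodes = nodes), class = "sway_trajectory")
}

# Tiny preprocessed cohort for normalization / SOM tests.
small_cohort <- function(n_young = 2L, n_old = 2L, conditions = 1L,
                         seed = 5L, trials_per_condition = 1L) {
  generate_cohort(cohort_config(n_young = n_young, n_old = n_old,
                                trials_per_condition = trials_per_condition,
                                condition_ids = conditions, seed = seed))
}
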