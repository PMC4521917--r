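# Preprocessing: raw irregular skeleton recordings -> fixed-size posture
# array (one row of 300 frames x 18 coordinates per retained trial).

#' Resample a trial onto a uniform time grid
#'
#' Cubic-spline interpolation of every coordinate onto an exact `rate` Hz
#' grid spanning the recorded time range (no extrapolation).
#'
#' @param trial A `sway_raw_trial` or `sway_uniform_trial`.
#' @param rate Target sampling rate, Hz.
#' @return A `sway_uniform_trial`: list with trial metadata, `rate`, `time`
#'   (uniform grid) and `coords` (frames x coordinates matrix, original
#'   column labels preserved).
#' @export
resample_uniform <- function(trial, rate = 30) {
  t <- trial$timestamps
  if (is.null(t)) t <- trial$time
  x <- trial$positions
  if (is.null(x)) x <- trial$coords
  if (length(t) < 4L) {
    abort_sway("need at least 4 frames to resample", "malformed_input")
  }
  if (any(diff(t) <= 0)) {
    abort_sway("timestamps must be strictly increasing", "malformed_input")
  }
  grid <- t[1L] + seq(0, floor((t[length(t)] - t[1L]) * rate)) / rate
  out <- apply(x, 2L, function(col) {
    stats::spline(t, col, xout = grid, method = "fmm")$y
  })
  structure(list(trial_id = trial$trial_id, subject_id = trial$subject_id,
                 condition_id = trial$condition_id, group = trial$group,
                 rate = rate, time = grid, coords = out),
            class = "sway_uniform_trial")
}

#' Reduce a 15-segment 3D trial to 9 frontal-plane landmarks
#'
#' Drops hands, elbows and feet and discards the sagittal (z) axis,
#' retaining the 18 coordinates of the posture vector. Selection is by
#' column label, so column order is irrelevant.
#'
#' @param trial A `sway_uniform_trial` whose `coords` contain
#'   `<segment>_<axis>` columns for all 15 segments.
#' @return A `sway_uniform_trial` with 18 columns ordered as
#'   [posture_colnames()].
#' @export
reduce_to_frontal <- function(trial) {
  wanted <- posture_colnames()
  have <- colnames(trial$coords)
  missing <- setdiff(wanted, have)
  if (length(missing) > 0L) {
    abort_sway(paste0("missing landmark columns: ",
                      paste(missing, collapse = ", ")), "malformed_input")
  }
  trial$coords <- trial$coords[, wanted, drop = FALSE]
  trial
}

# Local maxima of x with topographic prominence >= min_prom. Returns sorted
# indices. Prominence of a peak: height minus the higher of the two lowest
# saddles separating it from higher ground (or the signal edge).
find_peaks <- function(x, min_prom) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  cand <- which(d[-length(d)] > 0 & d[-1L] <= 0) + 1L
  if (length(cand) == 0L) return(integer(0))
  keep <- logical(length(cand))
  for (j in seq_along(cand)) {
    i <- cand[j]
    h <- x[i]
    left_min <- h
    k <- i - 1L
    while (k >= 1L && x[k] <= h) {
      if (x[k] < left_min) left_min <- x[k]
      k <- k - 1L
    }
    if (k < 1L) left_min <- min(x[seq_len(i - 1L)])
    right_min <- h
    k <- i + 1L
    while (k <= n && x[k] <= h) {
      if (x[k] < right_min) right_min <- x[k]
      k <- k + 1L
    }
    if (k > n) right_min <- min(x[seq(i + 1L, n)])
    prom <- h - max(left_min, right_min)
    keep[j] <- prom >= min_prom
  }
  cand[keep]
}

#' Segment a trial into sway cycles
#'
#' A sway cycle is one full left-right-left sway of the shoulders, starting
#' and ending at the outermost left position. Boundaries are the local
#' minima of the mean shoulder medio-lateral coordinate (left = negative x)
#' whose prominence exceeds a fraction of the signal's interquartile range.
#'
#' @param trial A frontal-plane `sway_uniform_trial` (18 columns).
#' @param prominence_frac Prominence threshold as a fraction of the IQR of
#'   the mean-shoulder ML signal.
#' @return A `sway_cycles`: list with `boundaries` (frame indices, 1-based),
#'   `n_cycles`, `durations` (s) and `rate`.
#' @export
detect_cycles <- function(trial, prominence_frac = 0.25) {
  if (length(trial$time) / trial$rate < 2 &&
      diff(range(trial$time)) < 2) {
    abort_sway("need at least 2 s of data to detect cycles", "invalid_argument")
  }
  s <- rowMeans(trial$coords[, c("left_shoulder_x", "right_shoulder_x"),
                             drop = FALSE])
  thr <- prominence_frac * IQR(s)
  minima <- find_peaks(-s, min_prom = thr)
  if (length(minima) < 2L) {
    abort_sway("fewer than 2 cycle boundaries found (no sway oscillation?)",
               "no_cycles")
  }
  structure(list(boundaries = minima,
                 n_cycles = length(minima) - 1L,
                 durations = diff(minima) / trial$rate,
                 rate = trial$rate,
                 discarded = FALSE),
            class = "sway_cycles")
}

#' Select the analysis cycles of a trial
#'
#' Discards the first detected cycle and keeps the subsequent `n`. A trial
#' with fewer than `n` cycles remaining is flagged discarded - a reported
#' outcome, not an error.
#'
#' @param seg A `sway_cycles` from [detect_cycles()].
#' @param n Number of cycles to keep.
#' @return A `sway_cycles` with `n` cycles and `discarded = FALSE`, or one
#'   with `discarded = TRUE` (and `n_available`) if too few cycles exist.
#' @export
select_cycles <- function(seg, n = 10L) {
  available <- seg$n_cycles - 1L  # after dropping the first cycle
  if (available < n) {
    return(structure(list(boundaries = NULL, n_cycles = 0L,
                          durations = numeric(0), rate = seg$rate,
                          discarded = TRUE, n_available = max(0L, available)),
                     class = "sway_cycles"))
  }
  b <- seg$boundaries[seq(2L, n + 2L)]
  structure(list(boundaries = b, n_cycles = n,
                 durations = diff(b) / seg$rate, rate = seg$rate,
                 discarded = FALSE),
            class = "sway_cycles")
}

#' Mean sway amplitude of a trial
#'
#' Per selected cycle, the peak-to-peak medio-lateral excursion of the
#' lower-back landmark; the trial's amplitude is the mean over cycles.
#'
#' @param trial A frontal-plane `sway_uniform_trial`.
#' @param seg A selected `sway_cycles`.
#' @return Amplitude in meters.
#' @export
sway_amplitude <- function(trial, seg) {
  if (isTRUE(seg$discarded) || seg$n_cycles < 1L) {
    abort_sway("segmentation holds no cycles", "invalid_argument")
  }
  x <- trial$coords[, "lower_back_x"]
  b <- seg$boundaries
  exc <- vapply(seq_len(seg$n_cycles), function(c) {
    idx <- seq(b[c], b[c + 1L] - 1L)
    diff(range(x[idx]))
  }, numeric(1))
  mean(exc)
}

#' Dominant sway frequency of a trial
#'
#' Frequency of the maximum of the periodogram of the linearly detrended,
#' Hann-windowed lower-back medio-lateral signal, excluding the
#' zero-frequency bin.
#'
#' @param trial A frontal-plane `sway_uniform_trial` with at least 4 s of
#'   data.
#' @return Frequency in Hz.
#' @export
sway_frequency <- function(trial) {
  x <- trial$coords[, "lower_back_x"]
  n <- length(x)
  if (n / trial$rate < 4) {
    abort_sway("need at least 4 s of data for a frequency estimate",
               "invalid_argument")
  }
  tt <- seq_len(n)
  x <- x - (stats::lm.fit(cbind(1, tt), x)$fitted.values)
  w <- 0.5 * (1 - cos(2 * pi * (tt - 1L) / (n - 1L)))  # Hann window
  p <- Mod(fft(x * w))^2
  half <- seq(2L, floor(n / 2) + 1L)  # exclude DC
  k <- half[which.max(p[half])]
  (k - 1L) * trial$rate / n
}

#' Time-normalize selected cycles to a fixed posture block
#'
#' Interpolates all 18 coordinate signals of each selected cycle onto
#' `frames_per_cycle` equally spaced phase points (0, 1/30, ..., 29/30 of
#' the cycle duration; the end boundary is excluded so consecutive cycles
#' do not duplicate a frame). All coordinates share the same time base, so
#' phase lags between segments are preserved. Concatenation of the cycles
#' yields the trial's posture block.
#'
#' @param trial A frontal-plane `sway_uniform_trial`.
#' @param seg A selected `sway_cycles` with exactly `n_cycles` cycles.
#' @param n_cycles Required cycle count (default 10).
#' @param frames_per_cycle Phase samples per cycle (default 30).
#' @return Matrix of `n_cycles * frames_per_cycle` rows x 18 columns.
#' @export
time_normalize <- function(trial, seg, n_cycles = 10L, frames_per_cycle = 30L) {
  if (isTRUE(seg$discarded) || seg$n_cycles != n_cycles) {
    abort_sway(sprintf("segmentation must hold exactly %d cycles", n_cycles),
               "invalid_argument")
  }
  b <- seg$boundaries
  phases <- (seq_len(frames_per_cycle) - 1L) / frames_per_cycle
  taus <- unlist(lapply(seq_len(n_cycles), function(c) {
    t0 <- trial$time[b[c]]
    t1 <- trial$time[b[c + 1L]]
    t0 + phases * (t1 - t0)
  }))
  out <- apply(trial$coords, 2L, function(col) {
    stats::spline(trial$time, col, xout = taus, method = "fmm")$y
  })
  rownames(out) <- NULL
  out
}

#' Preprocess one raw trial end to end
#'
#' Resample, reduce to the frontal plane, segment cycles, select the
#' analysis cycles, compute sway amplitude and frequency, and
#' time-normalize. Trials with too few cycles (or no detectable
#' oscillation) are flagged discarded rather than raising.
#'
#' @param raw A `sway_raw_trial`.
#' @param rate Resampling rate, Hz.
#' @param n_cycles Cycles required per trial.
#' @return List: `trial_id`, `discarded`, `reason`, `frames` (300 x 18
#'   matrix or NULL), `amplitude` (m), `frequency` (Hz).
#' @export
preprocess_trial <- function(raw, rate = 30, n_cycles = 10L) {
  uni <- reduce_to_frontal(resample_uniform(raw, rate = rate))
  seg <- tryCatch(detect_cycles(uni), swaysom_no_cycles = function(e) NULL)
  if (is.null(seg)) {
    return(list(trial_id = raw$trial_id, discarded = TRUE,
                reason = "no cycles detected", frames = NULL,
                amplitude = NA_real_, frequency = NA_real_))
  }
  sel <- select_cycles(seg, n = n_cycles)
  freq <- tryCatch(sway_frequency(uni), swaysom_invalid_argument = function(e) NA_real_)
  if (isTRUE(sel$discarded)) {
    return(list(trial_id = raw$trial_id, discarded = TRUE,
                reason = sprintf("only %d cycles after dropping the first",
                                 sel$n_available),
                frames = NULL, amplitude = NA_real_, frequency = freq))
  }
  list(trial_id = raw$trial_id, discarded = FALSE, reason = NA_character_,
       frames = time_normalize(uni, sel, n_cycles = n_cycles),
       amplitude = sway_amplitude(uni, sel), frequency = freq)
}

#' Preprocess a cohort into a posture array
#'
#' Applies [preprocess_trial()] to every trial and stacks the retained
#' trials into the 3-dimensional posture array `P` (trials x 300 frames x
#' 18 coordinates).
#'
#' @param cohort A `sway_cohort` (or a plain list of `sway_raw_trial`s).
#' @param rate,n_cycles See [preprocess_trial()].
#' @return A `sway_posture_array`: list with `values` (I x J x K array),
#'   `info` (data frame of retained-trial metadata incl. amplitude and
#'   frequency) and `metrics` (per-trial metrics for all trials incl. the
#'   discarded flag).
#' @export
preprocess_cohort <- function(cohort, rate = 30, n_cycles = 10L) {
  trials <- if (inherits(cohort, "sway_cohort")) cohort$trials else cohort
  manifest <- if (inherits(cohort, "sway_cohort")) cohort$manifest else NULL
  res <- lapply(trials, preprocess_trial, rate = rate, n_cycles = n_cycles)
  metrics <- data.frame(
    trial_id = vapply(res, `[[`, character(1), "trial_id"),
    discarded = vapply(res, `[[`, logical(1), "discarded"),
    amplitude_m = vapply(res, `[[`, numeric(1), "amplitude"),
    frequency_hz = vapply(res, `[[`, numeric(1), "frequency"),
    stringsAsFactors = FALSE
  )
  rownames(metrics) <- NULL
  if (!is.null(manifest)) {
    metrics <- merge(manifest, metrics, by = "trial_id", sort = FALSE)
  }
  kept <- Filter(function(r) !r$discarded, res)
  J <- n_cycles * 30L
  K <- 18L
  values <- array(NA_real_, dim = c(length(kept), J, K),
                  dimnames = list(vapply(kept, `[[`, character(1), "trial_id"),
                                  NULL, posture_colnames()))
  for (i in seq_along(kept)) values[i, , ] <- kept[[i]]$frames
  info <- metrics[!metrics$discarded, , drop = FALSE]
  rownames(info) <- NULL
  structure(list(values = values, info = info, metrics = metrics),
            class = "sway_posture_array")
}

#' @export
print.sway_posture_array <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<sway_posture_array> %d trials x %d frames x %d coordinates (%d discarded)\n",
              d[1], d[2], d[3], sum(x$metrics$discarded)))
  invisible(x)
}
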