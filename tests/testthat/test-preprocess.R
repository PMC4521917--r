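test_that("cubic-spline resampling is exact where it should be", {
  # knots of an already-uniform 30 Hz recording are reproduced
  t <- seq(0, 5, by = 1 / 30)
  tr <- make_raw_trial(t)
  out <- resample_uniform(tr, rate = 30)
  expect_lt(max(abs(out$coords - tr$positions)), 1e-9)
  expect_equal(diff(range(diff(out$time))), 0, tolerance = 1e-12)

  # a cubic polynomial sampled irregularly is recovered exactly
  set.seed(1)
  tj <- sort(runif(200, 0, 6))
  cub <- function(t) 0.3 + 0.2 * t - 0.05 * t^2 + 0.01 * t^3
  trc <- make_raw_trial(tj, fun = cub)
  outc <- resample_uniform(trc, rate = 30)
  expected <- vapply(seq_len(45), function(j) cub(outc$time) + j / 100,
                     numeric(length(outc$time)))
  expect_lt(max(abs(outc$coords - expected)), 1e-9)

  # a 1 Hz sinusoid sampled at ~30 Hz with jitter: error < 1e-4 m
  set.seed(2)
  ts <- seq(0, 10, by = 1 / 30) + runif(301, -0.005, 0.005)
  ts <- sort(ts)
  sine <- function(t) 0.1 * sin(2 * pi * t)
  trs <- make_raw_trial(ts, fun = sine)
  outs <- resample_uniform(trs, rate = 30)
  inner <- outs$time > 0.2 & outs$time < 9.8  # spline ends are less accurate
  err <- abs(outs$coords[inner, 1L] - (sine(outs$time[inner]) + 1 / 100))
  expect_lt(max(err), 1e-4)

  expect_error(resample_uniform(make_raw_trial(c(0, 0.1, 0.2))),
               class = "swaysom_malformed_input")
  bad <- make_raw_trial(c(0, 0.1, 0.05, 0.2, 0.3))
  expect_error(resample_uniform(bad), class = "swaysom_malformed_input")
})

test_that("frontal reduction keeps 9 labelled landmarks in posture order", {
  t <- seq(0, 3, by = 1 / 30)
  uni <- resample_uniform(make_raw_trial(t))
  red <- reduce_to_frontal(uni)
  expect_equal(ncol(red$coords), 18L)
  expect_identical(colnames(red$coords), posture_colnames())
  expect_false(any(grepl("hand|elbow|foot|_z$", colnames(red$coords))))

  # selection is label-driven: permuting columns changes nothing
  perm <- uni
  perm$coords <- perm$coords[, rev(colnames(perm$coords))]
  expect_identical(reduce_to_frontal(perm)$coords, red$coords)

  # all-zero input stays all-zero
  zero <- uni
  zero$coords[] <- 0
  expect_true(all(reduce_to_frontal(zero)$coords == 0))

  broken <- uni
  colnames(broken$coords)[1L] <- "skull_x"
  expect_error(reduce_to_frontal(broken), class = "swaysom_malformed_input")
})

test_that("cycle detection finds the outermost-left shoulder positions", {
  # sin over 12 periods has 12 interior minima -> 11 complete cycles
  f <- 0.5
  tr <- make_frontal_trial(function(t) 0.1 * sin(2 * pi * f * t),
                           duration = 12 / f)
  seg <- detect_cycles(tr)
  expect_equal(seg$n_cycles, 11L)
  # boundaries sit at the analytic minima t = 3/(4f) + k/f, within 1 frame
  analytic <- 3 / (4 * f) + (0:11) / f
  detected <- tr$time[seg$boundaries]
  expect_lt(max(abs(detected - analytic[seq_along(detected)])), 1 / 30 + 1e-9)

  # monotone drift has no cycles
  drift <- make_frontal_trial(function(t) 0.01 * t, duration = 10)
  expect_error(detect_cycles(drift), class = "swaysom_no_cycles")

  # moderate noise does not change the cycle count
  set.seed(4)
  noisy <- make_frontal_trial(function(t) 0.1 * sin(2 * pi * f * t) +
                                rnorm(length(t), sd = 0.005),
                              duration = 12 / f)
  expect_equal(detect_cycles(noisy)$n_cycles, 11L)
})

test_that("cycle selection drops the first cycle and flags short trials", {
  tr <- make_frontal_trial(function(t) 0.1 * sin(2 * pi * 0.5 * t),
                           duration = 26)  # 13 periods -> 12 cycles
  seg <- detect_cycles(tr)
  expect_gte(seg$n_cycles, 11L)
  sel <- select_cycles(seg, 10)
  expect_false(sel$discarded)
  expect_equal(sel$n_cycles, 10L)
  # selected cycles are the 2nd..11th detected ones
  expect_identical(sel$boundaries, seg$boundaries[2:12])

  short <- detect_cycles(make_frontal_trial(
    function(t) 0.1 * sin(2 * pi * 0.5 * t), duration = 20))  # 10 periods
  expect_true(select_cycles(short, 10)$discarded)
})

test_that("sway amplitude is the mean per-cycle peak-to-peak ML excursion", {
  tr <- make_frontal_trial(function(t) 0.1 * sin(2 * pi * 0.5 * t),
                           duration = 26)
  sel <- select_cycles(detect_cycles(tr), 10)
  expect_equal(sway_amplitude(tr, sel), 0.2, tolerance = 1e-3)

  # constant lower back with oscillating shoulders: amplitude 0
  tr0 <- make_frontal_trial(function(t) 0.1 * sin(2 * pi * 0.5 * t),
                            duration = 26)
  tr0$coords[, "lower_back_x"] <- 0.5
  sel0 <- select_cycles(detect_cycles(tr0), 10)
  expect_equal(sway_amplitude(tr0, sel0), 0)

  # two cycles with excursions 0.18 and 0.22 average to 0.20
  rate <- 30
  tcut <- 2  # one 0.5 Hz period
  trm <- make_frontal_trial(function(t) {
    a <- ifelse(t < tcut, 0.09, 0.11)
    a * sin(2 * pi * 0.5 * t)
  }, duration = 4)
  seg <- structure(list(boundaries = c(1L, 1L + 2 * rate, 1L + 4 * rate),
                        n_cycles = 2L, durations = c(2, 2), rate = rate,
                        discarded = FALSE), class = "sway_cycles")
  expect_equal(sway_amplitude(trm, seg), 0.2, tolerance = 1e-3)

  expect_error(sway_amplitude(tr, select_cycles(detect_cycles(tr), 100)),
               class = "swaysom_invalid_argument")
})

test_that("dominant frequency comes from the lower-back power spectrum", {
  tr <- make_frontal_trial(function(t) 0.1 * sin(2 * pi * 0.5 * t),
                           duration = 60)
  expect_equal(sway_frequency(tr), 0.5, tolerance = (30 / (60 * 30)) / 0.5)

  # a strong 0.5 Hz tone beats a weak 2 Hz tone
  tr2 <- make_frontal_trial(function(t) sin(2 * pi * 0.5 * t) +
                              0.2 * sin(2 * pi * 2 * t), duration = 60)
  expect_equal(sway_frequency(tr2), 0.5, tolerance = 0.05)

  # white noise: not a physical claim, just a deterministic regression
  set.seed(9)
  trn <- make_frontal_trial(function(t) rnorm(length(t), sd = 0.01),
                            duration = 30)
  f1 <- sway_frequency(trn)
  expect_true(f1 > 0 && f1 < 15)
  expect_identical(sway_frequency(trn), f1)

  short <- make_frontal_trial(function(t) sin(2 * pi * t), duration = 2)
  expect_error(sway_frequency(short), class = "swaysom_invalid_argument")
})

test_that("single-tone frequency recovery holds across the sway band", {
  for (f in seq(0.2, 2, by = 0.3)) {
    dur <- 60
    tr <- make_frontal_trial(function(t) 0.1 * sin(2 * pi * f * t),
                             duration = dur)
    bin <- 30 / length(tr$time)
    expect_equal(sway_frequency(tr), f, tolerance = (bin + 1e-9) / f)
  }
})

test_that("time normalization yields 300 frames and preserves phase lags", {
  subj <- toy_subject(variability = 0.08)
  tr <- generate_trial(subj, neutral_condition(), n_cycles = 10, seed = 21)
  uni <- reduce_to_frontal(resample_uniform(tr))
  sel <- select_cycles(detect_cycles(uni), 10)
  frames <- time_normalize(uni, sel)
  expect_equal(dim(frames), c(300L, 18L))
  expect_true(all(is.finite(frames)))

  # a constant phase offset between two signals survives normalization
  f0 <- 0.5
  lag_s <- 0.2
  trl <- make_frontal_trial(function(t) 0.1 * sin(2 * pi * f0 * t),
                            duration = 26)
  trl$coords[, "head_x"] <- 0.1 * sin(2 * pi * f0 * (trl$time + lag_s))
  sell <- select_cycles(detect_cycles(trl), 10)
  fl <- time_normalize(trl, sell)
  cc <- stats::ccf(fl[, "head_x"], fl[, "lower_back_x"], lag.max = 10,
                   plot = FALSE)
  best_lag <- cc$lag[which.max(cc$acf)]
  # 0.2 s at 0.5 Hz is 10% of a cycle = 3 of 30 phase samples (the sign
  # encodes which signal leads; the magnitude is what must survive)
  expect_lte(abs(abs(best_lag) - 3), 1)

  # identical cycles produce 10 identical blocks
  tri <- make_frontal_trial(function(t) 0.1 * sin(2 * pi * 0.5 * t),
                            duration = 26)
  seli <- select_cycles(detect_cycles(tri), 10)
  fi <- time_normalize(tri, seli)
  for (c in 1:9) {
    expect_lt(max(abs(fi[(c * 30 + 1):((c + 1) * 30), ] - fi[1:30, ])), 1e-4)
  }

  expect_error(time_normalize(uni, select_cycles(detect_cycles(uni), 9)),
               class = "swaysom_invalid_argument")
})

test_that("cohort preprocessing keeps complete trials and flags short ones", {
  co <- generate_cohort(cohort_config(n_young = 2, n_old = 2,
                                      condition_ids = c(1, 3),
                                      trials_per_condition = 1,
                                      corrupted = c(young = 1, old = 1),
                                      seed = 31))
  pa <- preprocess_cohort(co)
  expect_s3_class(pa, "sway_posture_array")
  expect_equal(sum(pa$metrics$discarded), 2L)
  expect_equal(dim(pa$values), c(6L, 300L, 18L))
  expect_true(all(is.finite(pa$values)))
  # discarded flags line up with the corruption ground truth
  expect_identical(pa$metrics$trial_id[pa$metrics$discarded],
                   co$manifest$trial_id[co$manifest$corrupted])
})
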