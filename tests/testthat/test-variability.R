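make_cycle_nodes <- function(per_cycle) {
  # stack 10 copies (or a list of 10 paths) of 30 x 2 lattice coordinates
  if (is.list(per_cycle)) do.call(rbind, per_cycle)
  else do.call(rbind, replicate(10, per_cycle, simplify = FALSE))
}

test_that("trajectories split into ordered 30-frame cycles", {
  nodes <- cbind(0:299, 299:0)
  cyc <- split_into_cycles(nodes)
  expect_equal(dim(cyc), c(10L, 30L, 2L))
  for (c in 1:10) {
    expect_equal(cyc[c, , 1], seq((c - 1) * 30, c * 30 - 1))
  }
  # round trip
  rebuilt <- do.call(rbind, lapply(1:10, function(c) cyc[c, , ]))
  expect_equal(rebuilt, unname(nodes), ignore_attr = TRUE)

  const <- matrix(5, nrow = 300, ncol = 2)
  cc <- split_into_cycles(const)
  expect_true(all(cc == 5))

  expect_error(split_into_cycles(nodes[1:100, ]),
               class = "swaysom_invalid_argument")
})

test_that("pairwise phase distances match hand cases and the oracle", {
  same <- split_into_cycles(matrix(2, nrow = 300, ncol = 2))
  expect_equal(pairwise_phase_distance(same, 7), 0)

  # two cycle paths at (0,0) and (3,4): distance 5 at every phase
  two <- split_into_cycles(make_cycle_nodes(list(
    matrix(0, 30, 2), matrix(c(3, 4), 30, 2, byrow = TRUE),
    matrix(0, 30, 2), matrix(c(3, 4), 30, 2, byrow = TRUE),
    matrix(0, 30, 2), matrix(c(3, 4), 30, 2, byrow = TRUE),
    matrix(0, 30, 2), matrix(c(3, 4), 30, 2, byrow = TRUE),
    matrix(0, 30, 2), matrix(c(3, 4), 30, 2, byrow = TRUE))))
  # 25 of 45 unordered pairs cross the two paths
  expect_equal(pairwise_phase_distance(two, 1), 5 * 25 / 45)

  set.seed(30)
  for (i in 1:100) {
    nodes <- matrix(sample(0:24, 600, replace = TRUE), ncol = 2)
    cyc <- split_into_cycles(nodes)
    b <- sample(30, 1)
    expect_equal(pairwise_phase_distance(cyc, b),
                 brute_pairwise_mean(cyc[, b, ]))
  }
  expect_error(pairwise_phase_distance(same, 31),
               class = "swaysom_invalid_argument")
})

test_that("TTvar is zero iff cycles are identical and matches hand arithmetic", {
  ident <- make_cycle_nodes(cbind(0:29, rep(3, 30)))
  expect_equal(ttvar(ident)$ttvar, 0)

  # 5 cycles on each of two paths a lattice distance 5 apart at every
  # phase: each frame's mean distance to the 9 other cycles is 5 * 5/9
  paths <- lapply(1:10, function(c) {
    if (c %% 2 == 1) matrix(0, 30, 2) else matrix(c(3, 4), 30, 2, byrow = TRUE)
  })
  tt <- ttvar(make_cycle_nodes(paths))
  expect_equal(unique(round(tt$per_frame, 12)), 25 / 9)
  expect_equal(tt$ttvar, 300 * 25 / 9)

  # non-identical cycles give strictly positive TTvar
  jit <- make_cycle_nodes(lapply(1:10, function(c) cbind(0:29, c)))
  expect_gt(ttvar(jit)$ttvar, 0)

  expect_error(ttvar(matrix(0, 100, 2)), class = "swaysom_invalid_argument")
})

test_that("the phase-aggregated TTvar is invariant to cycle relabelling", {
  set.seed(31)
  nodes <- matrix(sample(0:24, 600, replace = TRUE), ncol = 2)
  base <- ttvar(nodes)$ttvar
  for (r in 1:5) {
    perm <- sample(10)
    permuted <- do.call(rbind, lapply(perm, function(c) {
      nodes[((c - 1) * 30 + 1):(c * 30), ]
    }))
    expect_equal(ttvar(permuted)$ttvar, base)
  }
})

test_that("sway phases split 14 endpoint / 16 traveling", {
  ph <- phase_of(1:30)
  expect_equal(sum(ph == "endpoint"), 14L)
  expect_equal(sum(ph == "traveling"), 16L)
  # turning points: cycle boundary (left) and mid-cycle (right)
  expect_equal(phase_of(1), "endpoint")
  expect_equal(phase_of(16), "endpoint")
  # quarter cycle is traveling
  expect_equal(phase_of(8), "traveling")
  expect_equal(phase_of(23), "traveling")
  # windows are 7 wide and wrap across the cycle boundary
  expect_equal(phase_of(28), "endpoint")
  expect_equal(phase_of(4), "endpoint")
  expect_equal(phase_of(5), "traveling")
  expect_error(phase_of(0), class = "swaysom_invalid_argument")
  expect_error(phase_of(31), class = "swaysom_invalid_argument")
})

test_that("node variability ellipses use the SEM of BMU coordinates", {
  ident <- split_into_cycles(make_cycle_nodes(cbind(0:29, rep(3, 30))))
  nv <- node_variability(ident)
  expect_true(all(nv$h_radius == 0))
  expect_true(all(nv$area == 0))

  # x-coordinates {0 x5, 10 x5}: SEM = sd/sqrt(10) = 5.2705/3.1623
  paths <- lapply(1:10, function(c) {
    x <- if (c <= 5) 0 else 10
    cbind(rep(x, 30), rep(2, 30))
  })
  nv2 <- node_variability(split_into_cycles(make_cycle_nodes(paths)))
  expect_equal(nv2$h_radius[1], sd(c(rep(0, 5), rep(10, 5))) / sqrt(10))
  expect_equal(nv2$h_radius[1], 1.6667, tolerance = 1e-4)
  expect_equal(nv2$v_radius[1], 0)
  expect_equal(nv2$area[1], 0)

  set.seed(32)
  nodes <- matrix(runif(600, 0, 24), ncol = 2)
  cyc <- split_into_cycles(nodes)
  nv3 <- node_variability(cyc)
  for (b in sample(30, 10)) {
    oracle <- brute_sem_ellipse(cyc[, b, 1], cyc[, b, 2])
    expect_equal(nv3$h_radius[b], unname(oracle["h"]))
    expect_equal(nv3$v_radius[b], unname(oracle["v"]))
    expect_equal(nv3$area[b], unname(oracle["area"]))
  }
})

test_that("phase summaries average ellipses within each sway phase", {
  uniform <- data.frame(phase = 1:30, sway_phase = phase_of(1:30),
                        h_radius = 1, v_radius = 1, area = pi)
  ps <- phase_summary(uniform)
  expect_equal(ps$mean_area[ps$sway_phase == "endpoint"],
               ps$mean_area[ps$sway_phase == "traveling"])
  expect_equal(sort(ps$n_phases), c(14L, 16L))

  mixed <- uniform
  mixed$area <- ifelse(mixed$sway_phase == "endpoint", 1, 2)
  ps2 <- phase_summary(mixed)
  expect_equal(ps2$mean_area[ps2$sway_phase == "endpoint"], 1)
  expect_equal(ps2$mean_area[ps2$sway_phase == "traveling"], 2)
})

test_that("extra turning-point jitter raises endpoint variability", {
  # cycles follow a common loop; add jitter only near phases 1 and 16
  set.seed(33)
  loop <- cbind(10 + 8 * cos(2 * pi * (0:29) / 30),
                10 + 8 * sin(2 * pi * (0:29) / 30))
  endpoint <- phase_of(1:30) == "endpoint"
  paths <- lapply(1:10, function(c) {
    p <- loop
    p[endpoint, ] <- p[endpoint, ] + matrix(rnorm(2 * sum(endpoint), sd = 2),
                                            ncol = 2)
    p
  })
  nv <- node_variability(split_into_cycles(make_cycle_nodes(paths)))
  ps <- phase_summary(nv)
  expect_gt(ps$mean_area[ps$sway_phase == "endpoint"],
            ps$mean_area[ps$sway_phase == "traveling"])
})

test_that("Mann-Whitney U handles exact, tied and approximate cases", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)
  expect_equal(mw$method, "exact")

  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p, 1)

  # exact enumeration agrees with wilcox.test on tie-free small samples
  set.seed(34)
  for (i in 1:50) {
    a <- rnorm(sample(3:6, 1))
    b <- rnorm(sample(3:6, 1))
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    mwi <- mann_whitney_u(a, b)
    expect_equal(mwi$U, unname(ref$statistic))
    expect_equal(mwi$p, ref$p.value, tolerance = 1e-12)
  }

  # normal approximation stays within 0.02 of the enumeration oracle
  set.seed(35)
  for (i in 1:20) {
    a <- rnorm(8)
    b <- rnorm(8)
    approx_p <- mann_whitney_u(a, b)$p
    expect_lt(abs(approx_p - brute_mw_exact_p(a, b)), 0.02)
  }

  expect_error(mann_whitney_u(numeric(0), 1:3),
               class = "swaysom_invalid_argument")
})

test_that("group comparison summarises TTvar per condition", {
  df <- data.frame(
    ttvar = c(1, 2, 3, 4, 10, 11, 12, 13),
    group = rep(c("young", "old"), each = 4),
    condition_id = rep(c(1, 1, 3, 3), 2)
  )
  cmp <- compare_ttvar_groups(df)
  expect_equal(nrow(cmp), 2L)
  expect_equal(cmp$median_young, c(1.5, 3.5))
  expect_equal(cmp$median_old, c(10.5, 12.5))
  expect_true(all(cmp$p <= 1 & cmp$p >= 0))
})
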