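# Movement-pattern variability from BMU trajectories.
#
# A trial's trajectory holds 300 BMUs: 10 sway cycles x 30 phase points.
# Total Trajectory Variability (TTvar) measures how far phase-matched
# points of the repeated cycles lie apart on the lattice: each frame gets
# the mean Euclidean lattice distance from its BMU to the BMUs of the 9
# other cycles at the same phase, and TTvar is the sum of the 300 per-frame
# entries. TTvar is a lattice distance and therefore unitless.

as_traj_nodes <- function(traj) {
  if (inherits(traj, "sway_trajectory")) traj$nodes else as.matrix(traj)
}

#' Split a BMU trajectory into its sway cycles
#'
#' @param traj A `sway_trajectory` or 300 x 2 matrix of lattice coordinates.
#' @param n_cycles,frames_per_cycle Cycle structure (default 10 x 30).
#' @return A `sway_cycle_set`: array of dim `c(n_cycles, frames_per_cycle,
#'   2)` (cycle, phase, lattice coordinate).
#' @export
split_into_cycles <- function(traj, n_cycles = 10L, frames_per_cycle = 30L) {
  nodes <- as_traj_nodes(traj)
  if (nrow(nodes) != n_cycles * frames_per_cycle || ncol(nodes) != 2L) {
    abort_sway(sprintf("trajectory must be %d x 2", n_cycles * frames_per_cycle),
               "invalid_argument")
  }
  out <- array(NA_real_, dim = c(n_cycles, frames_per_cycle, 2L),
               dimnames = list(NULL, NULL, c("x", "y")))
  for (c in seq_len(n_cycles)) {
    idx <- ((c - 1L) * frames_per_cycle + 1L):(c * frames_per_cycle)
    out[c, , ] <- nodes[idx, ]
  }
  structure(out, class = c("sway_cycle_set", "array"))
}

#' Mean pairwise lattice distance between cycles at one phase
#'
#' Euclidean distance between each unordered pair of cycles' BMU
#' coordinates at phase `b`, averaged over all pairs (45 pairs for 10
#' cycles).
#'
#' @param cycles A `sway_cycle_set`.
#' @param b Phase index, 1-based.
#' @return Non-negative scalar.
#' @export
pairwise_phase_distance <- function(cycles, b) {
  np <- dim(cycles)[2L]
  if (!is_count(b, 1L) || b > np) {
    abort_sway(sprintf("phase must be in 1..%d", np), "invalid_argument")
  }
  pts <- cycles[, b, , drop = TRUE]
  mean(stats::dist(pts))
}

#' Total Trajectory Variability of a trial
#'
#' For every frame, the mean Euclidean distance (on the output lattice by
#' default) from that frame's BMU to the phase-matched BMUs of the other
#' cycles; TTvar is the sum of all per-frame entries. Zero iff all cycles
#' follow an identical lattice path.
#'
#' A weight-space variant (`space = "weight"`, requires the trained map and
#' the 1-based node indices on the trajectory) measures the same
#' construction with distances between BMU weight vectors instead of
#' lattice coordinates; it is provided for comparison and is not the
#' default.
#'
#' @param traj A `sway_trajectory` or 300 x 2 lattice-coordinate matrix.
#' @param space `"lattice"` (default) or `"weight"`.
#' @param model A trained `sway_som`, required for `space = "weight"`.
#' @param n_cycles,frames_per_cycle Cycle structure (default 10 x 30).
#' @return A `sway_ttvar`: list with `trial_id`, `ttvar` and `per_frame`
#'   (length 300).
#' @export
ttvar <- function(traj, space = c("lattice", "weight"), model = NULL,
                  n_cycles = 10L, frames_per_cycle = 30L) {
  space <- match.arg(space)
  if (space == "lattice") {
    pts_mat <- as_traj_nodes(traj)
  } else {
    if (is.null(model) || !inherits(traj, "sway_trajectory") ||
        is.null(traj$node_index)) {
      abort_sway("weight-space TTvar needs a sway_trajectory with node indices and the trained model",
                 "invalid_argument")
    }
    pts_mat <- model$weights[traj$node_index, , drop = FALSE]
  }
  J <- n_cycles * frames_per_cycle
  if (nrow(pts_mat) != J) {
    abort_sway(sprintf("trajectory must have %d frames", J), "invalid_argument")
  }
  per_frame <- numeric(J)
  for (b in seq_len(frames_per_cycle)) {
    rows <- b + frames_per_cycle * (seq_len(n_cycles) - 1L)
    pts <- pts_mat[rows, , drop = FALSE]
    D <- as.matrix(stats::dist(pts))
    per_frame[rows] <- rowSums(D) / (n_cycles - 1L)
  }
  structure(list(trial_id = if (inherits(traj, "sway_trajectory")) traj$trial_id else NULL,
                 ttvar = sum(per_frame), per_frame = per_frame, space = space),
            class = "sway_ttvar")
}

#' Classify cycle phases as sway endpoint or traveling
#'
#' The sway endpoint phases are the 7 phase points centered on each turning
#' point - the left turn at the cycle boundary (phase 1, windows wrapping
#' across the boundary) and the right turn at mid-cycle (phase 16) - giving
#' 14 endpoint phases; the remaining 16 are traveling phases.
#'
#' @param phase Integer phase index (1..30), vectorized.
#' @param frames_per_cycle Phase points per cycle (default 30).
#' @return Character vector: `"endpoint"` or `"traveling"`.
#' @export
phase_of <- function(phase, frames_per_cycle = 30L) {
  if (any(!is.finite(phase)) || any(phase < 1L) || any(phase > frames_per_cycle) ||
      any(phase != round(phase))) {
    abort_sway(sprintf("phase must be an integer in 1..%d", frames_per_cycle),
               "invalid_argument")
  }
  half <- frames_per_cycle / 2L
  left <- ((1L + seq(-3L, 3L) - 1L) %% frames_per_cycle) + 1L
  right <- (1L + half) + seq(-3L, 3L)
  ifelse(phase %in% c(left, right), "endpoint", "traveling")
}

#' Per-phase variability ellipses of a cycle set
#'
#' For each phase point, the horizontal (x) and vertical (y) radius is the
#' standard error of the mean of the cycles' BMU coordinates, and the
#' ellipse area is `pi * h * v`.
#'
#' @param cycles A `sway_cycle_set`.
#' @return Data frame: `phase`, `sway_phase` (endpoint/traveling),
#'   `h_radius`, `v_radius`, `area`.
#' @export
node_variability <- function(cycles) {
  np <- dim(cycles)[2L]
  nc <- dim(cycles)[1L]
  h <- v <- numeric(np)
  for (b in seq_len(np)) {
    h[b] <- sd(cycles[, b, 1L]) / sqrt(nc)
    v[b] <- sd(cycles[, b, 2L]) / sqrt(nc)
  }
  data.frame(phase = seq_len(np),
             sway_phase = phase_of(seq_len(np), frames_per_cycle = np),
             h_radius = h, v_radius = v, area = pi * h * v,
             stringsAsFactors = FALSE)
}

#' Average variability per sway phase
#'
#' Means of the ellipse area and radii over the endpoint phases and over
#' the traveling phases.
#'
#' @param ellipses Output of [node_variability()].
#' @return Data frame with one row per sway phase: `sway_phase`, `n_phases`,
#'   `mean_area`, `mean_h_radius`, `mean_v_radius`.
#' @export
phase_summary <- function(ellipses) {
  agg <- lapply(split(ellipses, ellipses$sway_phase), function(d) {
    data.frame(sway_phase = d$sway_phase[1L], n_phases = nrow(d),
               mean_area = mean(d$area), mean_h_radius = mean(d$h_radius),
               mean_v_radius = mean(d$v_radius), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$sway_phase), , drop = FALSE]
}

#' Mann-Whitney U test (rank-sum), exact for small samples
#'
#' U statistic with midrank tie handling. For `n_a + n_b <= 12` the
#' two-sided p-value is exact, by full enumeration of all assignments of
#' the pooled (mid)ranks; otherwise the normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param a,b Numeric samples.
#' @return List: `U` (for sample `a`), `p` (two-sided), `method`.
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    abort_sway("both samples must be non-empty", "invalid_argument")
  }
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (n <= 12L) {
    sel <- combn(n, na)
    Us <- colSums(matrix(r[sel], nrow = na)) - na * (na + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(Us <= U + eps), mean(Us >= U - eps)))
    method <- "exact"
  } else {
    mu <- na * nb / 2
    tie_counts <- table(c(a, b))
    tie_term <- sum(tie_counts^3 - tie_counts) / (n * (n - 1))
    sig2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- U - mu
      z <- (z - sign(z) * 0.5) / sqrt(sig2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal_approximation"
  }
  list(U = U, p = p, method = method)
}

#' Compare TTvar between groups, per condition
#'
#' @param ttvar_df Data frame with columns `ttvar`, `group` (young/old) and
#'   `condition_id`.
#' @return Data frame per condition: group medians, `U`, `p`.
#' @export
compare_ttvar_groups <- function(ttvar_df) {
  out <- lapply(split(ttvar_df, ttvar_df$condition_id), function(d) {
    young <- d$ttvar[d$group == "young"]
    old <- d$ttvar[d$group == "old"]
    mw <- mann_whitney_u(old, young)
    data.frame(condition_id = d$condition_id[1L],
               n_young = length(young), n_old = length(old),
               median_young = median(young), median_old = median(old),
               U = mw$U, p = mw$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
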