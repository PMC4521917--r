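# Kohonen self-organizing map, written from scratch: random initialization
# within the data range, sequential (online) training with a Gaussian
# lattice neighborhood and linearly decaying schedules, and mapping of
# posture sequences to best-matching-unit (BMU) trajectories.

#' Initialize a self-organizing map
#'
#' Nodes are arranged on a `rows` x `cols` square lattice (0-based integer
#' coordinates, row-major node order) and receive random weights drawn
#' uniformly within the per-coordinate data range.
#'
#' @param rows,cols Lattice size (default 25 x 25).
#' @param dim Weight-vector dimensionality K.
#' @param data_range 2 x K matrix (rows: min, max) or a single `c(min, max)`
#'   pair recycled over coordinates.
#' @param seed Integer seed; initialization is reproducible.
#' @return A `sway_som`: list with `rows`, `cols`, `dim`, `weights`
#'   (nodes x K), `coords` (nodes x 2, 0-based lattice x, y), `seed`,
#'   `trained`.
#' @export
som_init <- function(rows = 25L, cols = 25L, dim, data_range, seed = 1L) {
  if (!is_count(rows, 1L) || !is_count(cols, 1L) || !is_count(dim, 1L)) {
    abort_sway("rows, cols and dim must be positive integers", "invalid_argument")
  }
  if (is.vector(data_range) && length(data_range) == 2L) {
    data_range <- matrix(rep(sort(data_range), dim), nrow = 2L)
  }
  data_range <- as.matrix(data_range)
  if (!all(dim(data_range) == c(2L, dim))) {
    abort_sway("data_range must be a 2 x dim matrix (min; max)", "invalid_argument")
  }
  m <- rows * cols
  node <- seq_len(m) - 1L
  coords <- cbind(x = node %% cols, y = node %/% cols)
  weights <- withr::with_seed(seed, {
    vapply(seq_len(dim), function(k) {
      runif(m, data_range[1L, k], data_range[2L, k])
    }, numeric(m))
  })
  weights <- matrix(weights, nrow = m, ncol = dim)
  structure(list(rows = rows, cols = cols, dim = dim, weights = weights,
                 coords = coords, seed = seed, trained = FALSE,
                 qe_trace = numeric(0)),
            class = "sway_som")
}

#' Range matrix of a data set, for [som_init()]
#'
#' @param data N x K matrix.
#' @return 2 x K matrix of per-coordinate min and max.
#' @export
som_data_range <- function(data) {
  apply(as.matrix(data), 2L, range)
}

#' Best matching unit of a single input vector
#'
#' The node whose weight vector has the smallest Euclidean distance to the
#' input; ties break to the smallest row-major node index.
#'
#' @param model A `sway_som`.
#' @param v Length-K numeric vector.
#' @return Named integer vector `c(x, y)` of 0-based lattice coordinates,
#'   with the 1-based node index as attribute `node`.
#' @export
find_bmu <- function(model, v) {
  if (length(v) != model$dim) {
    abort_sway(sprintf("input has dimension %d, map expects %d",
                       length(v), model$dim), "invalid_argument")
  }
  idx <- bmu_batch_cpp(model$weights, matrix(as.numeric(v), nrow = 1L))[1L]
  structure(c(x = model$coords[idx, 1L], y = model$coords[idx, 2L]),
            node = idx)
}

#' Train a self-organizing map
#'
#' Sequential training: one iteration is one full presentation of all data
#' rows in a freshly shuffled (seeded) order. For each presented vector the
#' BMU and its lattice neighborhood move towards the vector:
#' `w(t+1) = w(t) + h(t) eta(t) (psi - w(t))`, with a Gaussian neighborhood
#' `h = exp(-d_lattice^2 / (2 sigma(t)^2))`. `sigma` decays linearly from
#' `sigma_range[1]` (default `max(rows, cols)/4`) to `sigma_range[2]`
#' (default 1) and the learning rate `eta` linearly from 0.5 to 0.01 over
#' the iterations.
#'
#' @param model A `sway_som` from [som_init()].
#' @param data N x K matrix of input vectors.
#' @param iterations Number of passes over the data (default 1000).
#' @param eta_range `c(start, end)` learning rate.
#' @param sigma_range `c(start, end)` neighborhood radius (lattice units);
#'   default `max(rows, cols) / 4` decaying to 1 (held constant on maps
#'   small enough that the start radius is already below 1).
#' @param subsample If non-NULL, train on this many rows drawn once
#'   (seeded) from `data` - a desk-scale control; the map geometry is
#'   unchanged.
#' @param seed Seed for the presentation order (and subsampling).
#' @return The trained `sway_som`, with `qe_trace` holding the per-iteration
#'   mean BMU distance measured during presentation.
#' @export
som_train <- function(model, data, iterations = 1000L,
                      eta_range = c(0.5, 0.01),
                      sigma_range = NULL,
                      subsample = NULL, seed = 1L) {
  if (is.null(sigma_range)) {
    s0 <- max(model$rows, model$cols) / 4
    sigma_range <- c(s0, min(1, s0))
  }
  data <- as.matrix(data)
  if (nrow(data) < 1L) abort_sway("empty training data", "invalid_argument")
  if (ncol(data) != model$dim) {
    abort_sway("data dimension does not match the map", "invalid_argument")
  }
  if (!is_count(iterations, 1L)) {
    abort_sway("iterations must be a positive integer", "invalid_argument")
  }
  if (eta_range[2L] > eta_range[1L] || sigma_range[2L] > sigma_range[1L]) {
    abort_sway("schedules must be non-increasing", "invalid_argument")
  }
  sched <- function(range, t, T) {
    if (T == 1L) range[1L] else range[1L] + (range[2L] - range[1L]) * (t - 1) / (T - 1)
  }
  weights <- model$weights + 0  # force a copy; C++ updates in place
  coords <- matrix(as.numeric(model$coords), ncol = 2L)
  qe <- numeric(iterations)
  withr::with_seed(seed, {
    if (!is.null(subsample) && subsample < nrow(data)) {
      data <- data[sample.int(nrow(data), subsample), , drop = FALSE]
    }
    n <- nrow(data)
    for (t in seq_len(iterations)) {
      ord <- sample.int(n)
      qe[t] <- som_epoch_cpp(weights, data, ord, coords,
                             sigma = max(sched(sigma_range, t, iterations), 1e-6),
                             eta = sched(eta_range, t, iterations))
    }
  })
  model$weights <- weights
  model$trained <- TRUE
  model$qe_trace <- qe
  model$config <- list(iterations = iterations, eta_range = eta_range,
                       sigma_range = sigma_range, subsample = subsample,
                       train_seed = seed)
  model
}

#' Quantization error of a map on a data set
#'
#' Mean Euclidean distance from each input vector to its BMU's weights.
#'
#' @param model A `sway_som`.
#' @param data N x K matrix.
#' @return Non-negative scalar.
#' @export
quantization_error <- function(model, data) {
  data <- as.matrix(data)
  if (nrow(data) < 1L) abort_sway("empty data", "invalid_argument")
  if (ncol(data) != model$dim) {
    abort_sway("data dimension does not match the map", "invalid_argument")
  }
  idx <- bmu_batch_cpp(model$weights, data)
  mean(sqrt(rowSums((data - model$weights[idx, , drop = FALSE])^2)))
}

#' Map a trial's posture frames to a BMU trajectory
#'
#' @param model A trained `sway_som`.
#' @param frames 300 x K matrix of normalized posture vectors, in frame
#'   order.
#' @param trial_id Optional identifier stored on the trajectory.
#' @param n_frames Required frame count (default 300).
#' @return A `sway_trajectory`: list with `trial_id` and `nodes` (300 x 2
#'   matrix of 0-based lattice x, y).
#' @export
map_trial <- function(model, frames, trial_id = NULL, n_frames = 300L) {
  frames <- as.matrix(frames)
  if (nrow(frames) != n_frames) {
    abort_sway(sprintf("expected %d frames, got %d", n_frames, nrow(frames)),
               "invalid_argument")
  }
  if (ncol(frames) != model$dim) {
    abort_sway("frame dimension does not match the map", "invalid_argument")
  }
  idx <- bmu_batch_cpp(model$weights, frames)
  nodes <- model$coords[idx, , drop = FALSE]
  colnames(nodes) <- c("x", "y")
  structure(list(trial_id = trial_id, nodes = nodes, node_index = idx),
            class = "sway_trajectory")
}

#' @export
print.sway_som <- function(x, ...) {
  cat(sprintf("<sway_som> %d x %d lattice, %d-d weights, %s\n",
              x$rows, x$cols, x$dim,
              if (x$trained) sprintf("trained (%d iterations, final QE %.4g)",
                                     length(x$qe_trace), tail(x$qe_trace, 1))
              else "untrained"))
  invisible(x)
}

#' @export
print.sway_trajectory <- function(x, ...) {
  cat(sprintf("<sway_trajectory> %s: %d BMUs on the lattice\n",
              x$trial_id %||% "(unnamed)", nrow(x$nodes)))
  invisible(x)
}

#' Plot a BMU trajectory on the lattice
#'
#' Base-graphics path of the trajectory over the map, cycle boundaries
#' marked.
#'
#' @param x A `sway_trajectory`.
#' @param rows,cols Lattice extent (defaults to the trajectory's range).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sway_trajectory <- function(x, rows = NULL, cols = NULL, ...) {
  n <- x$nodes
  graphics::plot(n[, 1L], n[, 2L], type = "l", col = "grey50",
                 xlim = c(0, (cols %||% (max(n[, 1L]) + 1)) - 1),
                 ylim = c(0, (rows %||% (max(n[, 2L]) + 1)) - 1),
                 xlab = "lattice x", ylab = "lattice y",
                 main = x$trial_id %||% "BMU trajectory", ...)
  graphics::points(n[, 1L], n[, 2L], pch = 16, cex = 0.5)
  invisible(x)
}
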