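# Amplitude-equalizing normalization of the posture array.
#
# Each trial is centered on its mean posture; the mean absolute excursion
# of every coordinate (its "amplitude") is then rescaled to the cohort
# grand mean for that coordinate. After normalization every trial has the
# same mean amplitude per body-segment coordinate, while the relative
# amplitude differences *between* coordinates (e.g. shoulder ML vs knee
# vertical) are preserved.

#' Center a trial on its mean posture
#'
#' Subtracts the trial's mean posture vector from every frame.
#'
#' @param frames J x K matrix (frames x coordinates) of one trial.
#' @return List with `centered` (J x K, column means zero) and
#'   `mean_posture` (length-K vector).
#' @export
center_trial <- function(frames) {
  frames <- as.matrix(frames)
  if (nrow(frames) < 1L) {
    abort_sway("cannot center an empty trial", "invalid_argument")
  }
  m <- colMeans(frames)
  list(centered = sweep(frames, 2L, m, "-"), mean_posture = m)
}

#' Mean amplitude of each coordinate of a centered trial
#'
#' The amplitude of coordinate k is the mean over frames of the absolute
#' centered excursion, `m_k = mean_j |c_{j,k}|`. A whole-posture-vector
#' variant (`method = "vector_norm"`: mean Euclidean norm of the centered
#' posture vector, identical for every k) is available for comparison but
#' is not the default, since only the per-coordinate reading yields a
#' well-defined per-coordinate scaling factor.
#'
#' @param centered J x K centered matrix (row mean approximately zero).
#' @param method `"coordinate"` (default) or `"vector_norm"`.
#' @return Length-K vector of mean amplitudes (meters).
#' @export
segment_amplitudes <- function(centered, method = c("coordinate", "vector_norm")) {
  method <- match.arg(method)
  centered <- as.matrix(centered)
  cm <- colMeans(centered)
  csd <- apply(centered, 2L, sd)
  off <- abs(cm) > 1e-6 * pmax(csd, .Machine$double.eps)
  if (any(off & csd > 0)) {
    warn_sway("input does not look centered (column mean >> 0); center_trial first",
              "contract_violation")
  }
  if (method == "coordinate") {
    colMeans(abs(centered))
  } else {
    rep(mean(sqrt(rowSums(centered^2))), ncol(centered))
  }
}

#' Fit the amplitude-normalization model over a cohort
#'
#' Computes the per-trial amplitude matrix `M` (I x K), the grand mean
#' amplitudes `m_k` (mean of `M` over trials, per coordinate) and the
#' scaling factors `f_{i,k} = m_k / m_{i,k}`.
#'
#' @param centered_trials List of J x K centered matrices, or an I x J x K
#'   array of centered values.
#' @param amplitude_method Passed to [segment_amplitudes()].
#' @return A `sway_norm_model`: list with `per_trial_means` (I x K),
#'   `grand_means` (K), `scale_factors` (I x K).
#' @export
fit_normalization <- function(centered_trials,
                              amplitude_method = c("coordinate", "vector_norm")) {
  amplitude_method <- match.arg(amplitude_method)
  trials <- as_trial_list(centered_trials)
  M <- do.call(rbind, lapply(trials, segment_amplitudes,
                             method = amplitude_method))
  zero <- which(M == 0, arr.ind = TRUE)
  if (nrow(zero) > 0L) {
    abort_sway(sprintf("degenerate trial: zero amplitude in trial %s, coordinate %s",
                       rownames(M)[zero[1L, 1L]] %||% zero[1L, 1L],
                       colnames(M)[zero[1L, 2L]] %||% zero[1L, 2L]),
               "degenerate_trial")
  }
  grand <- colMeans(M)
  F <- sweep(1 / M, 2L, grand, "*")
  structure(list(per_trial_means = M, grand_means = grand, scale_factors = F,
                 amplitude_method = amplitude_method),
            class = "sway_norm_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_trial_list <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) {
    ids <- dimnames(x)[[1L]]
    out <- lapply(seq_len(dim(x)[1L]), function(i) x[i, , ])
    names(out) <- ids
    out
  } else if (is.list(x)) {
    x
  } else {
    abort_sway("expected a list of matrices or a 3-d array", "invalid_argument")
  }
}

#' Apply a fitted normalization model
#'
#' Rescales every centered value: `psi_{i,j,k} = c_{i,j,k} * f_{i,k}`.
#' After this step the mean absolute value of every coordinate equals the
#' grand mean `m_k` in every trial (verified to 1e-9 relative; a violation
#' raises a classed warning).
#'
#' @param centered_trials List of J x K centered matrices or I x J x K array.
#' @param model A `sway_norm_model` fitted on the same layout.
#' @return I x J x K array of normalized values.
#' @export
apply_normalization <- function(centered_trials, model) {
  trials <- as_trial_list(centered_trials)
  I <- length(trials)
  if (I != nrow(model$scale_factors)) {
    abort_sway("trial count does not match the fitted model", "invalid_argument")
  }
  J <- nrow(trials[[1L]])
  K <- ncol(trials[[1L]])
  if (K != ncol(model$scale_factors)) {
    abort_sway("coordinate count does not match the fitted model", "invalid_argument")
  }
  psi <- array(NA_real_, dim = c(I, J, K),
               dimnames = list(names(trials), NULL, colnames(trials[[1L]])))
  for (i in seq_len(I)) {
    psi[i, , ] <- sweep(as.matrix(trials[[i]]), 2L, model$scale_factors[i, ], "*")
  }
  # Post-condition: equal mean amplitude per coordinate across trials.
  if (identical(model$amplitude_method, "coordinate")) {
    for (i in seq_len(I)) {
      rel <- abs(colMeans(abs(matrix(psi[i, , ], ncol = K))) - model$grand_means) /
        pmax(model$grand_means, .Machine$double.eps)
      if (any(rel > 1e-9)) {
        warn_sway(sprintf("normalization post-condition violated in trial %d (max rel err %.2e)",
                          i, max(rel)), "contract_violation")
        break
      }
    }
  }
  psi
}

#' Center and normalize a posture array in one call
#'
#' @param parray A `sway_posture_array` (or bare I x J x K array).
#' @param amplitude_method Passed to [fit_normalization()].
#' @return A `sway_normalized_array`: list with `values` (I x J x K
#'   normalized array), `model` (`sway_norm_model` augmented with
#'   `trial_mean_postures`) and `info` (trial metadata if available).
#' @export
normalize_posture <- function(parray, amplitude_method = "coordinate") {
  values <- if (inherits(parray, "sway_posture_array")) parray$values else parray
  info <- if (inherits(parray, "sway_posture_array")) parray$info else NULL
  trials <- as_trial_list(values)
  centered <- lapply(trials, center_trial)
  cent_mats <- lapply(centered, `[[`, "centered")
  model <- fit_normalization(cent_mats, amplitude_method = amplitude_method)
  model$trial_mean_postures <- t(vapply(centered, `[[`,
                                        numeric(dim(values)[3L]), "mean_posture"))
  psi <- apply_normalization(cent_mats, model)
  structure(list(values = psi, model = model, info = info),
            class = "sway_normalized_array")
}

#' Normalize trials against frozen grand means
#'
#' Centers each trial, recomputes its own per-coordinate amplitudes, and
#' rescales to the grand means of a previously fitted model. This is how
#' held-out data enter a trained pipeline, and it makes the normalization
#' scale-invariant: multiplying a trial's raw coordinates by any positive
#' constant leaves its normalized block unchanged.
#'
#' @param parray A `sway_posture_array`, bare I x J x K array, or a single
#'   J x K matrix.
#' @param model A fitted `sway_norm_model` supplying `grand_means`.
#' @return A `sway_normalized_array` (or a J x K matrix if a single matrix
#'   was given).
#' @export
normalize_with_model <- function(parray, model) {
  single <- is.matrix(parray)
  values <- if (inherits(parray, "sway_posture_array")) parray$values
            else if (single) array(parray, dim = c(1L, dim(parray))) else parray
  info <- if (inherits(parray, "sway_posture_array")) parray$info else NULL
  trials <- as_trial_list(values)
  K <- dim(values)[3L]
  if (K != length(model$grand_means)) {
    abort_sway("coordinate count does not match the fitted model", "invalid_argument")
  }
  psi <- array(NA_real_, dim = dim(values), dimnames = dimnames(values))
  for (i in seq_along(trials)) {
    ct <- center_trial(trials[[i]])
    m <- segment_amplitudes(ct$centered,
                            method = model$amplitude_method %||% "coordinate")
    if (any(m == 0)) {
      abort_sway(sprintf("degenerate trial %d: zero amplitude", i),
                 "degenerate_trial")
    }
    psi[i, , ] <- sweep(ct$centered, 2L, model$grand_means / m, "*")
  }
  if (single) return(psi[1L, , ])
  structure(list(values = psi, model = model, info = info),
            class = "sway_normalized_array")
}

#' Flatten a normalized posture array into the SOM input matrix
#'
#' Stacks all trials' frames trial-major, frame-minor into an (I*J) x K
#' matrix, together with an invertible row index.
#'
#' @param normalized A `sway_normalized_array` or bare I x J x K array.
#' @return List with `matrix` ((I*J) x K) and `index` (data frame: `row`,
#'   `trial` (index), `trial_id`, `frame`).
#' @export
flatten_for_som <- function(normalized) {
  values <- if (inherits(normalized, "sway_normalized_array")) normalized$values else normalized
  d <- dim(values)
  I <- d[1L]; J <- d[2L]; K <- d[3L]
  mat <- matrix(aperm(values, c(2L, 1L, 3L)), nrow = I * J, ncol = K)
  colnames(mat) <- dimnames(values)[[3L]]
  ids <- dimnames(values)[[1L]] %||% as.character(seq_len(I))
  index <- data.frame(row = seq_len(I * J),
                      trial = rep(seq_len(I), each = J),
                      trial_id = rep(ids, each = J),
                      frame = rep(seq_len(J), times = I),
                      stringsAsFactors = FALSE)
  list(matrix = mat, index = index)
}

#' Persist / restore a normalization model as JSON
#'
#' @param model A `sway_norm_model`.
#' @param path JSON file path.
#' @return `write_norm_model`: the path, invisibly. `read_norm_model`: the
#'   model.
#' @export
write_norm_model <- function(model, path) {
  jsonlite::write_json(list(grand_means = model$grand_means,
                            per_trial_means = model$per_trial_means,
                            scale_factors = model$scale_factors,
                            amplitude_method = model$amplitude_method),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_norm_model
#' @export
read_norm_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(per_trial_means = as.matrix(x$per_trial_means),
                 grand_means = as.numeric(x$grand_means),
                 scale_factors = as.matrix(x$scale_factors),
                 amplitude_method = x$amplitude_method),
            class = "sway_norm_model")
}
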