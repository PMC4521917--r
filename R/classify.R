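# Young/old classification of BMU trajectories: 600-dimensional trajectory
# vectors (all 300 x coordinates, then all 300 y coordinates) from the
# discriminating conditions feed a second SOM; a repeated-split kNN
# classifier then labels trials from their position on that map.

#' Build trajectory vectors from BMU trajectories
#'
#' Each trial's trajectory is flattened to a length-600 vector: the x
#' lattice coordinates of BMUs 1..300 followed by the y coordinates. Rows
#' are restricted to the selected conditions (default: the two complex
#' conditions, where the groups differ in TTvar).
#'
#' @param trajectories Named list of `sway_trajectory` (names = trial ids).
#' @param meta Data frame with `trial_id`, `group`, `condition_id`.
#' @param conditions Condition ids to keep.
#' @return List: `S` (trials x 600 matrix), `labels` (factor young/old),
#'   `trial_id`.
#' @export
build_trajectory_vectors <- function(trajectories, meta, conditions = c(3L, 5L)) {
  keep <- meta$trial_id[meta$condition_id %in% conditions]
  keep <- keep[keep %in% names(trajectories)]
  if (length(keep) == 0L) {
    abort_sway("no trials in the selected conditions", "invalid_argument")
  }
  S <- t(vapply(keep, function(id) {
    nodes <- trajectories[[id]]$nodes
    c(nodes[, 1L], nodes[, 2L])
  }, numeric(2L * nrow(trajectories[[keep[1L]]]$nodes))))
  rownames(S) <- keep
  labels <- factor(meta$group[match(keep, meta$trial_id)],
                   levels = c("young", "old"))
  list(S = S, labels = labels, trial_id = keep)
}

#' Train the second SOM on trajectory vectors
#'
#' A 25 x 25 lattice of 600-dimensional weight vectors by default; each
#' trial is then mapped to its BMU on this map, giving a 2-dimensional
#' representation of the whole trial's movement coordination.
#'
#' @param S Trials x 600 matrix from [build_trajectory_vectors()].
#' @param rows,cols Lattice size.
#' @param iterations,eta_range,sigma_range,subsample See [som_train()].
#' @param seed Seed for initialization and training.
#' @return List: `model` (trained `sway_som`), `bmu` (trials x 2 matrix of
#'   lattice coordinates).
#' @export
train_second_som <- function(S, rows = 25L, cols = 25L, iterations = 200L,
                             eta_range = c(0.5, 0.01),
                             sigma_range = c(max(rows, cols) / 4, 1),
                             subsample = NULL, seed = 1L) {
  S <- as.matrix(S)
  if (nrow(S) < 1L) abort_sway("empty trajectory-vector matrix", "invalid_argument")
  model <- som_init(rows, cols, dim = ncol(S), data_range = som_data_range(S),
                    seed = derive_seed(seed, 1L))
  model <- som_train(model, S, iterations = iterations, eta_range = eta_range,
                     sigma_range = sigma_range, subsample = subsample,
                     seed = derive_seed(seed, 2L))
  idx <- bmu_batch_cpp(model$weights, S)
  bmu <- model$coords[idx, , drop = FALSE]
  colnames(bmu) <- c("x", "y")
  rownames(bmu) <- rownames(S)
  list(model = model, bmu = bmu)
}

# One stratified random split: per class, round(train_fraction * n_class)
# training samples (clamped so both sides of the split are non-empty).
# Assumes an active RNG context supplied by the caller.
stratified_split <- function(labels, train_fraction) {
  labels <- droplevels(as.factor(labels))
  class_n <- table(labels)
  train_n <- pmin(pmax(round(train_fraction * class_n), 1L), class_n - 1L)
  train_idx <- unlist(lapply(levels(labels), function(lv) {
    idx <- which(labels == lv)
    sample(idx, train_n[[lv]])
  }), use.names = FALSE)
  list(train = sort(train_idx),
       test = setdiff(seq_along(labels), train_idx))
}

# Majority-vote kNN prediction for one test matrix against a training set;
# distance ties and vote ties resolve to the single nearest neighbor.
knn_predict <- function(train, train_labels, test, k) {
  lev <- levels(train_labels)
  apply(test, 1L, function(v) {
    d2 <- rowSums(sweep(train, 2L, v, "-")^2)
    ord <- order(d2)
    nb <- train_labels[ord[seq_len(k)]]
    tab <- table(nb)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) top else as.character(train_labels[ord[1L]])
  })
}

#' Repeated-split k-nearest-neighbor classification
#'
#' Per run: a seeded stratified random split (70% training / 30% testing by
#' default), each test sample labeled by the majority vote of its `k`
#' nearest training samples (Euclidean distance); accuracy is the fraction
#' of correctly labeled test samples. The default 100 runs are aggregated
#' into a mean accuracy, with the per-run accuracies retained.
#'
#' @param features Numeric matrix (samples x features), e.g. the BMU
#'   coordinates on the second SOM.
#' @param labels Factor (or character) with at least two classes present.
#' @param k Number of neighbors.
#' @param train_fraction Fraction of samples used for training.
#' @param runs Number of random splits.
#' @param seed Seed; the whole report is reproducible.
#' @return A `sway_knn_report`: list with `accuracies` (per run),
#'   `mean_accuracy`, `k`, `runs`, `train_fraction`, `n`, `seed`.
#' @export
knn_classify <- function(features, labels, k = 5L, train_fraction = 0.7,
                         runs = 100L, seed = 1L) {
  features <- as.matrix(features)
  labels <- droplevels(as.factor(labels))
  n <- nrow(features)
  if (length(labels) != n) {
    abort_sway("labels must match the feature rows", "invalid_argument")
  }
  if (nlevels(labels) < 2L) {
    abort_sway("need at least two classes", "invalid_argument")
  }
  class_n <- table(labels)
  train_n <- pmin(pmax(round(train_fraction * class_n), 1L), class_n - 1L)
  if (k > sum(train_n)) {
    abort_sway("k exceeds the training-set size", "invalid_argument")
  }
  acc <- numeric(runs)
  withr::with_seed(seed, {
    for (r in seq_len(runs)) {
      split <- stratified_split(labels, train_fraction)
      pred <- knn_predict(features[split$train, , drop = FALSE],
                          labels[split$train],
                          features[split$test, , drop = FALSE], k)
      acc[r] <- mean(pred == as.character(labels[split$test]))
    }
  })
  structure(list(accuracies = acc, mean_accuracy = mean(acc), k = k,
                 runs = runs, train_fraction = train_fraction, n = n,
                 n_train = sum(train_n), seed = seed),
            class = "sway_knn_report")
}

#' @export
print.sway_knn_report <- function(x, ...) {
  cat(sprintf("<sway_knn_report> mean accuracy %.1f%% over %d runs (k = %d, %d/%d train/test)\n",
              100 * x$mean_accuracy, x$runs, x$k, x$n_train, x$n - x$n_train))
  invisible(x)
}
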