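# End-to-end convenience wrappers tying the modules together.

#' Run the sway-variability analysis on a cohort
#'
#' Preprocesses every trial, fits and applies the amplitude normalization,
#' trains the first SOM on the flattened posture matrix, maps every
#' retained trial to its BMU trajectory and computes TTvar.
#'
#' @param cohort A `sway_cohort`.
#' @param rows,cols First-SOM lattice size.
#' @param iterations Training iterations (full passes).
#' @param subsample Optional cap on the number of posture vectors used for
#'   training (the full matrix is still mapped).
#' @param seed Seed for SOM initialization and training.
#' @param rate,n_cycles Preprocessing parameters.
#' @return A `sway_analysis`: list with `posture` (`sway_posture_array`),
#'   `normalized` (`sway_normalized_array`), `flat` (SOM input matrix +
#'   index), `som` (trained `sway_som`), `trajectories` (named list of
#'   `sway_trajectory`), `ttvar` (data frame with trial metadata and
#'   TTvar).
#' @export
run_sway_analysis <- function(cohort, rows = 25L, cols = 25L,
                              iterations = 1000L, subsample = NULL,
                              seed = 1L, rate = 30, n_cycles = 10L) {
  posture <- preprocess_cohort(cohort, rate = rate, n_cycles = n_cycles)
  normalized <- normalize_posture(posture)
  flat <- flatten_for_som(normalized)
  model <- som_init(rows, cols, dim = ncol(flat$matrix),
                    data_range = som_data_range(flat$matrix),
                    seed = derive_seed(seed, 11L))
  model <- som_train(model, flat$matrix, iterations = iterations,
                     subsample = subsample, seed = derive_seed(seed, 12L))
  trajectories <- map_trajectories(model, normalized)
  tt <- vapply(trajectories, function(tr) ttvar(tr)$ttvar, numeric(1))
  ttvar_df <- data.frame(trial_id = names(trajectories), ttvar = unname(tt),
                         stringsAsFactors = FALSE)
  if (!is.null(posture$info)) {
    ttvar_df <- merge(posture$info, ttvar_df, by = "trial_id", sort = FALSE)
  }
  structure(list(posture = posture, normalized = normalized, flat = flat,
                 som = model, trajectories = trajectories, ttvar = ttvar_df),
            class = "sway_analysis")
}

#' Map every trial of a normalized array to its BMU trajectory
#'
#' @param model A trained `sway_som`.
#' @param normalized A `sway_normalized_array` (or I x J x K array).
#' @return Named list of `sway_trajectory`.
#' @export
map_trajectories <- function(model, normalized) {
  values <- if (inherits(normalized, "sway_normalized_array")) normalized$values else normalized
  ids <- dimnames(values)[[1L]] %||% as.character(seq_len(dim(values)[1L]))
  J <- dim(values)[2L]
  out <- lapply(seq_len(dim(values)[1L]), function(i) {
    map_trial(model, values[i, , ], trial_id = ids[i], n_frames = J)
  })
  names(out) <- ids
  out
}

#' Classify young vs old from an analysis
#'
#' Builds the 600-dimensional trajectory vectors of the trials in the
#' selected conditions, trains the second SOM, and runs the repeated-split
#' kNN classifier on the trials' BMU coordinates on that map (`features =
#' "bmu"`) or directly on the 600-dimensional vectors (`features =
#' "vectors"`).
#'
#' @param analysis A `sway_analysis` from [run_sway_analysis()].
#' @param conditions Condition ids fed to the classifier.
#' @param rows,cols,iterations,subsample Second-SOM parameters.
#' @param features `"bmu"` (default) or `"vectors"`.
#' @param k,train_fraction,runs kNN parameters.
#' @param seed Seed for the second SOM and the splits.
#' @return List: `vectors` (from [build_trajectory_vectors()]), `second_som`
#'   (from [train_second_som()]), `report` (`sway_knn_report`).
#' @export
classify_cohort <- function(analysis, conditions = c(3L, 5L), rows = 25L,
                            cols = 25L, iterations = 200L, subsample = NULL,
                            features = c("bmu", "vectors"), k = 5L,
                            train_fraction = 0.7, runs = 100L, seed = 1L) {
  features <- match.arg(features)
  vec <- build_trajectory_vectors(analysis$trajectories, analysis$ttvar,
                                  conditions = conditions)
  second <- train_second_som(vec$S, rows = rows, cols = cols,
                             iterations = iterations, subsample = subsample,
                             seed = derive_seed(seed, 21L))
  feat <- if (features == "bmu") second$bmu else vec$S
  report <- knn_classify(feat, vec$labels, k = k,
                         train_fraction = train_fraction, runs = runs,
                         seed = derive_seed(seed, 22L))
  list(vectors = vec, second_som = second, report = report,
       features = features)
}
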