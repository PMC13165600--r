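#' Default end-to-end run configuration
#'
#' Returns the configuration list consumed by [run_pipeline()]. Every
#' stochastic stage carries an explicit seed (simulation, split, grid, cv,
#' model, permutation); a config missing any of them is rejected before any
#' computation starts.
#'
#' @param seed Base seed used to derive the stage seeds (stage offsets are
#'   fixed and documented in the returned list).
#' @param algorithms Algorithms to train (subset of rf/svm_rbf/knn).
#' @param placements Sensor placements to analyse independently.
#' @param n_participants Number of simulated participants.
#' @param importance_repeats Shuffles per feature for the RF permutation
#'   importance (0 disables the importance stage).
#' @param ... Overrides for [sim_config()] fields (e.g. `trials`,
#'   `segment_seconds`).
#' @return A named list (`run_config`).
#' @export
default_run_config <- function(seed = 100,
                               algorithms = c("rf", "svm_rbf", "knn"),
                               placements = c("ankle", "lower_back", "hip"),
                               n_participants = 48,
                               importance_repeats = 10,
                               ...) {
  list(
    n_participants = n_participants,
    algorithms = algorithms,
    placements = placements,
    window_seconds = 1,
    stride_seconds = 1,
    test_fraction = 0.2,
    nzv_freq_ratio = 19,
    nzv_unique_pct = 10,
    n_grid_points = 10,
    cv_folds = 5,
    trees = 500,
    importance_repeats = importance_repeats,
    sim_overrides = list(...),
    seeds = list(simulation = seed, split = seed + 1, grid = seed + 2,
                 cv = seed + 3, model = seed + 4, permutation = seed + 5)
  )
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys as in [default_run_config()].
#' @return The validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_run_config()
  for (nm in setdiff(names(base), c("seeds"))) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- base[[nm]]
  }
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(config) {
  need_seeds <- c("simulation", "split", "grid", "cv", "model", "permutation")
  seeds <- config$seeds
  missing <- need_seeds[vapply(need_seeds, function(s)
    is.null(seeds[[s]]) || is.na(seeds[[s]]), logical(1))]
  if (length(missing)) {
    stop("run config missing seed(s): ", paste(missing, collapse = ", "))
  }
  if (!all(config$algorithms %in% c("rf", "svm_rbf", "knn"))) {
    stop("unknown algorithm in config")
  }
  for (p in config$placements) check_placement(p)
  invisible(config)
}

#' Run the full pipeline: simulate, extract, split, tune, fit, evaluate
#'
#' For each placement, simulates the synthetic dataset, windows and extracts
#' features, performs the participant-level split, then — for each
#' algorithm — tunes under grouped cross-validation, fits the final model
#' and evaluates it on the held-out participants. For the random forest,
#' permutation feature importance on the test rows is added. All reports and
#' a config snapshot are written as plain JSON/CSV files under `out_dir`;
#' reruns with the same config are byte-identical.
#'
#' @param config A configuration list (see [default_run_config()]).
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return Nested list: `results[[placement]][[algorithm]]` with elements
#'   `report` ([evaluate_classifier()]), `model` and optionally
#'   `importance`; plus the `split` per placement.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  validate_run_config(config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(config, file.path(out_dir, "run_config.yaml"))
  }
  results <- list()
  for (placement in config$placements) {
    sim_args <- c(list(n_participants = config$n_participants,
                       placement = placement,
                       seed = config$seeds$simulation),
                  config$sim_overrides)
    scfg <- do.call(sim_config, sim_args)
    dataset <- simulate_dataset(scfg)
    windows <- unlist(lapply(dataset$recordings, function(rec) {
      window_segments(rec, dataset$segments,
                      window_seconds = config$window_seconds,
                      stride_seconds = config$stride_seconds)
    }), recursive = FALSE)
    features <- extract_features(windows)
    split <- split_participants(features$participant_id, features$label,
                                test_fraction = config$test_fraction,
                                seed = config$seeds$split)
    train <- features[features$participant_id %in% split$train, ,
                      drop = FALSE]
    test <- features[features$participant_id %in% split$test, , drop = FALSE]
    placement_res <- list(split = split)
    for (algorithm in config$algorithms) {
      spec <- classifier_spec(algorithm,
                              n_grid_points = config$n_grid_points,
                              cv_folds = config$cv_folds,
                              trees = config$trees,
                              grid_seed = config$seeds$grid,
                              cv_seed = config$seeds$cv,
                              model_seed = config$seeds$model)
      model <- train_classifier(train, spec,
                                nzv_freq_ratio = config$nzv_freq_ratio,
                                nzv_unique_pct = config$nzv_unique_pct)
      report <- evaluate_classifier(model, test)
      entry <- list(model = model, report = report)
      if (algorithm == "rf" && config$importance_repeats > 0) {
        entry$importance <- permutation_importance(
          model, test, n_repeats = config$importance_repeats,
          seed = config$seeds$permutation)
      }
      if (!is.null(out_dir)) {
        write_report(report, file.path(out_dir, sprintf(
          "report_%s_%s.json", placement, algorithm)))
        if (!is.null(entry$importance)) {
          utils::write.csv(as.data.frame(entry$importance),
                           file.path(out_dir, sprintf(
                             "importance_%s_%s.csv", placement, algorithm)),
                           row.names = FALSE)
        }
      }
      placement_res[[algorithm]] <- entry
    }
    results[[placement]] <- placement_res
  }
  invisible(results)
}

#' Bundled reference confusion matrices
#'
#' Loads the published 3x3 test-set confusion matrices for the three
#' classifiers (Random Forest, SVM, KNN) that ship with the package as a
#' plain-text fixture. They serve as worked examples for the metric
#' functions: re-running [percent_agreement()], [cohens_kappa()] and
#' [column_percentages()] on these counts reproduces the reference
#' accuracies.
#'
#' @return Named list of `confusion_matrix` objects (`rf`, `svm_rbf`,
#'   `knn`).
#' @export
reference_confusion_matrices <- function() {
  path <- system.file("extdata", "reference_confusion_counts.csv",
                      package = "accelhar", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$algorithm), function(d) {
    d <- d[match(activity_levels(), d$predicted), ]
    as_confusion_matrix(as.matrix(d[, activity_levels()]))
  })
  out[c("rf", "svm_rbf", "knn")]
}
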