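#' Specification of a classifier and its tuning protocol
#'
#' Supported algorithms: Random Forest (`"rf"`, 500 trees fixed; tunes
#' `mtry` and `min_n`), RBF-kernel Support Vector Machine (`"svm_rbf"`;
#' tunes `cost` and `rbf_sigma`) and K-Nearest Neighbors (`"knn"`; tunes
#' `n_neighbors`). Hyperparameters are searched over a seeded Latin-hypercube
#' grid of `n_grid_points` settings under `cv_folds`-fold participant-grouped
#' cross-validation.
#'
#' @param algorithm `"rf"`, `"svm_rbf"` or `"knn"`.
#' @param n_grid_points Number of hyperparameter settings (default 10).
#' @param cv_folds Number of cross-validation folds (default 5).
#' @param trees Number of trees for the random forest (fixed, default 500).
#' @param seed Base seed; `grid_seed`, `cv_seed` and `model_seed` default to
#'   `seed`, `seed + 1` and `seed + 2` and may be set individually.
#' @param grid_seed,cv_seed,model_seed Stage seeds (grid draw, fold
#'   assignment, model fitting).
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(algorithm = c("rf", "svm_rbf", "knn"),
                            n_grid_points = 10, cv_folds = 5, trees = 500,
                            seed = 1, grid_seed = seed, cv_seed = seed + 1,
                            model_seed = seed + 2) {
  algorithm <- match.arg(algorithm)
  stopifnot(n_grid_points >= 1, cv_folds >= 2, trees >= 1)
  structure(list(algorithm = algorithm,
                 n_grid_points = as.integer(n_grid_points),
                 cv_folds = as.integer(cv_folds),
                 trees = as.integer(trees),
                 grid_seed = as.integer(grid_seed),
                 cv_seed = as.integer(cv_seed),
                 model_seed = as.integer(model_seed)),
            class = "classifier_spec")
}

#' Draw the hyperparameter grid
#'
#' A seeded Latin-hypercube draw of `n_grid_points` settings over the
#' documented ranges: `mtry` in `[1, feature_count]`, `min_n` in `[2, 40]`,
#' `cost` in `2^[-5, 10]`, `rbf_sigma` in `10^[-4, 0]`, `n_neighbors` in
#' `[1, 2 * round(sqrt(train_size))]`.
#'
#' @param spec A [classifier_spec()].
#' @param feature_count Number of (kept) predictors.
#' @param train_size Number of training rows (used for the KNN range).
#' @return A data.frame of hyperparameter settings with a `complexity`
#'   column used only for tie-breaking during model selection.
#' @export
make_grid <- function(spec, feature_count, train_size) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (feature_count < 1L) stop("feature_count must be >= 1")
  n <- spec$n_grid_points
  d <- switch(spec$algorithm, rf = 2L, svm_rbf = 2L, knn = 1L)
  u <- withr::with_seed(spec$grid_seed, lhs::randomLHS(n, d))
  grid <- switch(
    spec$algorithm,
    rf = {
      mtry <- pmin(pmax(round(1 + u[, 1L] * (feature_count - 1)), 1L),
                   feature_count)
      min_n <- round(2 + u[, 2L] * 38)
      data.frame(mtry = mtry, min_n = min_n,
                 complexity = mtry + (40 - min_n) / 40)
    },
    svm_rbf = {
      cost <- 2^(-5 + u[, 1L] * 15)
      rbf_sigma <- 10^(-4 + u[, 2L] * 4)
      data.frame(cost = cost, rbf_sigma = rbf_sigma, complexity = log2(cost))
    },
    knn = {
      kmax <- max(1L, 2L * round(sqrt(train_size)))
      k <- pmin(pmax(round(1 + u[, 1L] * (kmax - 1)), 1L), kmax)
      data.frame(n_neighbors = k, complexity = -k)
    })
  grid$setting <- seq_len(n)
  grid
}

## Fit one algorithm on standardized features. `df` must already be
## preprocessed (apply_preprocess); features are taken in canonical order.
fit_algorithm <- function(spec, df, setting) {
  x <- as.matrix(df[, feature_columns(df), drop = FALSE])
  y <- activity_factor(df$label)
  switch(
    spec$algorithm,
    rf = ranger::ranger(x = x, y = y, num.trees = spec$trees,
                        mtry = min(setting$mtry, ncol(x)),
                        min.node.size = setting$min_n,
                        probability = TRUE, seed = spec$model_seed,
                        num.threads = 1),
    svm_rbf = withr::with_seed(
      spec$model_seed,
      e1071::svm(x = x, y = y, kernel = "radial",
                 cost = setting$cost, gamma = setting$rbf_sigma,
                 scale = FALSE, probability = FALSE)),
    knn = caret::knn3(x = x, y = y, k = setting$n_neighbors))
}

## Class probabilities in ACTIVITY_LEVELS column order, rows summing to 1.
## SVM probabilities are pairwise-coupled from the one-vs-one decision
## values: each pairwise decision is passed through a logistic link and the
## per-class votes are normalized — an approximation that avoids refitting a
## probability model but preserves the decision ranking.
predict_probabilities <- function(spec, model, df) {
  x <- as.matrix(df[, feature_columns(df), drop = FALSE])
  # seeded: knn prediction breaks exact-distance ties via the RNG
  p <- withr::with_seed(spec$model_seed, switch(
    spec$algorithm,
    rf = stats::predict(model, data = x, num.threads = 1)$predictions,
    knn = stats::predict(model, x, type = "prob"),
    svm_rbf = {
      pred <- stats::predict(model, x, decision.values = TRUE)
      d <- attr(pred, "decision.values")
      score <- matrix(0, nrow(x), length(ACTIVITY_LEVELS),
                      dimnames = list(NULL, ACTIVITY_LEVELS))
      for (j in seq_len(ncol(d))) {
        pair <- strsplit(colnames(d)[j], "/", fixed = TRUE)[[1L]]
        r <- 1 / (1 + exp(-d[, j]))
        score[, pair[1L]] <- score[, pair[1L]] + r
        score[, pair[2L]] <- score[, pair[2L]] + (1 - r)
      }
      score / rowSums(score)
    }))
  colnames(p) <- colnames(p) %||% ACTIVITY_LEVELS
  p <- p[, ACTIVITY_LEVELS, drop = FALSE]
  p / rowSums(p)
}

## Hard labels: argmax probability, ties to the earlier class in the fixed
## walking < running < jumping order.
hard_labels <- function(prob) {
  factor(ACTIVITY_LEVELS[max.col(prob, ties.method = "first")],
         levels = ACTIVITY_LEVELS)
}

## Participant-grouped fold assignment: a partition of the training
## participants into cv_folds groups of near-equal size.
make_folds <- function(participants, cv_folds, seed) {
  ids <- sort(unique(participants))
  if (length(ids) < cv_folds) {
    stop("fewer training participants (", length(ids), ") than folds (",
         cv_folds, ")")
  }
  withr::with_seed(seed, {
    shuffled <- sample(ids)
    split(shuffled, rep_len(seq_len(cv_folds), length(shuffled)))
  })
}

#' Grid-search cross-validation grouped by participant
#'
#' Folds partition the training *participants* (never windows), so no
#' participant appears in both the analysis and assessment portion of a
#' fold. Preprocessing (variance filter + standardization) is re-fitted
#' inside each fold on its analysis portion. For every grid setting and fold
#' the percent agreement, macro one-vs-all ROC-AUC and Cohen's Kappa of the
#' assessment predictions are recorded; results are summarized as mean and
#' standard error (sd / sqrt(folds)) over folds.
#'
#' @param matrix Training feature matrix (raw, unpreprocessed).
#' @param spec A [classifier_spec()].
#' @param grid Optional grid from [make_grid()]; drawn automatically
#'   otherwise.
#' @param nzv_freq_ratio,nzv_unique_pct Variance-filter thresholds passed to
#'   [fit_preprocess()].
#' @return A list of class `cv_results` with `folds` (per-fold per-setting
#'   metrics), `summary` (per-setting mean and SE) and the grid.
#' @export
cross_validate <- function(matrix, spec, grid = NULL,
                           nzv_freq_ratio = 19, nzv_unique_pct = 10) {
  stopifnot(inherits(spec, "classifier_spec"))
  feats <- feature_columns(matrix)
  if (is.null(grid)) {
    grid <- make_grid(spec, length(feats), nrow(matrix))
  }
  folds <- make_folds(matrix$participant_id, spec$cv_folds, spec$cv_seed)
  records <- list()
  for (f in seq_along(folds)) {
    held <- folds[[f]]
    analysis <- matrix[!matrix$participant_id %in% held, , drop = FALSE]
    assessment <- matrix[matrix$participant_id %in% held, , drop = FALSE]
    prep <- fit_preprocess(analysis, nzv_freq_ratio, nzv_unique_pct)
    a <- apply_preprocess(prep, analysis)
    b <- apply_preprocess(prep, assessment)
    obs <- activity_factor(b$label)
    for (s in seq_len(nrow(grid))) {
      model <- fit_algorithm(spec, a, grid[s, , drop = FALSE])
      prob <- predict_probabilities(spec, model, b)
      pred <- hard_labels(prob)
      cm <- confusion_matrix(obs, pred)
      records[[length(records) + 1L]] <- data.frame(
        setting = grid$setting[s], fold = f,
        percent_agreement = percent_agreement(cm),
        roc_auc = suppressWarnings(roc_auc_ova(obs, prob)$macro),
        kappa = cohens_kappa(cm))
    }
  }
  per_fold <- do.call(rbind, records)
  agg <- function(metric) {
    m <- tapply(per_fold[[metric]], per_fold$setting, mean)
    se <- tapply(per_fold[[metric]], per_fold$setting,
                 function(v) stats::sd(v) / sqrt(length(v)))
    data.frame(setting = as.integer(names(m)), mean = as.numeric(m),
               se = as.numeric(se))
  }
  summary <- data.frame(setting = grid$setting)
  for (metric in c("percent_agreement", "roc_auc", "kappa")) {
    s <- agg(metric)
    summary[[paste0(metric, "_mean")]] <- s$mean[match(summary$setting,
                                                       s$setting)]
    summary[[paste0(metric, "_se")]] <- s$se[match(summary$setting,
                                                   s$setting)]
  }
  structure(list(folds = per_fold, summary = summary, grid = grid,
                 fold_participants = folds),
            class = "cv_results")
}

#' Pick the winning grid setting
#'
#' The chosen setting maximizes the mean cross-validated percent agreement;
#' ties break to higher mean macro ROC-AUC, then higher mean Kappa, then to
#' the less complex model (lower `complexity` in the grid). Agreement leads
#' because the rank-based ROC-AUC saturates on well-separated classes and
#' cannot distinguish a well-calibrated model from an underfit one whose
#' scores still rank correctly.
#'
#' @param cv A [cross_validate()] result.
#' @return The winning grid row (with its hyperparameters).
#' @export
select_best <- function(cv) {
  stopifnot(inherits(cv, "cv_results"))
  s <- merge(cv$summary, cv$grid, by = "setting")
  s <- s[order(-s$percent_agreement_mean, -s$roc_auc_mean, -s$kappa_mean,
               s$complexity, s$setting), , drop = FALSE]
  s[1L, , drop = FALSE]
}

#' Fit the final model on the full training set
#'
#' Re-fits preprocessing on the complete training matrix and trains the
#' algorithm with the chosen hyperparameters.
#'
#' @param matrix Training feature matrix (raw).
#' @param spec A [classifier_spec()].
#' @param chosen A single grid row (e.g. from [select_best()]).
#' @param cv_results Optional [cross_validate()] result stored alongside.
#' @inheritParams cross_validate
#' @return An object of class `trained_classifier`.
#' @export
fit_final <- function(matrix, spec, chosen, cv_results = NULL,
                      nzv_freq_ratio = 19, nzv_unique_pct = 10) {
  prep <- fit_preprocess(matrix, nzv_freq_ratio, nzv_unique_pct)
  train <- apply_preprocess(prep, matrix)
  model <- fit_algorithm(spec, train, chosen)
  structure(list(spec = spec,
                 chosen = chosen[, setdiff(names(chosen),
                                           c("complexity", "setting",
                                             grep("_mean$|_se$", names(chosen),
                                                  value = TRUE))),
                                 drop = FALSE],
                 preprocess = prep,
                 model = model,
                 cv_results = cv_results,
                 classes = ACTIVITY_LEVELS,
                 train_participants = sort(unique(matrix$participant_id))),
            class = "trained_classifier")
}

#' Tune and train one classifier end to end
#'
#' Runs [make_grid()], [cross_validate()], [select_best()] and [fit_final()]
#' in sequence. Fully deterministic given the spec's seeds.
#'
#' @inheritParams cross_validate
#' @return A `trained_classifier`.
#' @export
train_classifier <- function(matrix, spec,
                             nzv_freq_ratio = 19, nzv_unique_pct = 10) {
  cv <- cross_validate(matrix, spec, grid = NULL,
                       nzv_freq_ratio = nzv_freq_ratio,
                       nzv_unique_pct = nzv_unique_pct)
  best <- select_best(cv)
  fit_final(matrix, spec, best, cv_results = cv,
            nzv_freq_ratio = nzv_freq_ratio, nzv_unique_pct = nzv_unique_pct)
}

#' Predict activities for new windows
#'
#' Applies the stored preprocessing and returns per-class probabilities
#' (summing to 1 over walking/running/jumping) and hard labels (argmax, ties
#' to the earlier class in the fixed order).
#'
#' @param object A `trained_classifier`.
#' @param newdata Feature matrix data.frame (raw, unpreprocessed).
#' @param ... Unused.
#' @return A list with `prob` (n x 3 matrix) and `class` (factor).
#' @export
predict.trained_classifier <- function(object, newdata, ...) {
  df <- apply_preprocess(object$preprocess, newdata)
  prob <- predict_probabilities(object$spec, object$model, df)
  list(prob = prob, class = hard_labels(prob))
}

#' @export
print.trained_classifier <- function(x, ...) {
  hp <- paste(names(x$chosen), signif(unlist(x$chosen), 4),
              sep = " = ", collapse = ", ")
  cat(sprintf("<trained_classifier> %s (%s)\n  %d features, %d training participants\n",
              x$spec$algorithm, hp, length(x$preprocess$kept),
              length(x$train_participants)))
  invisible(x)
}

#' Save / load a trained classifier
#'
#' The model artifact is a directory holding JSON metadata (algorithm,
#' chosen hyperparameters, preprocessing state, CV summary) plus the fitted
#' model state; a reloaded model gives identical predictions.
#'
#' @param model A `trained_classifier`.
#' @param dir Artifact directory (created if needed).
#' @return `save_classifier()` returns `dir` invisibly; `load_classifier()`
#'   returns the `trained_classifier`.
#' @export
save_classifier <- function(model, dir) {
  stopifnot(inherits(model, "trained_classifier"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(algorithm = model$spec$algorithm,
               spec = unclass(model$spec),
               chosen = as.list(model$chosen),
               preprocess = list(kept = model$preprocess$kept,
                                 dropped = as.list(model$preprocess$dropped),
                                 center = as.list(model$preprocess$center),
                                 scale = as.list(model$preprocess$scale)),
               classes = model$classes,
               train_participants = model$train_participants,
               cv_summary = if (!is.null(model$cv_results))
                 model$cv_results$summary)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  saveRDS(model, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(dir) {
  path <- file.path(dir, "model.rds")
  if (!file.exists(path)) stop("no model artifact at ", dir)
  model <- readRDS(path)
  stopifnot(inherits(model, "trained_classifier"))
  model
}
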