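#' Participant-level stratified train/test split
#'
#' Splits participants (never windows) into training and testing sets so no
#' participant contributes data to both sides. Participants are ranked by
#' their activity-window composition (fraction of jumping windows), grouped
#' into quartile strata, and the test set is sampled within strata so
#' train/test class proportions stay close. When all participants share the
#' same composition — as under the fixed trial protocol — this degenerates to
#' a simple random participant split.
#'
#' @param participant_id Character vector, one entry per window.
#' @param label Activity label per window (parallel to `participant_id`).
#' @param test_fraction Fraction of participants assigned to the test set
#'   (default 0.20); the test count is the nearest integer.
#' @param seed Integer seed; the split is reproducible given the seed.
#' @return An object of class `split_spec`: list with character vectors
#'   `train` and `test` (disjoint, union = all participants), plus the seed
#'   and fraction used.
#' @export
split_participants <- function(participant_id, label, test_fraction = 0.2,
                               seed) {
  if (missing(seed) || is.null(seed)) stop("seed is required")
  if (length(participant_id) != length(label)) {
    stop("participant_id and label must have equal length")
  }
  label <- activity_factor(label)
  ids <- sort(unique(as.character(participant_id)))
  n <- length(ids)
  if (n < 5L) stop("need at least 5 participants to stratify")
  n_test <- round(test_fraction * n)
  if (n_test < 1L || n_test >= n) {
    stop("test_fraction yields an empty train or test set")
  }
  jump_frac <- vapply(ids, function(id) {
    mean(label[participant_id == id] == "jumping")
  }, numeric(1))
  ord <- ids[order(jump_frac, ids)]
  n_strata <- 4L
  stratum <- ceiling(seq_len(n) * n_strata / n)
  test_ids <- withr::with_seed(seed, {
    sizes <- tabulate(stratum, n_strata)
    quota <- n_test * sizes / n
    base <- floor(quota)
    rem <- n_test - sum(base)
    if (rem > 0L) {
      extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1L
    }
    unlist(lapply(seq_len(n_strata), function(s) {
      pool <- ord[stratum == s]
      if (base[s] == 0L) return(character())
      pool[sample.int(length(pool), base[s])]
    }))
  })
  structure(list(train = setdiff(ids, test_ids),
                 test = sort(test_ids),
                 test_fraction = test_fraction,
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec> %d train / %d test participants (seed %d)\n",
              length(x$train), length(x$test), x$seed))
  invisible(x)
}

#' Fit feature preprocessing on training rows
#'
#' Implements the standard two-step predictor preprocessing: removal of
#' (near-)zero-variance features, then standardization. A feature is dropped
#' if it has zero variance, or if the ratio of its most common value's
#' frequency to the second most common exceeds `nzv_freq_ratio` *and* the
#' percentage of unique values is below `nzv_unique_pct` (the conventional
#' 95/5 frequency-ratio + 10% unique rule; both are knobs). Centering and
#' scaling statistics are estimated on the training rows only.
#'
#' @param train_matrix Feature matrix data.frame (training rows only).
#' @param nzv_freq_ratio Frequency-ratio threshold (default 19, i.e. 95/5).
#' @param nzv_unique_pct Percent-unique threshold (default 10).
#' @return An object of class `preprocess_state` with `kept` (ordered feature
#'   names), `dropped` (named character vector of reasons), `center` and
#'   `scale` (named numeric vectors over kept features).
#' @export
fit_preprocess <- function(train_matrix, nzv_freq_ratio = 19,
                           nzv_unique_pct = 10) {
  feats <- feature_columns(train_matrix)
  if (nrow(train_matrix) == 0L || length(feats) == 0L) {
    stop("empty training matrix")
  }
  n <- nrow(train_matrix)
  dropped <- character()
  for (f in feats) {
    x <- train_matrix[[f]]
    if (stats::sd(x) == 0) {
      dropped[f] <- "zero variance"
      next
    }
    tab <- sort(table(x), decreasing = TRUE)
    freq_ratio <- if (length(tab) > 1L) tab[[1L]] / tab[[2L]] else Inf
    unique_pct <- 100 * length(tab) / n
    if (freq_ratio > nzv_freq_ratio && unique_pct < nzv_unique_pct) {
      dropped[f] <- "near-zero variance"
    }
  }
  kept <- setdiff(feats, names(dropped))
  if (length(kept) == 0L) stop("all features dropped by the variance filter")
  center <- vapply(kept, function(f) mean(train_matrix[[f]]), numeric(1))
  scale <- vapply(kept, function(f) stats::sd(train_matrix[[f]]), numeric(1))
  structure(list(kept = kept, dropped = dropped,
                 center = center, scale = scale),
            class = "preprocess_state")
}

#' @export
print.preprocess_state <- function(x, ...) {
  cat(sprintf("<preprocess_state> %d features kept, %d dropped\n",
              length(x$kept), length(x$dropped)))
  if (length(x$dropped)) {
    cat(paste0("  - ", names(x$dropped), ": ", x$dropped, collapse = "\n"),
        "\n")
  }
  invisible(x)
}

#' Apply fitted preprocessing to a feature matrix
#'
#' Uses the training-set center/scale without re-estimation and drops the
#' same columns, so test rows are transformed exactly as the model expects.
#'
#' @param state A [fit_preprocess()] result.
#' @param matrix Feature matrix data.frame.
#' @return The matrix with metadata columns untouched and kept features
#'   standardized by the training statistics.
#' @export
apply_preprocess <- function(state, matrix) {
  stopifnot(inherits(state, "preprocess_state"))
  missing <- setdiff(state$kept, names(matrix))
  if (length(missing)) {
    stop("matrix missing preprocessed feature(s): ",
         paste(missing, collapse = ", "))
  }
  meta <- intersect(META_COLUMNS, names(matrix))
  out <- matrix[, c(meta, state$kept), drop = FALSE]
  for (f in state$kept) {
    out[[f]] <- (out[[f]] - state$center[[f]]) / state$scale[[f]]
  }
  out
}
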