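#' Confusion matrix with fixed class order
#'
#' Rows are predicted labels, columns observed labels, both in the fixed
#' walking, running, jumping order (or any supplied level set). Column sums
#' equal the observed class counts and the grand total is the number of
#' evaluated windows.
#'
#' @param observed,predicted Label vectors (character or factor).
#' @param levels Class levels in display order; defaults to
#'   [activity_levels()].
#' @return An integer matrix of class `confusion_matrix`
#'   (predicted x observed).
#' @export
confusion_matrix <- function(observed, predicted,
                             levels = activity_levels()) {
  o <- factor(as.character(observed), levels = levels)
  p <- factor(as.character(predicted), levels = levels)
  if (anyNA(o) || anyNA(p)) stop("labels outside the class level set")
  m <- table(predicted = p, observed = o)
  structure(unclass(m), class = "confusion_matrix")
}

#' Build a confusion matrix from pre-tabulated counts
#'
#' For re-entering published confusion tables: `counts` is a square matrix
#' with rows = predicted, columns = observed, in `levels` order.
#'
#' @param counts Square numeric matrix of non-negative counts.
#' @inheritParams confusion_matrix
#' @return A `confusion_matrix`.
#' @export
as_confusion_matrix <- function(counts, levels = activity_levels()) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("counts must be square")
  if (nrow(counts) != length(levels)) {
    stop("counts dimension must match the number of levels")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  dimnames(counts) <- list(predicted = levels, observed = levels)
  structure(counts, class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = predicted, columns = observed)\n")
  print(unclass(x))
  invisible(x)
}

#' Column percentages of a confusion matrix
#'
#' Each column is expressed as a percentage of its observed class total,
#' matching the per-column percentage convention of published confusion
#' tables.
#'
#' @param cm A `confusion_matrix`.
#' @return Numeric matrix of percentages (columns sum to 100 where the
#'   observed count is non-zero).
#' @export
column_percentages <- function(cm) {
  m <- unclass(cm)
  totals <- colSums(m)
  totals[totals == 0] <- NA_real_
  sweep(m, 2L, totals, "/") * 100
}

#' Overall percent agreement
#'
#' `100 * trace / grand total` of the confusion matrix.
#'
#' @param cm A `confusion_matrix` (or square count matrix).
#' @return Percentage in `[0, 100]`.
#' @export
percent_agreement <- function(cm) {
  m <- unclass(as.matrix(cm))
  100 * sum(diag(m)) / sum(m)
}

#' Cohen's Kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o = trace / N` and expected agreement
#' `p_e = sum_c(row_c * col_c) / N^2` from the matrix marginals. If
#' `p_e = 1` (degenerate marginals) kappa is undefined and 0 is returned
#' with a warning.
#'
#' @param cm A `confusion_matrix` (or square count matrix).
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(cm) {
  m <- unclass(as.matrix(cm))
  n <- sum(m)
  if (n == 0) stop("empty confusion matrix")
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (pe >= 1) {
    warning("expected agreement is 1; kappa undefined, returning 0")
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' One-vs-all ROC-AUC per class and macro average
#'
#' For each class, the binary AUC of that class's probability (score)
#' against class membership, computed with the midrank (tie-aware)
#' formulation — equivalent to the probability that a random positive
#' outranks a random negative, with ties counting one half. The overall
#' value is the unweighted mean over classes. A class absent from the
#' observed labels has undefined AUC and is excluded from the macro mean
#' with a warning.
#'
#' @param observed Label vector.
#' @param probabilities Numeric matrix, one column per class (named, or in
#'   level order).
#' @param levels Class levels; defaults to [activity_levels()].
#' @return A list with `per_class` (named numeric, `NA` where undefined)
#'   and `macro`.
#' @export
roc_auc_ova <- function(observed, probabilities,
                        levels = activity_levels()) {
  o <- factor(as.character(observed), levels = levels)
  if (anyNA(o)) stop("labels outside the class level set")
  p <- as.matrix(probabilities)
  if (is.null(colnames(p))) colnames(p) <- levels
  aucs <- vapply(levels, function(cl) {
    pos <- o == cl
    n1 <- sum(pos)
    n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L) return(NA_real_)
    r <- rank(p[, cl])
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  if (anyNA(aucs)) {
    warning("class(es) absent from observed labels excluded from macro AUC: ",
            paste(levels[is.na(aucs)], collapse = ", "))
  }
  list(per_class = aucs, macro = mean(aucs, na.rm = TRUE))
}

#' One-vs-all metrics per activity
#'
#' For each class the 3-class problem is collapsed to a binary one (that
#' class vs the rest): the 2x2 table is formed from the confusion-matrix
#' counts and percent agreement and Cohen's Kappa are recomputed on it; the
#' AUC comes from [roc_auc_ova()] when probabilities are supplied.
#'
#' @param cm A `confusion_matrix`.
#' @param observed,probabilities Optional: the observed labels and score
#'   matrix, needed only for the AUC column.
#' @return A data.frame with one row per class: `percent_agreement`,
#'   `kappa` and (optionally) `roc_auc`.
#' @export
per_class_metrics <- function(cm, observed = NULL, probabilities = NULL) {
  m <- unclass(as.matrix(cm))
  levels <- colnames(m)
  aucs <- if (!is.null(observed) && !is.null(probabilities)) {
    roc_auc_ova(observed, probabilities, levels = levels)$per_class
  } else {
    rep(NA_real_, length(levels))
  }
  rows <- lapply(seq_along(levels), function(i) {
    a <- m[i, i]
    b <- sum(m[i, -i])
    c_ <- sum(m[-i, i])
    d <- sum(m[-i, -i])
    two <- matrix(c(a, c_, b, d), 2L, 2L)
    data.frame(activity = levels[i],
               percent_agreement = percent_agreement(two),
               roc_auc = aucs[i],
               kappa = cohens_kappa(two))
  })
  do.call(rbind, rows)
}

#' Collapse a confusion matrix to one-vs-rest 2x2 counts
#'
#' @param cm A `confusion_matrix`.
#' @param class The positive class.
#' @return A 2x2 matrix `(TP, FN; FP, TN)` with predicted rows and observed
#'   columns in (class, rest) order.
#' @export
binary_collapse <- function(cm, class) {
  m <- unclass(as.matrix(cm))
  i <- match(class, colnames(m))
  if (is.na(i)) stop("unknown class: ", class)
  out <- matrix(c(m[i, i], sum(m[-i, i]), sum(m[i, -i]), sum(m[-i, -i])),
                2L, 2L,
                dimnames = list(predicted = c(class, "rest"),
                                observed = c(class, "rest")))
  out
}

#' Evaluate a trained classifier on a test feature matrix
#'
#' Computes the full report: overall percent agreement, macro one-vs-all
#' ROC-AUC and Cohen's Kappa; the same three metrics per activity
#' (one-vs-all); and the 3x3 confusion matrix.
#'
#' @param model A `trained_classifier`.
#' @param test_matrix Feature matrix data.frame (raw, unpreprocessed).
#' @return A list of class `evaluation_report`.
#' @export
evaluate_classifier <- function(model, test_matrix) {
  pred <- stats::predict(model, test_matrix)
  obs <- activity_factor(test_matrix$label)
  cm <- confusion_matrix(obs, pred$class)
  auc <- roc_auc_ova(obs, pred$prob)
  structure(list(
    algorithm = model$spec$algorithm,
    n_test = nrow(test_matrix),
    overall = list(percent_agreement = percent_agreement(cm),
                   roc_auc = auc$macro,
                   kappa = cohens_kappa(cm)),
    per_class = per_class_metrics(cm, obs, pred$prob),
    confusion = cm,
    confusion_column_pct = column_percentages(cm)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s on %d test windows\n", x$algorithm,
              x$n_test))
  cat(sprintf("  overall: agreement %.1f%%, ROC-AUC %.3f, kappa %.3f\n",
              x$overall$percent_agreement, x$overall$roc_auc,
              x$overall$kappa))
  for (i in seq_len(nrow(x$per_class))) {
    r <- x$per_class[i, ]
    cat(sprintf("  %-8s agreement %.1f%%, ROC-AUC %.3f, kappa %.3f\n",
                paste0(r$activity, ":"), r$percent_agreement, r$roc_auc,
                r$kappa))
  }
  print(x$confusion)
  invisible(x)
}

#' Permutation feature importance
#'
#' For each kept feature, its values in the evaluation matrix are shuffled
#' `n_repeats` times (independent within-column permutations, seeded) and
#' the importance is the baseline metric minus the mean permuted metric —
#' the drop in performance when the feature's information is destroyed.
#' Computed on held-out rows with the final model.
#'
#' @param model A `trained_classifier`.
#' @param test_matrix Feature matrix data.frame (raw, unpreprocessed).
#' @param metric Currently `"percent_agreement"`.
#' @param n_repeats Number of shuffles per feature (default 10, >= 1).
#' @param seed Integer seed.
#' @return A data.frame of class `importance_report`, sorted by decreasing
#'   importance, with columns `feature`, `importance`, `sd` (over repeats).
#' @export
permutation_importance <- function(model, test_matrix,
                                   metric = "percent_agreement",
                                   n_repeats = 10, seed = 1) {
  stopifnot(inherits(model, "trained_classifier"))
  metric <- match.arg(metric, "percent_agreement")
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  obs <- activity_factor(test_matrix$label)
  score <- function(df) {
    100 * mean(stats::predict(model, df)$class == obs)
  }
  baseline <- score(test_matrix)
  feats <- model$preprocess$kept
  n <- nrow(test_matrix)
  res <- withr::with_seed(seed, {
    lapply(feats, function(f) {
      drops <- vapply(seq_len(n_repeats), function(rep) {
        shuffled <- test_matrix
        shuffled[[f]] <- shuffled[[f]][sample.int(n)]
        baseline - score(shuffled)
      }, numeric(1))
      data.frame(feature = f, importance = mean(drops),
                 sd = stats::sd(drops))
    })
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$importance, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "baseline") <- baseline
  attr(out, "n_repeats") <- n_repeats
  class(out) <- c("importance_report", "data.frame")
  out
}
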