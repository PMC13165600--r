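#' Read and write feature matrices as CSV
#'
#' Feature matrices round-trip losslessly through CSV with a fixed,
#' documented column order: `participant_id`, `placement`, `label`,
#' `window_index`, then the 54 features of [feature_names()]. Values are
#' written with full double precision.
#'
#' @param matrix A feature matrix data.frame (see [extract_features()]).
#' @param path File path.
#' @return `write_feature_matrix()` returns `path` invisibly;
#'   `read_feature_matrix()` returns the validated data.frame.
#' @export
write_feature_matrix <- function(matrix, path) {
  cols <- c(META_COLUMNS, feature_names())
  missing <- setdiff(cols, names(matrix))
  if (length(missing)) {
    stop("feature matrix missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- matrix[, cols, drop = FALSE]
  for (f in feature_names()) {
    df[[f]] <- sprintf("%.17g", df[[f]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(window_index = "integer"))
  cols <- c(META_COLUMNS, feature_names())
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("feature matrix schema error; missing column(s): ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(df), cols)
  if (length(extra)) {
    stop("feature matrix schema error; unexpected column(s): ",
         paste(extra, collapse = ", "))
  }
  df <- df[, cols, drop = FALSE]
  for (f in feature_names()) df[[f]] <- as.numeric(df[[f]])
  df
}

#' Serialize an evaluation report (or any report list) to JSON
#'
#' Writes deterministically (no timestamps), unboxing scalars and keeping
#' full numeric precision, so identical reports produce byte-identical files.
#'
#' @param report A list, e.g. from [evaluate_classifier()].
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  report <- unclass_report(report)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

unclass_report <- function(x) {
  if (inherits(x, "confusion_matrix")) {
    return(list(counts = apply(unclass(x), 1L, as.list, simplify = FALSE)))
  }
  if (is.list(x)) return(lapply(unclass(x), unclass_report))
  if (is.matrix(x)) return(apply(x, 1L, as.list, simplify = FALSE))
  if (is.factor(x)) return(as.character(x))
  x
}
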