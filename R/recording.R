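#' Construct a triaxial acceleration recording
#'
#' A `triaxial_recording` holds one participant's continuous x/y/z
#' acceleration stream in gravitational units (g), together with the sampling
#' frequency and sensor placement. The y axis is the primary vertical axis by
#' the export convention of hip/back/ankle-worn devices.
#'
#' @param samples Numeric matrix or data.frame with columns `ax`, `ay`, `az`
#'   (accelerations in g). A 3-column unnamed matrix is accepted and the
#'   columns are taken as x, y, z in order.
#' @param fs Sampling frequency in Hz (> 0). Default 100 Hz.
#' @param recording_id,participant_id Identifier strings.
#' @param placement One of `"ankle"`, `"lower_back"`, `"hip"`.
#' @param max_g Absolute dynamic range of the sensor in g. Samples with
#'   `|value| > max_g` are rejected (or clipped, see `on_out_of_range`).
#' @param on_out_of_range `"error"` (default) to reject out-of-range samples,
#'   `"clip"` to clamp them to `[-max_g, max_g]` with a warning.
#' @return An object of class `triaxial_recording`: a list with elements
#'   `recording_id`, `participant_id`, `placement`, `fs` and `samples`
#'   (a data.frame with columns `ax`, `ay`, `az`).
#' @export
triaxial_recording <- function(samples, fs = 100,
                               recording_id = "rec",
                               participant_id = "p",
                               placement = "hip",
                               max_g = 16,
                               on_out_of_range = c("error", "clip")) {
  on_out_of_range <- match.arg(on_out_of_range)
  if (is.matrix(samples)) samples <- as.data.frame(samples)
  if (ncol(samples) != 3L) stop("samples must have exactly 3 columns (x, y, z)")
  names(samples) <- c("ax", "ay", "az")
  for (col in names(samples)) {
    v <- samples[[col]]
    if (!is.numeric(v)) stop("non-numeric acceleration column: ", col)
    if (any(!is.finite(v))) {
      stop("non-finite acceleration value in column ", col,
           " at row ", which(!is.finite(v))[1L])
    }
  }
  if (nrow(samples) < 1L) stop("recording must contain at least one sample")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number (Hz)")
  }
  out_of_range <- abs(as.matrix(samples)) > max_g
  if (any(out_of_range)) {
    if (on_out_of_range == "error") {
      bad_row <- which(rowSums(out_of_range) > 0)[1L]
      stop("acceleration exceeds +/-", max_g, " g at row ", bad_row)
    }
    m <- pmin(pmax(as.matrix(samples), -max_g), max_g)
    samples <- as.data.frame(m)
    names(samples) <- c("ax", "ay", "az")
    warning(sum(out_of_range), " sample value(s) clipped to +/-", max_g, " g")
  }
  structure(
    list(recording_id = as.character(recording_id),
         participant_id = as.character(participant_id),
         placement = check_placement(placement),
         fs = fs,
         samples = samples),
    class = "triaxial_recording"
  )
}

#' @export
print.triaxial_recording <- function(x, ...) {
  cat(sprintf(
    "<triaxial_recording> %s (participant %s, %s)\n  %d samples @ %g Hz = %.2f s\n",
    x$recording_id, x$participant_id, x$placement,
    nrow(x$samples), x$fs, nrow(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.triaxial_recording <- function(x) nrow(x$samples)

#' Read a raw acceleration recording from CSV
#'
#' Reads an ActiGraph-raw-export-like CSV: three numeric acceleration columns
#' in g, optionally preceded by a metadata header block of a known number of
#' lines. Row order is preserved.
#'
#' @param path Path to the CSV file.
#' @param fs Sampling frequency in Hz.
#' @param skip Number of leading metadata lines to skip (default 0).
#' @param columns Integer vector of length 3: which CSV columns hold the x, y
#'   and z accelerations (default `c(1, 2, 3)`).
#' @param header Logical; does the (post-skip) table start with a header row?
#' @inheritParams triaxial_recording
#' @return A [triaxial_recording()].
#' @export
read_recording <- function(path, fs = 100, skip = 0, columns = c(1L, 2L, 3L),
                           header = FALSE,
                           recording_id = basename(path),
                           participant_id = "p",
                           placement = "hip",
                           max_g = 16,
                           on_out_of_range = c("error", "clip")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, skip = skip, header = header,
                        stringsAsFactors = FALSE)
  if (max(columns) > ncol(df)) {
    stop("CSV has ", ncol(df), " column(s); need acceleration columns ",
         paste(columns, collapse = ", "))
  }
  acc <- df[, columns, drop = FALSE]
  for (j in seq_along(acc)) {
    v <- acc[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      if (anyNA(num)) {
        stop("non-numeric value in acceleration column ", columns[j],
             " of ", path, " at data line ", which(is.na(num))[1L])
      }
      acc[[j]] <- num
    }
  }
  triaxial_recording(acc, fs = fs, recording_id = recording_id,
                     participant_id = participant_id, placement = placement,
                     max_g = max_g,
                     on_out_of_range = match.arg(on_out_of_range))
}

#' Write a recording to CSV
#'
#' Writes the three acceleration columns (x, y, z order, no header) so that
#' `read_recording()` round-trips the samples.
#'
#' @param recording A [triaxial_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "triaxial_recording"))
  utils::write.table(recording$samples, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Construct an activity segment table
#'
#' Segments mark labeled activity bouts inside a recording with 0-based,
#' half-open sample intervals `[start, end)`. Segments belonging to one
#' recording must not overlap.
#'
#' @param recording_id Character vector of recording ids.
#' @param label Activity labels (walking/running/jumping).
#' @param start,end Integer sample indices, 0-based, half-open.
#' @return A data.frame of class `activity_segments`.
#' @export
activity_segments <- function(recording_id, label, start, end) {
  df <- data.frame(recording_id = as.character(recording_id),
                   label = activity_factor(label),
                   start = as.integer(start),
                   end = as.integer(end),
                   stringsAsFactors = FALSE)
  if (any(df$start < 0L)) stop("segment start must be >= 0")
  if (any(df$end <= df$start)) stop("segment end must exceed start")
  for (id in unique(df$recording_id)) {
    s <- df[df$recording_id == id, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1L && any(s$start[-1L] < s$end[-nrow(s)])) {
      stop("overlapping segments in recording ", id)
    }
  }
  class(df) <- c("activity_segments", "data.frame")
  df
}

#' Read / write segment label files
#'
#' Label files are CSVs with columns `recording_id,label,start,end`
#' (0-based half-open sample indices).
#'
#' @param path File path.
#' @return `read_segments()` returns an [activity_segments()] table.
#' @export
read_segments <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("recording_id", "label", "start", "end")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("label file missing column(s): ", paste(missing, collapse = ", "))
  }
  activity_segments(df$recording_id, df$label, df$start, df$end)
}

#' @rdname read_segments
#' @param segments An [activity_segments()] table.
#' @export
write_segments <- function(segments, path) {
  utils::write.csv(as.data.frame(segments), path, row.names = FALSE)
  invisible(path)
}
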