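#' Cut labeled sliding windows out of a recording
#'
#' Slices each activity segment into fixed-duration windows that inherit the
#' segment's label. Windows start at the segment start and advance by the
#' stride; a trailing partial window (shorter than the full window length) is
#' dropped. Windows never span segment boundaries. A segment shorter than one
#' window simply yields no windows.
#'
#' The number of windows per segment is
#' `max(0, floor((len - W) / S) + 1)` with `W = round(fs * window_seconds)`
#' and `S = round(fs * stride_seconds)` in samples.
#'
#' @param recording A [triaxial_recording()].
#' @param segments An [activity_segments()] table (rows for other recordings
#'   are ignored).
#' @param window_seconds Window duration in seconds (default 1).
#' @param stride_seconds Stride between window starts in seconds; defaults to
#'   the window length (non-overlapping windows).
#' @return A list of `labeled_window` objects. Each carries
#'   `participant_id`, `placement`, `label`, `window_index` (0-based, global
#'   over the returned list) and `samples` (a W x 3 matrix, columns ax/ay/az).
#' @export
window_segments <- function(recording, segments, window_seconds = 1,
                            stride_seconds = window_seconds) {
  stopifnot(inherits(recording, "triaxial_recording"))
  if (!is.numeric(window_seconds) || window_seconds <= 0) {
    stop("window_seconds must be > 0")
  }
  if (!is.numeric(stride_seconds) || stride_seconds <= 0) {
    stop("stride_seconds must be > 0")
  }
  segs <- segments[segments$recording_id == recording$recording_id, ,
                   drop = FALSE]
  n <- nrow(recording$samples)
  if (nrow(segs) && any(segs$end > n)) {
    stop("segment extends past recording end (", n, " samples)")
  }
  w <- as.integer(round(recording$fs * window_seconds))
  s <- as.integer(round(recording$fs * stride_seconds))
  if (w < 1L || s < 1L) stop("window/stride shorter than one sample")
  mat <- as.matrix(recording$samples)
  windows <- list()
  idx <- 0L
  for (i in seq_len(nrow(segs))) {
    seg_start <- segs$start[i]
    seg_end <- segs$end[i]
    len <- seg_end - seg_start
    if (len < w) next
    starts <- seq.int(seg_start, seg_end - w, by = s)
    for (st in starts) {
      windows[[length(windows) + 1L]] <- structure(
        list(participant_id = recording$participant_id,
             placement = recording$placement,
             label = as.character(segs$label[i]),
             window_index = idx,
             fs = recording$fs,
             samples = mat[(st + 1L):(st + w), , drop = FALSE]),
        class = "labeled_window")
      idx <- idx + 1L
    }
  }
  windows
}

#' @export
print.labeled_window <- function(x, ...) {
  cat(sprintf("<labeled_window> %s #%d (participant %s, %s): %d samples @ %g Hz\n",
              x$label, x$window_index, x$participant_id, x$placement,
              nrow(x$samples), x$fs))
  invisible(x)
}
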