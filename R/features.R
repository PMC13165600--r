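#' Names of the 54 window features, in canonical column order
#'
#' The feature vector per 1 s window is composed of:
#' \itemize{
#'   \item per axis a in x, y, z: `mean_a`, `sd_a`, `cv_a`, `skew_a`,
#'     `kurt_a`, `min_a`, `p25_a`, `median_a`, `p75_a`, `max_a` (30 values);
#'   \item resultant magnitude r = sqrt(x^2 + y^2 + z^2): `mean_r`, `sd_r`;
#'   \item per series s in x, y, z, r: `domfreq_s` (Hz), `dommag_s`,
#'     `totpower_s`, `medfreq_s` (Hz) (16 values);
#'   \item cross-axis Pearson correlations `corr_xy`, `corr_xz`, `corr_yz`;
#'   \item orientation angles `roll`, `pitch`, `yaw` (radians).
#' }
#' The time/percentile/magnitude list yields 50 features when spectral
#' features cover only the three axes; the four spectral features are also
#' computed on the resultant magnitude to complete the documented set of 54.
#'
#' @return Character vector of length 54.
#' @export
feature_names <- function() {
  time_stats <- c("mean", "sd", "cv", "skew", "kurt",
                  "min", "p25", "median", "p75", "max")
  freq_stats <- c("domfreq", "dommag", "totpower", "medfreq")
  c(as.vector(t(outer(c("x", "y", "z"), time_stats,
                      function(a, s) paste0(s, "_", a)))),
    "mean_r", "sd_r",
    as.vector(t(outer(c("x", "y", "z", "r"), freq_stats,
                      function(a, s) paste0(s, "_", a)))),
    "corr_xy", "corr_xz", "corr_yz",
    "roll", "pitch", "yaw")
}

## Metadata columns carried alongside the 54 features.
META_COLUMNS <- c("participant_id", "placement", "label", "window_index")

#' Time-domain summary statistics of one axis
#'
#' Computes the ten per-axis time-domain features. Conventions: `sd` is the
#' sample (n-1) standard deviation; `cv = sd / max(|mean|, 1e-6)` (the guard
#' keeps the ratio bounded on zero-mean horizontal axes); skewness
#' `m3 / m2^1.5` and excess kurtosis `m4 / m2^2 - 3` use central moments with
#' n denominators; a constant series has skew = kurt = 0 by convention;
#' percentiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7).
#'
#' @param series Numeric vector, length >= 2, finite.
#' @return Named numeric vector: mean, sd, cv, skew, kurt, min, p25, median,
#'   p75, max.
#' @export
time_features <- function(series) {
  if (!is.numeric(series) || length(series) < 2L) {
    stop("series must be numeric with length >= 2")
  }
  if (any(!is.finite(series))) stop("series contains non-finite values")
  n <- length(series)
  mu <- mean(series)
  s <- stats::sd(series)
  cv <- s / max(abs(mu), 1e-6)
  d <- series - mu
  m2 <- mean(d^2)
  if (m2 > 0) {
    skew <- mean(d^3) / m2^1.5
    kurt <- mean(d^4) / m2^2 - 3
  } else {
    skew <- 0
    kurt <- 0
  }
  q <- stats::quantile(series, probs = c(0, 0.25, 0.5, 0.75, 1),
                       names = FALSE, type = 7)
  c(mean = mu, sd = s, cv = cv, skew = skew, kurt = kurt,
    min = q[1L], p25 = q[2L], median = q[3L], p75 = q[4L], max = q[5L])
}

#' Mean and standard deviation of the signal magnitude
#'
#' The resultant magnitude is the per-sample Euclidean norm
#' `r_i = sqrt(ax_i^2 + ay_i^2 + az_i^2)`.
#'
#' @param window A `labeled_window` or a numeric n x 3 matrix.
#' @return Named numeric vector `c(mean_r, sd_r)`.
#' @export
magnitude_features <- function(window) {
  m <- window_matrix(window)
  r <- sqrt(rowSums(m^2))
  c(mean_r = mean(r), sd_r = stats::sd(r))
}

resultant <- function(window) {
  m <- window_matrix(window)
  sqrt(rowSums(m^2))
}

window_matrix <- function(window) {
  m <- if (inherits(window, "labeled_window")) window$samples else window
  m <- as.matrix(m)
  if (ncol(m) != 3L) stop("window must have 3 axis columns")
  if (any(!is.finite(m))) stop("window contains non-finite values")
  m
}

#' FFT spectral features of one series
#'
#' The discrete Fourier transform of the mean-removed series is evaluated at
#' bins `k = 1 ... floor(N/2)` (DC excluded — with the gravity offset present
#' the DC bin would otherwise dominate every window). With magnitudes `M_k`
#' at frequencies `k * fs / N`:
#' \itemize{
#'   \item `domfreq`: frequency of the largest `M_k` (ties break to the
#'     lowest frequency);
#'   \item `dommag`: `max(M_k) / N`;
#'   \item `totpower`: `sum(M_k^2) / N^2`;
#'   \item `medfreq`: lowest bin frequency where the cumulative `M_k^2`
#'     reaches half of the total.
#' }
#' A constant series has `dommag = totpower = 0` and `domfreq = medfreq`
#' equal to the lowest bin frequency (the tie-break).
#'
#' @param series Numeric vector, length >= 4.
#' @param fs Sampling frequency in Hz.
#' @return Named numeric vector: domfreq, dommag, totpower, medfreq.
#' @export
frequency_features <- function(series, fs) {
  if (!is.numeric(series) || length(series) < 4L) {
    stop("series must be numeric with length >= 4")
  }
  if (any(!is.finite(series))) stop("series contains non-finite values")
  n <- length(series)
  spec <- stats::fft(series - mean(series))
  k <- seq_len(n %/% 2L)
  mag <- Mod(spec[k + 1L])
  freq <- k * fs / n
  p <- mag^2
  total <- sum(p)
  imax <- which.max(mag)         # which.max returns the first (lowest-f) tie
  med_i <- if (total > 0) which(cumsum(p) >= 0.5 * total)[1L] else 1L
  c(domfreq = freq[imax],
    dommag = mag[imax] / n,
    totpower = total / n^2,
    medfreq = freq[med_i])
}

#' Pearson correlations between axis pairs
#'
#' If either axis of a pair is constant within the window its correlation is
#' undefined; the convention here is to return 0 for that pair.
#'
#' @inheritParams magnitude_features
#' @return Named numeric vector `c(corr_xy, corr_xz, corr_yz)`.
#' @export
cross_axis_correlations <- function(window) {
  m <- window_matrix(window)
  sds <- apply(m, 2L, stats::sd)
  pair <- function(i, j) {
    if (sds[i] == 0 || sds[j] == 0) return(0)
    stats::cor(m[, i], m[, j])
  }
  c(corr_xy = pair(1L, 2L), corr_xz = pair(1L, 3L), corr_yz = pair(2L, 3L))
}

#' Orientation angles from low-pass-filtered acceleration
#'
#' Each axis is low-pass filtered (2nd-order Butterworth, 1 Hz cutoff,
#' zero-phase; see [lowpass_zerophase()]) to isolate the gravity component,
#' and the filtered window means `(gx, gy, gz)` give
#' `roll = atan2(gy, gz)`, `pitch = atan2(-gx, sqrt(gy^2 + gz^2))`,
#' `yaw = atan2(gx, gy)`.
#'
#' Yaw — rotation about the gravity vector — is not observable from a static
#' accelerometer; the formula above is a documented convention, not a
#' physical heading estimate.
#'
#' @inheritParams magnitude_features
#' @param fs Sampling frequency in Hz.
#' @return Named numeric vector `c(roll, pitch, yaw)` in radians.
#' @export
orientation_features <- function(window, fs) {
  m <- window_matrix(window)
  g <- vapply(1:3, function(j) mean(lowpass_zerophase(m[, j], fs)), numeric(1))
  c(roll = atan2(g[2L], g[3L]),
    pitch = atan2(-g[1L], sqrt(g[2L]^2 + g[3L]^2)),
    yaw = atan2(g[1L], g[2L]))
}

window_features <- function(window, fs) {
  m <- window_matrix(window)
  r <- sqrt(rowSums(m^2))
  tx <- time_features(m[, 1L])
  ty <- time_features(m[, 2L])
  tz <- time_features(m[, 3L])
  out <- c(
    stats::setNames(tx, paste0(names(tx), "_x")),
    stats::setNames(ty, paste0(names(ty), "_y")),
    stats::setNames(tz, paste0(names(tz), "_z")),
    mean_r = mean(r), sd_r = stats::sd(r),
    stats::setNames(frequency_features(m[, 1L], fs),
                    c("domfreq_x", "dommag_x", "totpower_x", "medfreq_x")),
    stats::setNames(frequency_features(m[, 2L], fs),
                    c("domfreq_y", "dommag_y", "totpower_y", "medfreq_y")),
    stats::setNames(frequency_features(m[, 3L], fs),
                    c("domfreq_z", "dommag_z", "totpower_z", "medfreq_z")),
    stats::setNames(frequency_features(r, fs),
                    c("domfreq_r", "dommag_r", "totpower_r", "medfreq_r")),
    cross_axis_correlations(m),
    orientation_features(m, fs)
  )
  out[feature_names()]
}

#' Extract the 54-feature matrix from labeled windows
#'
#' Applies the full feature set to every window and returns one row per
#' window, with metadata columns (`participant_id`, `placement`, `label`,
#' `window_index`) followed by the 54 features in [feature_names()] order.
#' Deterministic; identical windows yield identical rows.
#'
#' @param windows A list of `labeled_window` objects (from
#'   [window_segments()]).
#' @param fs Sampling frequency in Hz; defaults to the value carried by the
#'   windows themselves.
#' @return A data.frame with 4 metadata columns + 54 feature columns. An
#'   empty window list yields a 0-row data.frame with the full header.
#' @export
extract_features <- function(windows, fs = NULL) {
  fn <- feature_names()
  if (length(windows) == 0L) {
    out <- c(list(participant_id = character(), placement = character(),
                  label = character(), window_index = integer()),
             stats::setNames(rep(list(numeric()), length(fn)), fn))
    return(as.data.frame(out, stringsAsFactors = FALSE))
  }
  rows <- vector("list", length(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    f <- fs %||% w$fs
    rows[[i]] <- tryCatch(
      window_features(w, f),
      error = function(e) {
        stop("feature extraction failed for window ", w$window_index,
             " (participant ", w$participant_id, "): ", conditionMessage(e))
      })
  }
  feats <- do.call(rbind, rows)
  meta <- data.frame(
    participant_id = vapply(windows, `[[`, character(1), "participant_id"),
    placement = vapply(windows, `[[`, character(1), "placement"),
    label = vapply(windows, `[[`, character(1), "label"),
    window_index = vapply(windows, `[[`, integer(1), "window_index"),
    stringsAsFactors = FALSE)
  cbind(meta, as.data.frame(feats))
}

#' Split a feature matrix into metadata and feature columns
#'
#' @param matrix A feature matrix data.frame as returned by
#'   [extract_features()].
#' @return For `feature_columns()`, the 54 feature names present in the
#'   matrix (in canonical order).
#' @export
feature_columns <- function(matrix) {
  intersect(feature_names(), names(matrix))
}
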