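#' Configuration for the synthetic activity-signal simulator
#'
#' Defines the laboratory-style protocol the simulator emulates: each
#' participant performs a fixed number of walking, running and jumping trials
#' (defaults 9 / 6 / 22) while wearing a triaxial accelerometer sampling at
#' `fs` Hz. The vertical (y) axis carries the +1 g gravity offset plus an
#' activity-specific impact train; horizontal axes carry correlated
#' lower-amplitude oscillation; white noise is added to all axes.
#'
#' @param n_participants Number of participants (default 48).
#' @param fs Sampling frequency in Hz (default 100).
#' @param placement Sensor placement; scales impact amplitudes via a fixed
#'   factor table (ankle 1.4, hip 1.0, lower_back 0.9).
#' @param walking_step_hz,running_step_hz Step-frequency ranges in Hz.
#' @param walking_amp_g,running_amp_g,jumping_amp_g Peak impact amplitude
#'   ranges in g above gravity.
#' @param jump_rate_hz Jump repetition rate range in Hz.
#' @param flight_fraction Range of the fraction of a jump cycle spent in
#'   flight (resultant near 0 g).
#' @param participant_sigma Sigma of the multiplicative lognormal
#'   participant effect applied to cadence and amplitude (default 0.1).
#' @param noise_sd_g White sensor noise standard deviation in g.
#' @param segment_seconds Named numeric vector: trial duration in seconds per
#'   activity.
#' @param trials Named integer vector: number of trials per activity.
#' @param rest_seconds Unlabeled quiet gap between trials (default 1 s).
#' @param seed Integer seed; fully determines the simulated dataset.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 48,
                       fs = 100,
                       placement = "hip",
                       walking_step_hz = c(1.5, 2.2),
                       running_step_hz = c(2.4, 3.2),
                       walking_amp_g = c(0.3, 0.8),
                       running_amp_g = c(1.5, 3.5),
                       jumping_amp_g = c(3.0, 7.0),
                       jump_rate_hz = c(0.8, 1.6),
                       flight_fraction = c(0.2, 0.4),
                       participant_sigma = 0.1,
                       noise_sd_g = 0.05,
                       segment_seconds = c(walking = 3, running = 2,
                                           jumping = 2),
                       trials = c(walking = 9, running = 6, jumping = 22),
                       rest_seconds = 1,
                       seed = 100) {
  cfg <- list(n_participants = as.integer(n_participants), fs = fs,
              placement = check_placement(placement),
              walking_step_hz = walking_step_hz,
              running_step_hz = running_step_hz,
              walking_amp_g = walking_amp_g,
              running_amp_g = running_amp_g,
              jumping_amp_g = jumping_amp_g,
              jump_rate_hz = jump_rate_hz,
              flight_fraction = flight_fraction,
              participant_sigma = participant_sigma,
              noise_sd_g = noise_sd_g,
              segment_seconds = segment_seconds,
              trials = trials,
              rest_seconds = rest_seconds,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_participants < 0L) stop("n_participants must be >= 0")
  if (cfg$fs <= 0) stop("fs must be > 0")
  rng <- c("walking_step_hz", "running_step_hz", "walking_amp_g",
           "running_amp_g", "jumping_amp_g", "jump_rate_hz")
  for (nm in rng) {
    r <- cfg[[nm]]
    if (length(r) != 2L || any(!is.finite(r)) || any(r < 0) || r[1L] > r[2L]) {
      stop(nm, " must be an ordered non-negative range c(lo, hi)")
    }
  }
  ff <- cfg$flight_fraction
  if (length(ff) != 2L || ff[1L] > ff[2L] || ff[1L] < 0 || ff[2L] > 0.6) {
    stop("flight_fraction must be an ordered range within [0, 0.6]")
  }
  if (cfg$participant_sigma < 0) stop("participant_sigma must be >= 0")
  if (cfg$noise_sd_g < 0) stop("noise_sd_g must be >= 0")
  for (nm in c("segment_seconds", "trials")) {
    v <- cfg[[nm]]
    if (!all(ACTIVITY_LEVELS %in% names(v))) {
      stop(nm, " must be named for walking, running and jumping")
    }
    if (any(v[ACTIVITY_LEVELS] < 0)) stop(nm, " must be non-negative")
  }
  if (is.null(cfg$seed) || is.na(cfg$seed)) stop("seed is required")
  invisible(cfg)
}

## Amplitude scaling by wear site: distal (ankle) sensors see larger impact
## accelerations than waist-level sites.
PLACEMENT_AMP_FACTOR <- c(ankle = 1.4, lower_back = 0.9, hip = 1.0)

## Per-participant RNG streams: sub-seed derived from the global seed so a
## single participant can be regenerated without simulating the others.
participant_seed <- function(seed, participant_index) {
  as.integer((as.numeric(seed) + 77003 * participant_index) %% 2147483647)
}

## One trial's noise-free signal. Returns an n x 3 matrix (ax, ay, az).
## Vertical (y): 1 g gravity + half-sine impact pulses (duty 20% of the
## cycle); running adds a brief low-g phase before each impact; jumping has a
## near-0 g flight interval followed by a high-amplitude landing spike.
## Horizontals: correlated oscillation at the cycle frequency, scaled to the
## impact amplitude.
synth_trial <- function(activity, n, fs, f, amp, flight_frac, phase) {
  t <- (seq_len(n) - 1L) / fs
  cyc <- (t * f + phase) %% 1
  y <- rep(1, n)
  if (activity == "walking") {
    duty <- 0.2
    in_pulse <- cyc < duty
    y[in_pulse] <- 1 + amp * sin(pi * cyc[in_pulse] / duty)
  } else if (activity == "running") {
    duty <- 0.2
    in_pulse <- cyc < duty
    y[in_pulse] <- 1 + amp * sin(pi * cyc[in_pulse] / duty)
    aerial <- cyc >= 0.75 & cyc < 0.87          # brief low-g aerial phase
    y[aerial] <- 0.1
  } else {                                      # jumping
    land <- 0.12                                # landing spike, cycle fraction
    flight <- cyc >= (1 - flight_frac - land) & cyc < (1 - land)
    landing <- cyc >= (1 - land)
    y[flight] <- 0
    y[landing] <- 1 + amp * sin(pi * (cyc[landing] - (1 - land)) / land)
  }
  h <- 0.25 * amp * sin(2 * pi * (t * f + phase))
  x <- 0.8 * h + 0.1 * amp * sin(2 * pi * (2 * f * t + phase) + 1)
  z <- 0.6 * h
  cbind(x, y, z, deparse.level = 0)
}

#' Simulate one participant's recording and its activity segments
#'
#' Generates a single concatenated recording containing all of the
#' participant's trials (walking, then running, then jumping, per the trial
#' counts in the config), separated by short unlabeled quiet gaps. Trial
#' cadence and amplitude are drawn uniformly from the configured ranges and
#' scaled by the participant's lognormal effect and the placement factor.
#' Fully determined by `(config, participant_index)`.
#'
#' @param config A [sim_config()].
#' @param participant_index Integer in `1:n_participants`.
#' @return A list with elements `recording` (a [triaxial_recording()]) and
#'   `segments` (an [activity_segments()] table).
#' @export
simulate_participant <- function(config, participant_index) {
  stopifnot(inherits(config, "sim_config"))
  if (participant_index < 1L || participant_index > config$n_participants) {
    stop("participant_index must be in 1:", config$n_participants)
  }
  pid <- sprintf("P%02d", participant_index)
  fs <- config$fs
  pf <- PLACEMENT_AMP_FACTOR[[config$placement]]
  withr::with_seed(participant_seed(config$seed, participant_index), {
    cadence_factor <- exp(stats::rnorm(1, 0, config$participant_sigma))
    amp_factor <- exp(stats::rnorm(1, 0, config$participant_sigma))
    rest_n <- as.integer(round(config$rest_seconds * fs))
    pieces <- list()
    seg_label <- character()
    seg_start <- integer()
    seg_end <- integer()
    pos <- 0L
    for (activity in ACTIVITY_LEVELS) {
      n_trials <- config$trials[[activity]]
      trial_n <- as.integer(round(config$segment_seconds[[activity]] * fs))
      for (k in seq_len(n_trials)) {
        if (trial_n < 1L) next
        rng <- switch(activity,
                      walking = config$walking_step_hz,
                      running = config$running_step_hz,
                      jumping = config$jump_rate_hz)
        amp_rng <- config[[paste0(activity, "_amp_g")]]
        f <- stats::runif(1, rng[1L], rng[2L]) * cadence_factor
        amp <- stats::runif(1, amp_rng[1L], amp_rng[2L]) * amp_factor * pf
        ff <- stats::runif(1, config$flight_fraction[1L],
                           config$flight_fraction[2L])
        phase <- stats::runif(1)
        sig <- synth_trial(activity, trial_n, fs, f, amp, ff, phase)
        pieces[[length(pieces) + 1L]] <- sig
        seg_label <- c(seg_label, activity)
        seg_start <- c(seg_start, pos)
        pos <- pos + trial_n
        seg_end <- c(seg_end, pos)
        if (rest_n > 0L) {
          rest <- cbind(numeric(rest_n), rep(1, rest_n), numeric(rest_n))
          pieces[[length(pieces) + 1L]] <- rest
          pos <- pos + rest_n
        }
      }
    }
    mat <- do.call(rbind, pieces)
    if (config$noise_sd_g > 0) {
      mat <- mat + matrix(stats::rnorm(length(mat), 0, config$noise_sd_g),
                          nrow(mat), 3L)
    }
    rec <- triaxial_recording(mat, fs = fs, recording_id = pid,
                              participant_id = pid,
                              placement = config$placement,
                              on_out_of_range = "clip")
    segs <- activity_segments(rep(pid, length(seg_label)), seg_label,
                              seg_start, seg_end)
    list(recording = rec, segments = segs)
  })
}

#' Simulate a full multi-participant dataset
#'
#' @param config A [sim_config()].
#' @return A list with `recordings` (list of [triaxial_recording()]) and
#'   `segments` (a single [activity_segments()] table covering all
#'   recordings). `n_participants = 0` yields empty outputs.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_participants == 0L) {
    return(list(recordings = list(),
                segments = activity_segments(character(), character(),
                                             integer(), integer())))
  }
  sims <- lapply(seq_len(config$n_participants),
                 function(i) simulate_participant(config, i))
  segs <- do.call(rbind, lapply(sims, `[[`, "segments"))
  class(segs) <- c("activity_segments", "data.frame")
  list(recordings = lapply(sims, `[[`, "recording"), segments = segs)
}

#' Write a simulated dataset to a directory
#'
#' Emits one headerless recording CSV per participant, a combined labels CSV
#' and a YAML snapshot of the simulation config.
#'
#' @param dataset Output of [simulate_dataset()].
#' @param config The [sim_config()] used.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in dataset$recordings) {
    write_recording(rec, file.path(dir, paste0(rec$recording_id, ".csv")))
  }
  write_segments(dataset$segments, file.path(dir, "labels.csv"))
  yaml::write_yaml(unclass(config), file.path(dir, "sim_config.yaml"))
  invisible(dir)
}
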