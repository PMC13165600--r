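# Shared fixtures and independent oracles used across the suite.

# Small, fast simulation protocol (full defaults are exercised separately).
tiny_sim_config <- function(seed = 42, n_participants = 6,
                            trials = c(walking = 2, running = 2,
                                       jumping = 3), ...) {
  sim_config(n_participants = n_participants, seed = seed, trials = trials,
             ...)
}

# Build a labeled window directly from axis vectors.
make_window <- function(x, y, z, fs = 100, label = "walking",
                        participant = "p1", placement = "hip", index = 0L) {
  structure(list(participant_id = participant, placement = placement,
                 label = label, window_index = as.integer(index), fs = fs,
                 samples = cbind(x, y, z, deparse.level = 0)),
            class = "labeled_window")
}

# Cache expensive fixtures across tests within one run.
.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Feature matrix from the tiny simulated dataset (6 participants).
tiny_feature_matrix <- function() {
  cached("tiny_fm", {
    ds <- simulate_dataset(tiny_sim_config())
    wins <- unlist(lapply(ds$recordings, function(r) {
      window_segments(r, ds$segments)
    }), recursive = FALSE)
    extract_features(wins)
  })
}

# Separable toy feature matrix: every feature takes a distinct constant per
# class (plus tiny jitter); several participants so grouped splits/folds are
# possible.
separable_matrix <- function(n_participants = 10, windows_each = 6,
                             seed = 7) {
  withr::with_seed(seed, {
    rows <- list()
    for (i in seq_len(n_participants)) {
      for (j in seq_len(windows_each)) {
        lab <- activity_levels()[1L + (j %% 3L)]
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = sprintf("S%02d", i), placement = "hip",
          label = lab, window_index = j - 1L,
          stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    base <- match(df$label, activity_levels())
    feats <- feature_names()
    for (k in seq_along(feats)) {
      df[[feats[k]]] <- base * (1 + k / 54) + rnorm(nrow(df), 0, 0.01)
    }
    df
  })
}

# Brute-force O(N^2) DFT oracle for the spectral features.
dft_oracle <- function(series, fs) {
  n <- length(series)
  x <- series - mean(series)
  ks <- seq_len(n %/% 2L)
  mag <- vapply(ks, function(k) {
    idx <- 0:(n - 1L)
    re <- sum(x * cos(-2 * pi * k * idx / n))
    im <- sum(x * sin(-2 * pi * k * idx / n))
    sqrt(re^2 + im^2)
  }, numeric(1))
  p <- mag^2
  total <- sum(p)
  imax <- which.max(mag)
  med_i <- if (total > 0) which(cumsum(p) >= 0.5 * total)[1L] else 1L
  c(domfreq = ks[imax] * fs / n, dommag = mag[imax] / n,
    totpower = total / n^2, medfreq = ks[med_i] * fs / n)
}

# Exhaustive concordant-pair AUC oracle (ties count one half).
auc_pair_oracle <- function(positive, score) {
  pos <- score[positive]
  neg <- score[!positive]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}
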