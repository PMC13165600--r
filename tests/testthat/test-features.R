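test_that("time-domain statistics follow the documented conventions", {
  f <- time_features(c(1, 1, 1, 1))
  expect_equal(unname(f[c("mean", "sd", "cv", "skew", "kurt", "min",
                          "max")]),
               c(1, 0, 0, 0, 0, 1, 1))

  g <- time_features(0:4)
  expect_equal(unname(g["mean"]), 2)
  expect_equal(unname(g["sd"]), sqrt(10 / 4))
  expect_equal(unname(g[c("min", "p25", "median", "p75", "max")]),
               c(0, 1, 2, 3, 4))
  expect_equal(unname(g["skew"]), 0)
  expect_equal(unname(g["kurt"]), 6.8 / 4 - 3)   # m4/m2^2 - 3, n denominators
})

test_that("skewness and kurtosis match the moment-based oracle", {
  skip_if_not_installed("e1071")
  withr::with_seed(4, {
    for (i in 1:5) {
      x <- rnorm(60)^2
      f <- time_features(x)
      expect_equal(unname(f["skew"]), e1071::skewness(x, type = 1))
      expect_equal(unname(f["kurt"]), e1071::kurtosis(x, type = 1))
    }
  })
})

test_that("time features are order-invariant and reject bad input", {
  x <- c(3.2, -1, 0.5, 8, 2)
  expect_equal(time_features(x), time_features(rev(x)))
  expect_error(time_features(1), "length")
  expect_error(time_features(c(1, NA, 2)), "non-finite")
})

test_that("magnitude features equal the per-sample Euclidean norm", {
  static <- make_window(rep(0, 100), rep(1, 100), rep(0, 100))
  expect_equal(magnitude_features(static), c(mean_r = 1, sd_r = 0))

  pyth <- make_window(rep(0.6, 100), rep(0.8, 100), rep(0, 100))
  expect_equal(unname(magnitude_features(pyth)["mean_r"]), 1)

  withr::with_seed(2, {
    m <- matrix(rnorm(300), ncol = 3)
    oracle <- apply(m, 1, function(v) sqrt(sum(v^2)))   # elementwise oracle
    got <- magnitude_features(m)
    expect_equal(unname(got["mean_r"]), mean(oracle))
    expect_equal(unname(got["sd_r"]), sd(oracle))
  })
})

test_that("spectral features resolve pure and mixed tones", {
  t <- (0:99) / 100
  ff <- frequency_features(sin(2 * pi * 5 * t), fs = 100)
  expect_equal(unname(ff["domfreq"]), 5)
  expect_equal(unname(ff["medfreq"]), 5)
  expect_equal(unname(ff["dommag"]), 0.5, tolerance = 1e-10)

  two <- sin(2 * pi * 3 * t) + 2 * sin(2 * pi * 10 * t)
  expect_equal(unname(frequency_features(two, 100)["domfreq"]), 10)

  const <- frequency_features(rep(2.5, 100), 100)
  expect_equal(unname(const[c("dommag", "totpower")]), c(0, 0))
  expect_equal(unname(const[c("domfreq", "medfreq")]), c(1, 1)) # lowest bin

  expect_error(frequency_features(c(1, 2, 3), 100), "length")
})

test_that("FFT features agree with the direct-DFT oracle to 1e-9 relative", {
  withr::with_seed(19, {
    for (i in 1:12) {
      n <- sample(8:128, 1)
      x <- rnorm(n) + sin(2 * pi * sample(1:3, 1) * seq_len(n) / n)
      got <- frequency_features(x, fs = 100)
      want <- dft_oracle(x, fs = 100)
      expect_equal(got, want, tolerance = 1e-9)
    }
  })
})

test_that("cross-axis correlations handle affine and degenerate axes", {
  x <- rnorm(50)
  w <- make_window(x, 2 * x + 1, rep(0.3, 50))
  cc <- cross_axis_correlations(w)
  expect_equal(unname(cc["corr_xy"]), 1)
  expect_equal(unname(cc[c("corr_xz", "corr_yz")]), c(0, 0))  # constant z
  w2 <- make_window(x, -x, x)
  expect_equal(unname(cross_axis_correlations(w2)["corr_xy"]), -1)
})

test_that("orientation angles recover static gravity poses", {
  n <- 100
  flat <- make_window(rep(0, n), rep(0, n), rep(1, n))
  o <- orientation_features(flat, 100)
  expect_equal(unname(o["roll"]), 0)
  expect_equal(unname(o["pitch"]), 0)

  upright <- make_window(rep(0, n), rep(1, n), rep(0, n))
  o2 <- orientation_features(upright, 100)
  expect_equal(unname(o2["roll"]), pi / 2)
  expect_equal(unname(o2["pitch"]), 0)
})

test_that("the 1 Hz low-pass suppresses ripple the raw mean cannot", {
  t <- (0:99) / 100
  # 10x the cutoff: angles must sit within 0.02 rad of the static pose
  w10 <- make_window(0.5 * sin(2 * pi * 10 * t), rep(0, 100), rep(1, 100))
  o10 <- orientation_features(w10, 100)
  expect_lt(abs(o10["roll"]), 0.02)
  expect_lt(abs(o10["pitch"]), 0.02)

  # non-integer cycle count: the unfiltered mean-based oracle breaks the
  # bound while the filtered estimate holds it
  x <- 0.5 * sin(2 * pi * 5.5 * t)
  w55 <- make_window(x, rep(0, 100), rep(1, 100))
  o55 <- orientation_features(w55, 100)
  raw_pitch <- atan2(-mean(x), 1)
  expect_gt(abs(raw_pitch), 0.02)
  expect_lt(abs(o55["pitch"]), 0.02)
  expect_lt(abs(o55["pitch"]), abs(raw_pitch))
})

test_that("zero-phase filtering passes constants exactly and attenuates 10x ripple", {
  t <- (0:99) / 100
  expect_equal(lowpass_zerophase(rep(0.7, 100), 100), rep(0.7, 100))
  # a tone 10x above cutoff keeps a decaying transient, but its window
  # mean — what the orientation features consume — stays ~100x below the
  # unit amplitude
  resid <- lowpass_zerophase(sin(2 * pi * 10 * t), 100)
  expect_lt(max(abs(resid)), 0.6)
  expect_lt(abs(mean(resid)), 0.01)
  expect_error(lowpass_zerophase(rnorm(8), 100), "too short")
})

test_that("every valid window yields exactly the 54 documented features", {
  expect_length(feature_names(), 54L)
  withr::with_seed(6, {
    wins <- lapply(1:3, function(i) {
      make_window(rnorm(100), 1 + rnorm(100), rnorm(100), index = i - 1L)
    })
  })
  fm <- extract_features(wins)
  expect_equal(nrow(fm), 3L)
  expect_equal(setdiff(names(fm), c("participant_id", "placement", "label",
                                    "window_index")),
               feature_names())
  expect_true(all(is.finite(as.matrix(fm[, feature_names()]))))
})

test_that("feature extraction is deterministic and metadata flows through", {
  w <- make_window(rnorm(100), rnorm(100) + 1, rnorm(100),
                   label = "running", participant = "P09",
                   placement = "ankle", index = 7L)
  fm <- extract_features(list(w, w))
  expect_equal(fm[1, feature_names()], fm[2, feature_names()],
               ignore_attr = TRUE)
  expect_equal(fm$participant_id, c("P09", "P09"))
  expect_equal(fm$label, c("running", "running"))
  expect_equal(fm$placement[1], "ankle")
})

test_that("feature ordering invariants hold on simulated windows", {
  fm <- tiny_feature_matrix()
  for (a in c("x", "y", "z")) {
    expect_true(all(fm[[paste0("min_", a)]] <= fm[[paste0("p25_", a)]]))
    expect_true(all(fm[[paste0("p25_", a)]] <= fm[[paste0("median_", a)]]))
    expect_true(all(fm[[paste0("median_", a)]] <= fm[[paste0("p75_", a)]]))
    expect_true(all(fm[[paste0("p75_", a)]] <= fm[[paste0("max_", a)]]))
  }
  for (s in c("x", "y", "z", "r")) {
    expect_true(all(fm[[paste0("domfreq_", s)]] <= 50))
    expect_true(all(fm[[paste0("medfreq_", s)]] <= 50))
    expect_true(all(fm[[paste0("totpower_", s)]] >= 0))
  }
  for (p in c("corr_xy", "corr_xz", "corr_yz")) {
    expect_true(all(abs(fm[[p]]) <= 1 + 1e-12))
  }
})

test_that("features are scale-equivariant under window scaling", {
  withr::with_seed(23, {
    w <- make_window(0.3 + 0.2 * rnorm(100), 1 + rnorm(100),
                     -0.4 + 0.3 * rnorm(100))
  })
  c_ <- 2.5
  ws <- make_window(c_ * w$samples[, 1], c_ * w$samples[, 2],
                    c_ * w$samples[, 3])
  a <- accelhar:::window_features(w, 100)
  b <- accelhar:::window_features(ws, 100)
  scaled <- unlist(lapply(c("x", "y", "z"), function(ax) {
    paste0(c("sd_", "min_", "max_", "mean_", "p25_", "median_", "p75_"), ax)
  }))
  scaled <- c(scaled, "mean_r", "sd_r",
              paste0("dommag_", c("x", "y", "z", "r")))
  expect_equal(b[scaled], c_ * a[scaled], tolerance = 1e-10)
  expect_equal(b[paste0("totpower_", c("x", "y", "z", "r"))],
               c_^2 * a[paste0("totpower_", c("x", "y", "z", "r"))],
               tolerance = 1e-10)
  invariant <- c(paste0(c("cv_", "skew_", "kurt_", "domfreq_", "medfreq_"),
                        rep(c("x", "y", "z"), each = 5)),
                 "domfreq_r", "medfreq_r",
                 "corr_xy", "corr_xz", "corr_yz", "roll", "pitch", "yaw")
  expect_equal(b[invariant], a[invariant], tolerance = 1e-8)
})
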