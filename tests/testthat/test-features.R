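# Spectral and time-domain feature extraction against independent oracles.

t4s <- (0:255) / 64

test_that("band_power matches the brute-force DFT oracle and Parseval", {
  expect_equal(band_power(rep(0, 256), c(0.5, 3)), 0)
  # exact-bin 2 Hz tone concentrates its power in the locomotion band
  tone <- sin(2 * pi * 2 * t4s)
  total <- band_power(tone, c(0, 32))
  expect_gt(band_power(tone, c(0.5, 3)) / total, 0.99)
  # Parseval: full-band power equals time-domain mean square of the
  # tapered signal
  set.seed(4)
  for (i in 1:5) {
    x <- rnorm(256)
    xt <- (x - mean(x)) * (0.5 * (1 - cos(2 * pi * (0:255) / 256)))
    expect_rel_equal(band_power(x, c(0, 32)), mean(xt^2), 1e-9)
  }
  expect_error(band_power(rnorm(256), c(10, 40)), "fs/2")
})

test_that("freezing index separates locomotion-band from freeze-band power", {
  expect_lt(freezing_index(sin(2 * pi * 2 * t4s)), 0.01)
  expect_gt(freezing_index(sin(2 * pi * 5 * t4s)), 100)
  mix <- sin(2 * pi * 2 * t4s) + sin(2 * pi * 5 * t4s + 1)
  fi <- freezing_index(mix)
  oracle <- oracle_band_power(mix, c(3, 8)) / oracle_band_power(mix, c(0.5, 3))
  expect_equal(fi, oracle, tolerance = 1e-9)
  expect_lt(abs(fi - 1), 0.05)
  # scale invariance of the ratio
  expect_equal(freezing_index(3.7 * mix), fi, tolerance = 1e-9)
  # near-zero locomotion power maps to a large finite value
  expect_true(is.finite(freezing_index(rep(0, 256))))
})

test_that("spectral peaks find the stride/stance structure", {
  two <- sin(2 * pi * 1 * t4s) + 0.5 * sin(2 * pi * 2 * t4s + 0.7)
  pk <- spectral_peaks(two)
  expect_equal(pk[["hfp_hz"]], 1)
  expect_equal(pk[["shfp_hz"]], 2)
  expect_lt(abs(pk[["mhfp"]] / pk[["mshfp"]] - 2), 0.1)
  # one true peak: runner-up falls back to a non-adjacent bin, tiny
  one <- sin(2 * pi * 5 * t4s)
  pk1 <- spectral_peaks(one)
  expect_equal(pk1[["hfp_hz"]], 5)
  expect_lt(pk1[["mshfp"]], 0.05 * pk1[["mhfp"]])
  # degenerate spectrum falls back to the band edge with zero magnitude
  expect_equal(spectral_peaks(rep(0, 256)),
               c(hfp_hz = 0.25, mhfp = 0, shfp_hz = 0.25, mshfp = 0))
})

test_that("time features match closed forms on constants and sines", {
  cw <- time_features(rep(0.5, 256))
  expect_equal(cw[["min"]], 0.5); expect_equal(cw[["max"]], 0.5)
  expect_equal(cw[["median"]], 0.5); expect_equal(cw[["mean"]], 0.5)
  expect_equal(cw[["rms"]], 0.5); expect_equal(cw[["std"]], 0)
  expect_equal(cw[["skewness"]], 0); expect_equal(cw[["kurtosis"]], 0)
  expect_equal(cw[["zcr"]], 0); expect_equal(cw[["mcr"]], 0)
  expect_equal(cw[["sum_mag"]], 128)
  sine <- sin(2 * pi * 2 * t4s)
  sf <- time_features(sine)
  expect_equal(sf[["mcr"]], 16 / 255)
  expect_lt(abs(sf[["skewness"]]), 0.01)
  expect_lt(abs(sf[["kurtosis"]] - (-1.5)), 0.05)
  # uniform samples: excess kurtosis near -1.2
  set.seed(6)
  su <- time_features(runif(256))
  expect_lt(abs(su[["kurtosis"]] - (-1.2)), 0.3)
})

test_that("spectral entropy is 0 for a pure tone and high for white noise", {
  expect_lt(spectral_entropy(sin(2 * pi * 4 * t4s), taper = FALSE), 0.01)
  expect_equal(spectral_entropy(rep(0, 256)), 0)
  set.seed(5)
  ent <- vapply(1:100, function(i) spectral_entropy(rnorm(256)),
                numeric(1))
  expect_gt(mean(ent), 0.9)
})

test_that("feature vectors have the frozen 14/17 layout and are finite", {
  w <- sin(2 * pi * 1.25 * t4s) + rnorm(256, 0, 0.05)
  v14 <- extract_features(w)
  v17 <- extract_features(w, include_discarded = TRUE)
  expect_length(v14, 14L)
  expect_length(v17, 17L)
  expect_named(v14, feature_names())
  expect_named(v17, feature_names(TRUE))
  expect_equal(v17[names(v14)], v14)
  expect_identical(extract_features(w), v14)   # determinism
  # every feature finite on a diverse corpus, including simulator windows
  corpus <- window_corpus(200L)
  b <- fixture_batch()
  all_w <- cbind(corpus, t(b$windows[seq(1, nrow(b$windows), by = 7), ]))
  for (j in seq_len(ncol(all_w)))
    expect_true(all(is.finite(extract_features(all_w[, j], include_discarded = TRUE))))
})

test_that("features match brute-force oracles over a 1000-window corpus", {
  corpus <- window_corpus(1000L)
  for (j in seq_len(ncol(corpus))) {
    x <- corpus[, j]
    expect_rel_equal(band_power(x, c(3, 8)), oracle_band_power(x, c(3, 8)))
    expect_rel_equal(band_power(x, c(0.5, 3)),
                     oracle_band_power(x, c(0.5, 3)))
    fi_oracle <- oracle_band_power(x, c(3, 8)) /
      max(oracle_band_power(x, c(0.5, 3)), 1e-12)
    expect_rel_equal(freezing_index(x), fi_oracle)
    pk <- spectral_peaks(x); ok <- oracle_peaks(x)
    expect_equal(pk[c("hfp_hz", "shfp_hz")], ok[c("hfp_hz", "shfp_hz")])
    expect_rel_equal(pk[c("mhfp", "mshfp")], ok[c("mhfp", "mshfp")])
    tf <- time_features(x); om <- oracle_moments(x)
    expect_rel_equal(tf[c("mean", "std", "skewness", "kurtosis")],
                     om[c("mean", "std", "skewness", "kurtosis")])
    expect_true(pk[["mhfp"]] >= pk[["mshfp"]])
  }
})

test_that("FI is higher during FoG than during gait on simulated data", {
  b <- fixture_batch()
  fi <- batch_features(b)[, "fi"]
  expect_gt(median(fi[b$labels == 1]), 5 * median(fi[b$labels == 0]))
})

test_that("feature CSV round trip preserves the canonical order", {
  b <- fixture_batch()
  f <- withr::local_tempfile(fileext = ".csv")
  df <- write_features_csv(b, f)
  back <- read_features_csv(f)
  expect_equal(names(back), c("subject_id", "start_index", "label",
                              feature_names()))
  expect_equal(as.matrix(back[feature_names()]),
               as.matrix(df[feature_names()]), tolerance = 1e-12)
})
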