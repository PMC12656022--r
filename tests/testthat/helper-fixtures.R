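# Shared fixtures, memoized so expensive objects (trained detectors,
# cohorts) are built once per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

# Small deterministic recording for I/O round trips.
tiny_recording <- function(n = 10L, seed = 42L) {
  set.seed(seed)
  fog_recording(time_ms = floor((0:(n - 1)) * 1000 / 64),
                accel_mg = matrix(sample(-2000:2000, n * 9, replace = TRUE),
                                  n, 9),
                annotation = sample(1:2, n, replace = TRUE),
                subject_id = "tiny")
}

# One simulated subject with clear FoG episodes (2 min), and a detector
# trained on it: enough for prediction/streaming tests.
fixture_subject <- function() memo("subject", function() {
  simulate_subject(sim_spec(duration_s = 120, fog_episodes = 2,
                            fog_dur_range = c(5, 15), seed = 3))
})

fixture_batch <- function() memo("batch", function() {
  make_batch(fixture_subject())
})

fixture_model <- function() memo("model", function() {
  b <- fixture_batch()
  grid_search_train(batch_features(b), b$labels, seed = 1)
})

# Well-separated Gaussian blobs for pure-classifier tests.
blob_data <- function(n = 200L, p = 14L, sep = 4, seed = 1L) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n / 2 * p, 0), ncol = p),
             matrix(stats::rnorm(n / 2 * p, sep), ncol = p))
  colnames(x) <- feature_names()
  list(x = x, y = rep(c(0L, 1L), each = n / 2))
}

# Seeded corpus of heterogeneous windows (noise, tones, gait-like mixes)
# for oracle comparisons.
window_corpus <- function(n_windows = 1000L, l = 256L, seed = 11L) {
  set.seed(seed)
  t <- (0:(l - 1)) / 64
  vapply(seq_len(n_windows), function(i) {
    kind <- i %% 4L
    base <- stats::rnorm(l, 0, 0.05)
    if (kind == 1L)
      base <- base + stats::runif(1, 0.1, 1) *
        sin(2 * pi * stats::runif(1, 0.5, 3) * t + stats::runif(1, 0, 6))
    if (kind == 2L)
      base <- base + stats::runif(1, 0.1, 1) *
        sin(2 * pi * stats::runif(1, 3, 8) * t + stats::runif(1, 0, 6)) +
        0.3 * sin(2 * pi * stats::runif(1, 8, 15) * t)
    if (kind == 3L)
      base <- 1 + base + 0.4 * sin(2 * pi * 1 * t) +
        0.25 * sin(2 * pi * 2 * t)
    base
  }, numeric(l))
}

# ---- independent oracles -------------------------------------------------

# Brute-force one-sided DFT via an explicit exponential-sum matrix (no fft).
oracle_dft <- function(x) {
  n <- length(x)
  k <- 0:(n %/% 2)
  w <- exp(-2i * pi * outer(0:(n - 1), k) / n)
  drop(x %*% w)
}

oracle_spectrum <- function(x, fs = 64, taper = TRUE) {
  n <- length(x)
  x <- x - sum(x) / n
  if (taper) x <- x * (0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n)))
  xf <- oracle_dft(x)
  mult <- c(1, rep(2, n %/% 2 - 1L), 1)
  list(freq = (0:(n %/% 2)) * fs / n,
       power = mult * Mod(xf)^2 / n^2,
       amplitude = 2 * Mod(xf) / (n / 2))
}

oracle_band_power <- function(x, band, fs = 64) {
  sp <- oracle_spectrum(x, fs)
  sum(sp$power[sp$freq >= band[1] & sp$freq <= band[2]])
}

oracle_peaks <- function(x, fs = 64, band = c(0.25, 15)) {
  sp <- oracle_spectrum(x, fs)
  a <- sp$amplitude
  idx <- which(sp$freq >= band[1] & sp$freq <= band[2])
  peaks <- idx[vapply(idx, function(k) {
    lo <- if (k > 1) a[k - 1] else -Inf
    hi <- if (k < length(a)) a[k + 1] else -Inf
    a[k] > lo && a[k] > hi
  }, logical(1))]
  peaks <- peaks[order(-a[peaks], sp$freq[peaks])]
  if (length(peaks) < 2) {
    rest <- setdiff(idx, c(peaks, peaks - 1L, peaks + 1L))
    rest <- rest[order(-a[rest], sp$freq[rest])]
    peaks <- c(peaks, rest)[1:2]
  }
  peaks <- peaks[order(-a[peaks], sp$freq[peaks])][1:2]
  c(hfp_hz = sp$freq[peaks[1]], mhfp = a[peaks[1]],
    shfp_hz = sp$freq[peaks[2]], mshfp = a[peaks[2]])
}

# Plain-sum moment oracle (population estimators, excess kurtosis).
oracle_moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  c(mean = mu, std = sqrt(m2), skewness = m3 / m2^1.5,
    kurtosis = m4 / m2^2 - 3)
}

expect_rel_equal <- function(actual, expected, tol = 1e-6) {
  denom <- pmax(abs(expected), 1e-12)
  expect_lt(max(abs(actual - expected) / denom), tol)
}
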