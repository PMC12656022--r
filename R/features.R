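# Per-window spectral and time-domain features.
#
# Spectrum estimation convention (used by every spectral feature): remove the
# window mean, apply a periodic Hann taper, take a length-L DFT, keep the
# one-sided half. The Hann taper limits leakage that would otherwise corrupt
# the Freezing Index at the 3 Hz band edge; "periodic" (denominator L, not
# L-1) confines an exact-bin tone to its bin and the two adjacent ones.

FREEZE_BAND <- c(3, 8)     # Hz, lower-limb trembling
LOCO_BAND <- c(0.5, 3)     # Hz, normal stepping
ANALYSIS_BAND <- c(0.25, 15)
FI_EPS <- 1e-12

hann_taper <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

# One-sided spectrum of a window. Power is normalized so that the sum over
# all one-sided bins equals the mean square of the (mean-removed, tapered)
# time signal (Parseval); amplitude is normalized so a unit sine at an exact
# bin reports magnitude 1.
window_spectrum <- function(x, fs = 64, taper = TRUE) {
  l <- length(x)
  x <- x - mean(x)
  w <- if (taper) hann_taper(l) else rep(1, l)
  xw <- x * w
  xf <- stats::fft(xw)[1:(l %/% 2 + 1L)]
  mag <- Mod(xf)
  mult <- c(1, rep(2, l %/% 2 - 1L), 1)          # double interior bins
  list(freq = (0:(l %/% 2)) * fs / l,
       power = mult * mag^2 / l^2,
       amplitude = 2 * mag / max(sum(w), .Machine$double.eps),
       total_power = mean(xw^2))
}

#' Band power of a window
#'
#' Sum of one-sided power-spectrum bins with `f_lo <= f <= f_hi`, computed on
#' the mean-removed, Hann-tapered window. Disjoint bands covering
#' \[0, fs/2\] sum to the total power of the tapered signal (Parseval).
#'
#' @param x window of samples (length 256 in the default pipeline).
#' @param band numeric `c(f_lo, f_hi)` in Hz.
#' @param fs sampling rate in Hz (default 64).
#' @return nonnegative power (units of g^2 for an acceleration window).
#' @export
band_power <- function(x, band, fs = 64) {
  if (length(band) != 2L || band[1L] < 0 || band[2L] > fs / 2 ||
      band[1L] >= band[2L])
    stop("band must satisfy 0 <= f_lo < f_hi <= fs/2; got [",
         paste(band, collapse = ", "), "] at fs = ", fs)
  sp <- window_spectrum(x, fs)
  sum(sp$power[sp$freq >= band[1L] & sp$freq <= band[2L]])
}

#' Freezing Index of a window
#'
#' Ratio of spectral power in the freezing band (3-8 Hz, lower-limb
#' trembling) to power in the locomotion band (0.5-3 Hz, normal stepping).
#' Elevated during FoG episodes, where spectral power shifts into the
#' freezing band. A small epsilon guards the denominator so that standing
#' windows with near-zero locomotion power map to a large finite ratio.
#'
#' @inheritParams band_power
#' @param freeze_band,loco_band band edges in Hz.
#' @return nonnegative ratio (unitless).
#' @export
freezing_index <- function(x, fs = 64, freeze_band = FREEZE_BAND,
                           loco_band = LOCO_BAND) {
  band_power(x, freeze_band, fs) / max(band_power(x, loco_band, fs), FI_EPS)
}

#' Two highest spectral peaks of a window
#'
#' Finds the two largest local maxima (strictly greater than both neighbor
#' bins) of the one-sided amplitude spectrum within the analysis band
#' (0.25-15 Hz), ties broken toward lower frequency. During normal gait
#' these correspond to the stride (~1 Hz) and stance (~2 Hz) frequencies.
#' When fewer than two local maxima exist, the remaining slots fall back to
#' the largest bins not adjacent to an already-selected peak; an all-zero
#' spectrum reports frequency 0.25 Hz with magnitude 0.
#'
#' @inheritParams band_power
#' @param band analysis band in Hz (default `c(0.25, 15)`).
#' @return named numeric: `hfp_hz`, `mhfp`, `shfp_hz`, `mshfp`
#'   (frequencies in Hz, magnitudes in the window's amplitude units), with
#'   `mhfp >= mshfp`.
#' @export
spectral_peaks <- function(x, fs = 64, band = ANALYSIS_BAND) {
  sp <- window_spectrum(x, fs)
  a <- sp$amplitude
  nb <- length(a)
  in_band <- which(sp$freq >= band[1L] & sp$freq <= band[2L])
  fallback_f <- sp$freq[in_band[1L]]
  if (all(a[in_band] <= 0))
    return(c(hfp_hz = fallback_f, mhfp = 0, shfp_hz = fallback_f, mshfp = 0))
  is_peak <- vapply(in_band, function(k) {
    lo <- if (k > 1L) a[k - 1L] else -Inf
    hi <- if (k < nb) a[k + 1L] else -Inf
    a[k] > lo && a[k] > hi
  }, logical(1))
  cand <- in_band[is_peak]
  cand <- cand[order(-a[cand], sp$freq[cand])]
  picked <- utils::head(cand, 2L)
  if (length(picked) < 2L) {
    rest <- setdiff(in_band, unique(c(picked, picked - 1L, picked + 1L)))
    rest <- rest[order(-a[rest], sp$freq[rest])]
    picked <- c(picked, utils::head(rest, 2L - length(picked)))
  }
  picked <- picked[order(-a[picked], sp$freq[picked])]
  if (length(picked) < 2L) picked <- rep(picked, 2L)[1:2]
  c(hfp_hz = sp$freq[picked[1L]], mhfp = a[picked[1L]],
    shfp_hz = sp$freq[picked[2L]], mshfp = a[picked[2L]])
}

count_crossings <- function(d) sum(diff(d > 0) != 0)

#' Time-domain features of a window
#'
#' Amplitude statistics (minimum, maximum, median, mean, RMS, standard
#' deviation), shape statistics (excess kurtosis and skewness, population
#' estimators; zero-variance windows report 0), crossing rates, and the sum
#' of magnitudes. Because the pipeline's windows hold a nonnegative
#' acceleration magnitude, a zero-crossing rate of the raw signal would be
#' degenerate: ZCR is therefore computed on the linearly detrended window
#' while MCR counts crossings of the raw window's own mean, keeping the two
#' features distinct.
#'
#' @param x window of samples, length >= 2.
#' @return named numeric vector: `min`, `max`, `median`, `mean`, `rms`,
#'   `std`, `kurtosis`, `skewness`, `zcr`, `mcr`, `sum_mag`. Crossing rates
#'   are per sample pair (divided by length - 1).
#' @export
time_features <- function(x) {
  l <- length(x)
  if (l < 2L) stop("window must have at least 2 samples")
  mu <- mean(x)
  d <- x - mu
  m2 <- mean(d^2)
  if (m2 > .Machine$double.eps) {
    skew <- mean(d^3) / m2^1.5
    kurt <- mean(d^4) / m2^2 - 3
  } else {
    skew <- 0; kurt <- 0
  }
  t0 <- seq_len(l) - (l + 1) / 2
  slope <- sum(t0 * d) / sum(t0^2)
  detr <- d - slope * t0
  c(min = min(x), max = max(x), median = stats::median(x), mean = mu,
    rms = sqrt(mean(x^2)), std = sqrt(m2), kurtosis = kurt,
    skewness = skew, zcr = count_crossings(detr) / (l - 1L),
    mcr = count_crossings(d) / (l - 1L), sum_mag = sum(abs(x)))
}

#' Normalized spectral entropy of a window
#'
#' Shannon entropy of the normalized one-sided power spectrum (DC bin
#' excluded), divided by the log of the bin count so the result lies in
#' \[0, 1\]: 0 for a single-bin tone, near 1 for white noise. A zero-power
#' window reports 0 by convention.
#'
#' @inheritParams band_power
#' @param taper apply the Hann taper (default `TRUE`); `FALSE` gives the
#'   plain-DFT spectrum.
#' @return entropy in \[0, 1\].
#' @export
spectral_entropy <- function(x, fs = 64, taper = TRUE) {
  sp <- window_spectrum(x, fs, taper)
  p <- sp$power[-1L]
  tot <- sum(p)
  if (tot <= 0) return(0)
  p <- p[p > 0] / tot
  -sum(p * log(p)) / log(length(sp$power) - 1L)
}

#' Canonical feature order
#'
#' The default classifier input has 14 features; RMS, mean and STD were
#' found to carry little independent information next to the retained
#' amplitude statistics and are kept out of the default set, available via
#' `include_discarded` (17 features) for importance analysis.
#'
#' @param include_discarded include `mean`, `rms`, `std` (appended last).
#' @return character vector of feature names in extraction order.
#' @export
feature_names <- function(include_discarded = FALSE) {
  base <- c("fi", "hfp_hz", "mhfp", "shfp_hz", "mshfp", "min", "max",
            "median", "kurtosis", "skewness", "entropy", "zcr", "mcr",
            "sum_mag")
  if (include_discarded) c(base, "mean", "rms", "std") else base
}

#' Extract the feature vector of one window
#'
#' @param x window of samples (length 256 in the default pipeline).
#' @param fs sampling rate in Hz (default 64).
#' @param include_discarded also return `mean`, `rms`, `std` (17 features
#'   instead of the default 14).
#' @return named numeric vector in [feature_names()] order.
#' @export
extract_features <- function(x, fs = 64, include_discarded = FALSE) {
  tf <- time_features(x)
  pk <- spectral_peaks(x, fs)
  v <- c(fi = freezing_index(x, fs), pk["hfp_hz"], pk["mhfp"],
         pk["shfp_hz"], pk["mshfp"], tf["min"], tf["max"], tf["median"],
         tf["kurtosis"], tf["skewness"],
         entropy = spectral_entropy(x, fs), tf["zcr"], tf["mcr"],
         tf["sum_mag"], tf["mean"], tf["rms"], tf["std"])
  names(v) <- feature_names(TRUE)
  v[feature_names(include_discarded)]
}

#' Feature matrix of a window batch
#'
#' @param batch a `window_batch` from [make_batch()].
#' @param include_discarded 17-feature set instead of 14.
#' @return numeric matrix, one row per window, columns in
#'   [feature_names()] order.
#' @export
batch_features <- function(batch, include_discarded = FALSE) {
  nm <- feature_names(include_discarded)
  m <- matrix(0, nrow(batch$windows), length(nm),
              dimnames = list(NULL, nm))
  for (i in seq_len(nrow(batch$windows)))
    m[i, ] <- extract_features(batch$windows[i, ], batch$fs_hz,
                               include_discarded)
  m
}

#' Write / read a labeled feature table as CSV
#'
#' The CSV carries a header naming the features in canonical order plus
#' `subject_id`, `start_index` and `label` columns, so a persisted table is
#' self-describing about feature order.
#'
#' @param batch a `window_batch`.
#' @param path destination CSV.
#' @param include_discarded 17-feature set instead of 14.
#' @return the data frame written, invisibly.
#' @export
write_features_csv <- function(batch, path, include_discarded = FALSE) {
  df <- data.frame(subject_id = rep(batch$subject_id,
                                    length(batch$labels)),
                   start_index = batch$start_index,
                   label = batch$labels,
                   batch_features(batch, include_discarded),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
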