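# Windowing pipeline: magnitude -> low-pass -> segment -> label.

#' Euclidean acceleration magnitude of one sensor
#'
#' @param rec a `fog_recording`.
#' @param sensor one of `"ankle"`, `"thigh"`, `"trunk"`. The detector uses
#'   the ankle (shank) sensor; the others exist for sensitivity analysis.
#' @param to_g divide the stored milli-g values by 1000 so downstream
#'   features are in g. Default `TRUE`.
#' @param axis optionally a single axis (`"x"`, `"y"`, `"z"`) instead of the
#'   Euclidean norm of the three.
#' @return numeric vector of length `n_samples(rec)`.
#' @export
magnitude <- function(rec, sensor = c("ankle", "thigh", "trunk"),
                      to_g = TRUE, axis = NULL) {
  sensor <- match.arg(sensor)
  cols <- paste(sensor, c("x", "y", "z"), sep = "_")
  a <- rec$accel_mg[, cols, drop = FALSE]
  if (!is.null(axis)) {
    if (!axis %in% c("x", "y", "z")) stop("unknown axis: ", axis)
    out <- a[, paste(sensor, axis, sep = "_")]
  } else {
    out <- sqrt(rowSums(a^2))
  }
  if (to_g) out / 1000 else out
}

# Direct-form II transposed IIR step with explicit state, so the same
# realization serves offline (vectorized over a whole series) and streaming
# (persistent zf across packets) use.
iir_filter <- function(b, a, x, zi = NULL) {
  b <- b / a[1L]; a <- a / a[1L]
  nfilt <- max(length(a), length(b))
  b <- c(b, rep(0, nfilt - length(b)))
  a <- c(a, rep(0, nfilt - length(a)))
  z <- if (is.null(zi)) rep(0, nfilt - 1L) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1L] * xi + z[1L]
    for (j in seq_len(nfilt - 2L))
      z[j] <- b[j + 1L] * xi + z[j + 1L] - a[j + 1L] * yi
    z[nfilt - 1L] <- b[nfilt] * xi - a[nfilt] * yi
    y[i] <- yi
  }
  list(y = y, zf = z)
}

# Steady-state initial conditions for a unit-step input (scipy lfilter_zi
# construction): ensures a constant signal passes through with no transient.
iir_step_state <- function(b, a) {
  b <- b / a[1L]; a <- a / a[1L]
  nfilt <- max(length(a), length(b))
  b <- c(b, rep(0, nfilt - length(b)))
  a <- c(a, rep(0, nfilt - length(a)))
  n <- nfilt - 1L
  A <- t(rbind(-a[2:nfilt], cbind(diag(1, n - 1L), rep(0, n - 1L))))
  B <- b[2:nfilt] - b[1L] * a[2:nfilt]
  solve(diag(1, n) - A, B)
}

# Zero-phase filtering with odd-reflection padding and matched initial
# conditions at both ends (the transient-free filtfilt construction).
zero_phase_filter <- function(b, a, x) {
  nfilt <- max(length(a), length(b))
  pad <- 3L * (nfilt - 1L)
  n <- length(x)
  if (n <= pad)
    stop("series too short for zero-phase filtering: need more than ",
         pad, " samples, got ", n)
  zi <- iir_step_state(b, a)
  ext <- c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- iir_filter(b, a, ext, zi * ext[1L])$y
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)])$y)
  y[(pad + 1L):(pad + n)]
}

lowpass_coefs <- function(cutoff_hz, fs_hz, order = 4L) {
  if (fs_hz <= 2 * cutoff_hz)
    stop("sampling rate must exceed twice the cutoff (fs = ", fs_hz,
         " Hz, cutoff = ", cutoff_hz, " Hz)")
  bt <- signal::butter(order, cutoff_hz / (fs_hz / 2), type = "low")
  list(b = bt$b, a = bt$a)
}

#' Low-pass filter an acceleration series
#'
#' 4th-order Butterworth with a 15 Hz default cutoff: human gait dynamics
#' lie below 15 Hz and higher frequencies are dominated by sensor noise.
#' In zero-phase mode the filter runs forward-backward (no group delay,
#' effectively 8th-order magnitude); in causal mode it runs single-pass,
#' which is what the streaming detector uses.
#'
#' @param x numeric series (acceleration magnitude).
#' @param cutoff_hz cutoff frequency in Hz (default 15).
#' @param fs_hz sampling rate in Hz (default 64).
#' @param zero_phase forward-backward if `TRUE` (default), causal otherwise.
#' @param order filter order (default 4).
#' @return filtered series, same length as `x`.
#' @export
lowpass <- function(x, cutoff_hz = 15, fs_hz = 64, zero_phase = TRUE,
                    order = 4L) {
  co <- lowpass_coefs(cutoff_hz, fs_hz, order)
  warmup <- 3L * (max(length(co$a), length(co$b)) - 1L)
  if (length(x) <= warmup)
    stop("series of length ", length(x), " is shorter than the filter ",
         "warm-up; provide at least ", warmup + 1L, " samples")
  if (zero_phase) zero_phase_filter(co$b, co$a, x)
  else iir_filter(co$b, co$a, x)$y
}

#' Sliding-window start indices
#'
#' For a series of `n` samples, windows of `l` samples advancing by `s`
#' samples start at 0, s, 2s, ... The count is `floor((n - l)/s) + 1` for
#' `n >= l` and 0 otherwise.
#'
#' @param n series length in samples.
#' @param l window length in samples (256 = 4 s at 64 Hz).
#' @param s step in samples (32 = 0.5 s at 64 Hz).
#' @return integer vector of 0-based start indices (possibly empty).
#' @export
window_starts <- function(n, l = 256L, s = 32L) {
  if (l <= 0L || s <= 0L) stop("window and step lengths must be positive")
  if (n < l) return(integer(0))
  seq.int(0L, n - l, by = s)
}

samples_or_stop <- function(seconds, fs_hz, what) {
  x <- seconds * fs_hz
  if (abs(x - round(x)) > 1e-9)
    stop(what, " of ", seconds, " s is not a whole number of samples at ",
         fs_hz, " Hz (", x, ")")
  as.integer(round(x))
}

#' Segment a series into overlapping windows
#'
#' @param x numeric series.
#' @param fs_hz sampling rate (default 64).
#' @param window_s window length in seconds (default 4).
#' @param step_s step in seconds (default 0.5).
#' @return list with `starts` (0-based) and `windows` (matrix, one row per
#'   window).
#' @export
segment_windows <- function(x, fs_hz = 64, window_s = 4, step_s = 0.5) {
  l <- samples_or_stop(window_s, fs_hz, "window length")
  s <- samples_or_stop(step_s, fs_hz, "step")
  starts <- window_starts(length(x), l, s)
  w <- matrix(0, length(starts), l)
  for (i in seq_along(starts)) w[i, ] <- x[(starts[i] + 1L):(starts[i] + l)]
  list(starts = starts, windows = w)
}

#' Label one annotation window
#'
#' A window touching any non-experimental sample (annotation 0) is excluded.
#' Otherwise it is labeled FoG when the fraction of samples annotated 2
#' reaches `threshold` (default 0.5, so an exact half-and-half window
#' resolves to FoG), and normal gait otherwise.
#'
#' @param ann integer annotation slice (values in {0,1,2}).
#' @param threshold FoG majority threshold in (0, 1].
#' @return `"fog"`, `"normal"`, or `"excluded"`.
#' @export
label_window <- function(ann, threshold = 0.5) {
  if (any(!(ann %in% c(0L, 1L, 2L))))
    stop("annotation values must be 0, 1 or 2")
  if (any(ann == 0L)) return("excluded")
  if (mean(ann == 2L) >= threshold) "fog" else "normal"
}

#' Build a labeled window batch from a recording
#'
#' Composes the preprocessing pipeline: ankle magnitude, 15 Hz low-pass,
#' 4 s / 0.5 s sliding-window segmentation, and window labeling. Windows
#' touching annotation-0 samples are dropped. Recordings with timestamp gaps
#' larger than two sample periods are split into contiguous blocks first so
#' no window straddles a gap.
#'
#' @param rec a `fog_recording`.
#' @param window_s,step_s window geometry in seconds (defaults 4 and 0.5).
#' @param cutoff_hz low-pass cutoff (default 15 Hz).
#' @param label_threshold FoG majority threshold (default 0.5).
#' @param sensor which sensor to use (default ankle).
#' @param zero_phase filtering mode (default `TRUE`; the streaming path uses
#'   `FALSE` for causal equivalence).
#' @return A `window_batch`: list with `windows` (M x L matrix of filtered
#'   magnitude in g), `labels` (0/1), `start_index` (0-based into the source
#'   recording), `subject_id`, `window_s`, `step_s`, `fs_hz`.
#' @export
make_batch <- function(rec, window_s = 4, step_s = 0.5, cutoff_hz = 15,
                       label_threshold = 0.5, sensor = "ankle",
                       zero_phase = TRUE) {
  validate_recording(rec)
  fs <- rec$sample_rate_hz
  l <- samples_or_stop(window_s, fs, "window length")
  blocks <- split_contiguous(rec)
  win <- list(); lab <- integer(0); st <- integer(0)
  offset <- 0L
  for (blk in blocks) {
    nb <- n_samples(blk)
    if (nb >= max(l, 13L)) {
      mag <- magnitude(blk, sensor)
      filt <- lowpass(mag, cutoff_hz, fs, zero_phase = zero_phase)
      seg <- segment_windows(filt, fs, window_s, step_s)
      if (length(seg$starts)) {
        labs <- vapply(seg$starts, function(s0) {
          label_window(blk$annotation[(s0 + 1L):(s0 + l)], label_threshold)
        }, character(1))
        keep <- labs != "excluded"
        if (any(keep)) {
          win[[length(win) + 1L]] <- seg$windows[keep, , drop = FALSE]
          lab <- c(lab, as.integer(labs[keep] == "fog"))
          st <- c(st, seg$starts[keep] + offset)
        }
      }
    }
    offset <- offset + nb
  }
  structure(
    list(windows = if (length(win)) do.call(rbind, win)
                   else matrix(0, 0L, l),
         labels = lab, start_index = st, subject_id = rec$subject_id,
         window_s = window_s, step_s = step_s, fs_hz = fs),
    class = "window_batch")
}

#' @export
print.window_batch <- function(x, ...) {
  cat("<window_batch> subject ", x$subject_id, ": ", nrow(x$windows),
      " windows of ", ncol(x$windows), " samples (", x$window_s, " s / ",
      x$step_s, " s step), ", sum(x$labels), " FoG\n", sep = "")
  invisible(x)
}
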