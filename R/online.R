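# Streaming detection: ring buffer, causal filter state, cue hysteresis,
# and the newline-delimited device packet codec.

#' Initialize streaming detector state
#'
#' The stream consumes raw triaxial ankle samples, converts them to
#' magnitude, filters them with the causal (single-pass) low-pass filter,
#' and keeps the last `window_s` seconds in a ring buffer. A classification
#' is emitted after every step once the buffer has filled: decision `i`
#' lands at sample index `L + S*i` (256 + 32 i at the defaults). The cue
#' turns on at the first FoG-positive decision and off after
#' `cue_off_after` consecutive negatives (hysteresis, so the cue spans an
#' episode rather than flickering).
#'
#' @param model a `fog_detector`.
#' @param fs_hz,window_s,step_s window geometry (defaults 64 Hz, 4 s,
#'   0.5 s).
#' @param cutoff_hz causal low-pass cutoff (default 15 Hz).
#' @param cue_off_after consecutive negative decisions that release the cue
#'   (default 2).
#' @param in_mg incoming samples are in milli-g and should be scaled to g
#'   (default `TRUE`, matching the DAPHNet dialect).
#' @return A `stream_state`.
#' @export
stream_init <- function(model, fs_hz = 64, window_s = 4, step_s = 0.5,
                        cutoff_hz = 15, cue_off_after = 2L, in_mg = TRUE) {
  l <- samples_or_stop(window_s, fs_hz, "window length")
  s <- samples_or_stop(step_s, fs_hz, "step")
  co <- lowpass_coefs(cutoff_hz, fs_hz)
  structure(
    list(model = model, fs_hz = fs_hz, l = l, s = s,
         ring = numeric(l), sample_count = 0L,
         filt_b = co$b, filt_a = co$a,
         filt_state = rep(0, max(length(co$a), length(co$b)) - 1L),
         decisions = data.frame(sample_index = integer(0),
                                label = integer(0), score = numeric(0),
                                cue_on = logical(0)),
         cue_active = FALSE, neg_streak = 0L,
         cue_off_after = as.integer(cue_off_after), in_mg = in_mg),
    class = "stream_state")
}

#' Feed samples to the streaming detector
#'
#' @param state a `stream_state` from [stream_init()].
#' @param new_samples n x 3 matrix (or length-3 vector) of raw ankle
#'   acceleration, or a numeric vector of precomputed magnitudes when
#'   `magnitude = TRUE`.
#' @param magnitude `new_samples` is already a magnitude series in g.
#' @return Updated `stream_state`; decisions accumulate in
#'   `state$decisions` (`sample_index` counts samples consumed when the
#'   decision fired, `cue_on` is the cue state after applying hysteresis).
#' @export
stream_step <- function(state, new_samples, magnitude = FALSE) {
  if (magnitude) {
    mag <- as.numeric(new_samples)
  } else {
    if (is.null(dim(new_samples)))
      new_samples <- matrix(new_samples, ncol = 3L, byrow = TRUE)
    mag <- sqrt(rowSums(new_samples^2))
    if (state$in_mg) mag <- mag / 1000
  }
  fr <- iir_filter(state$filt_b, state$filt_a, mag, state$filt_state)
  state$filt_state <- fr$zf
  for (v in fr$y) {
    state$ring <- c(state$ring[-1L], v)
    state$sample_count <- state$sample_count + 1L
    if (state$sample_count >= state$l &&
        (state$sample_count - state$l) %% state$s == 0L) {
      pred <- predict(state$model,
                      extract_features(state$ring, state$fs_hz,
                                       include_discarded =
                                         length(state$model$feature_order) > 14L))
      if (pred$label == 1L) {
        state$cue_active <- TRUE
        state$neg_streak <- 0L
      } else {
        state$neg_streak <- state$neg_streak + 1L
        if (state$neg_streak >= state$cue_off_after)
          state$cue_active <- FALSE
      }
      state$decisions <- rbind(state$decisions,
                               data.frame(sample_index = state$sample_count,
                                          label = pred$label,
                                          score = pred$score,
                                          cue_on = state$cue_active))
    }
  }
  state
}

#' Replay a recording through the streaming detector
#'
#' Feeds a recording's ankle samples through [stream_step()] in packets of
#' `chunk` samples and returns the decision log — the file-replay
#' equivalent of running the wearable online.
#'
#' @param rec a `fog_recording`.
#' @param model a `fog_detector`.
#' @param chunk samples per packet (default 32, one step).
#' @param ... passed to [stream_init()].
#' @return data frame of decisions with an added `time_s` column.
#' @export
replay_stream <- function(rec, model, chunk = 32L, ...) {
  state <- stream_init(model, fs_hz = rec$sample_rate_hz, ...)
  ankle <- rec$accel_mg[, 1:3, drop = FALSE]
  n <- nrow(ankle)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    state <- stream_step(state, ankle[i:j, , drop = FALSE])
    i <- j + 1L
  }
  d <- state$decisions
  d$time_s <- d$sample_index / rec$sample_rate_hz
  d
}

#' Rhythmic cue pattern
#'
#' The haptic stimulus is a square wave obtained by repeated activation and
#' deactivation of the vibration motor: within each period of
#' `1/rate_hz` seconds the motor is on for the first `duty` fraction.
#'
#' @param rate_hz pattern frequency in Hz (default 1).
#' @param duty on-fraction in (0, 1) (default 0.5).
#' @return A `cue_pattern`.
#' @export
cue_pattern <- function(rate_hz = 1, duty = 0.5) {
  if (rate_hz <= 0) stop("rate_hz must be positive")
  if (duty <= 0 || duty >= 1) stop("duty must lie in (0, 1)")
  structure(list(rate_hz = rate_hz, duty = duty), class = "cue_pattern")
}

#' Motor state of a cue pattern
#'
#' Pure function of the time since cue activation: on iff the fractional
#' part of `t * rate_hz` is below `duty`.
#'
#' @param pattern a [cue_pattern()].
#' @param t_s seconds since activation (vectorized, >= 0).
#' @return logical vector.
#' @export
cue_state <- function(pattern, t_s) {
  if (any(t_s < 0)) stop("t_s must be nonnegative")
  (t_s * pattern$rate_hz) %% 1 < pattern$duty
}

#' Detection latency per FoG onset
#'
#' For each true episode onset, the time from onset to the first
#' FoG-positive decision at or after it. Under the majority-label rule the
#' earliest window that can go positive ends half a window after the
#' onset, so even a perfect classifier has a floor of about
#' `window_s/2 + step_s` seconds.
#'
#' @param true_onsets sorted sample indices of episode onsets.
#' @param decisions decision log from [replay_stream()]/[stream_step()].
#' @param fs_hz sampling rate (default 64).
#' @return data frame with `onset_index`, `latency_s` (`NA` when missed),
#'   `missed`.
#' @export
detection_latency <- function(true_onsets, decisions, fs_hz = 64) {
  pos <- decisions$sample_index[decisions$label == 1L]
  res <- lapply(true_onsets, function(on) {
    hit <- pos[pos >= on]
    if (!length(hit)) data.frame(onset_index = on, latency_s = NA_real_,
                                 missed = TRUE)
    else data.frame(onset_index = on,
                    latency_s = (min(hit) - on) / fs_hz, missed = FALSE)
  })
  do.call(rbind, res)
}

# ---- packet codec -------------------------------------------------------
# Newline-delimited text frames in the spirit of the device's UDP packets:
#   FOG,<direction>,<timestamp_ms>,<motor>,<decision>,<n>,<samples...>,<checksum>
# direction: H (to host, carries samples) or D (to device, carries the
# classifier decision). decision is "-" on to-host frames. The checksum is
# the sum of all preceding comma-separated fields' bytes modulo 65536.

#' Construct a device packet
#'
#' A to-host packet carries up to 32 raw triaxial ankle samples (one 0.5 s
#' step), the acquisition timestamp and the current motor state; a
#' to-device packet carries the classifier decision that drives the motor.
#'
#' @param timestamp_ms integer acquisition timestamp.
#' @param samples n x 3 matrix of raw ankle values in milli-g (n <= 32);
#'   may have zero rows for a to-device frame.
#' @param motor_on logical motor activation status.
#' @param direction `"to_host"` or `"to_device"`.
#' @param decision optional 0/1 classifier decision (to-device frames).
#' @return A `fog_packet`.
#' @export
fog_packet <- function(timestamp_ms, samples = matrix(numeric(0), 0, 3),
                       motor_on = FALSE,
                       direction = c("to_host", "to_device"),
                       decision = NULL) {
  direction <- match.arg(direction)
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L && nrow(samples) > 0L)
    stop("samples must have 3 columns")
  if (nrow(samples) > 32L) stop("at most 32 samples per packet")
  storage.mode(samples) <- "double"
  dimnames(samples) <- NULL
  structure(list(timestamp_ms = as.integer(timestamp_ms),
                 samples = samples, motor_on = isTRUE(motor_on),
                 direction = direction,
                 decision = if (is.null(decision)) NULL
                            else as.integer(decision)),
            class = "fog_packet")
}

packet_checksum <- function(body) {
  sum(utf8ToInt(body)) %% 65536L
}

#' Serialize / parse a device packet
#'
#' `encode_packet()` renders one newline-free text frame with a trailing
#' additive checksum; `decode_packet()` parses it back, rejecting frames
#' with a bad magic, field count, or checksum. `decode(encode(p))` is the
#' identity.
#'
#' @param packet a [fog_packet()].
#' @param line a text frame.
#' @return `encode_packet()`: a character frame. `decode_packet()`: a
#'   `fog_packet`.
#' @export
encode_packet <- function(packet) {
  stopifnot(inherits(packet, "fog_packet"))
  dircode <- if (packet$direction == "to_host") "H" else "D"
  dec <- if (is.null(packet$decision)) "-" else as.character(packet$decision)
  samp <- if (nrow(packet$samples))
    format(as.vector(t(packet$samples)), trim = TRUE, scientific = FALSE,
           digits = 15)
  else character(0)
  body <- paste(c("FOG", dircode, packet$timestamp_ms,
                  as.integer(packet$motor_on), dec, nrow(packet$samples),
                  samp), collapse = ",")
  paste0(body, ",", packet_checksum(body))
}

#' @rdname encode_packet
#' @export
decode_packet <- function(line) {
  parts <- strsplit(trimws(line), ",", fixed = TRUE)[[1L]]
  if (length(parts) < 7L)
    stop("frame error at field ", length(parts), ": truncated packet")
  if (parts[1L] != "FOG") stop("frame error at field 1: bad magic '",
                               parts[1L], "'")
  body <- paste(parts[-length(parts)], collapse = ",")
  chk <- suppressWarnings(as.integer(parts[length(parts)]))
  if (is.na(chk) || chk != packet_checksum(body))
    stop("frame error at field ", length(parts), ": checksum mismatch")
  n <- suppressWarnings(as.integer(parts[6L]))
  if (is.na(n) || length(parts) != 7L + 3L * n)
    stop("frame error at field 6: sample count disagrees with frame length")
  samples <- if (n > 0L)
    matrix(as.numeric(parts[7:(6L + 3L * n)]), n, 3L, byrow = TRUE)
  else matrix(numeric(0), 0, 3)
  fog_packet(timestamp_ms = as.integer(parts[3L]), samples = samples,
             motor_on = parts[4L] == "1",
             direction = if (parts[2L] == "H") "to_host" else "to_device",
             decision = if (parts[5L] == "-") NULL
                        else as.integer(parts[5L]))
}
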