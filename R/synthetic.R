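# Synthetic multi-subject accelerometer cohorts with the spectral structure
# the detector assumes: stride/stance peaks near 1 and 2 Hz during gait,
# reduced-amplitude 3-8 Hz trembling during FoG, near-noise-floor standing.

#' Simulation parameters
#'
#' Defaults describe one ~5 minute walking trial: 64 Hz sampling, a 1 Hz
#' stride fundamental with a 2 Hz stance harmonic at 0.6 of its amplitude,
#' four FoG episodes with durations drawn uniformly from 0.5-40.5 s (the
#' episode-duration range of the DAPHNet annotations), trembling during
#' FoG confined to the 3-8 Hz freezing band at half the gait amplitude,
#' 15 % of the task spent standing, and 0.02 g white sensor noise over a
#' 1 g gravity baseline.
#'
#' @param duration_s trial length in seconds (default 300).
#' @param fs_hz sampling rate (default 64).
#' @param stride_hz gait fundamental in Hz (default 1).
#' @param stance_hz second gait peak in Hz (default `2 * stride_hz`).
#' @param gait_amp stride oscillation amplitude in g (default 0.3).
#' @param harmonic_ratio stance amplitude relative to stride (default 0.6).
#' @param fog_episodes number of FoG episodes (default 4).
#' @param fog_dur_range episode duration bounds in seconds, within
#'   \[0.5, 40.5\].
#' @param fog_band trembling frequency band in Hz (default `c(3, 8)`).
#' @param fog_amp_scale trembling amplitude relative to `gait_amp`, in
#'   (0, 1) (default 0.5: FoG magnitude drops relative to gait).
#' @param stand_fraction fraction of the task spent standing (default
#'   0.15).
#' @param noise_std white noise standard deviation in g (default 0.02).
#' @param gravity_g gravity baseline on the vertical axis (default 1).
#' @param margin_s non-experimental (annotation 0) lead-in/lead-out
#'   seconds (default 2).
#' @param seed integer seed (default 1).
#' @return A `sim_spec`.
#' @export
sim_spec <- function(duration_s = 300, fs_hz = 64, stride_hz = 1,
                     stance_hz = 2 * stride_hz, gait_amp = 0.3,
                     harmonic_ratio = 0.6, fog_episodes = 4L,
                     fog_dur_range = c(0.5, 40.5), fog_band = c(3, 8),
                     fog_amp_scale = 0.5, stand_fraction = 0.15,
                     noise_std = 0.02, gravity_g = 1, margin_s = 2,
                     seed = 1L) {
  spec <- structure(as.list(environment()), class = "sim_spec")
  if (fog_dur_range[1L] < 0.5 || fog_dur_range[2L] > 40.5 ||
      fog_dur_range[1L] > fog_dur_range[2L])
    stop("fog_dur_range must lie within [0.5, 40.5] s")
  if (fog_amp_scale <= 0 || fog_amp_scale >= 1)
    stop("fog_amp_scale must lie in (0, 1)")
  if (stand_fraction < 0 || stand_fraction >= 1)
    stop("stand_fraction must lie in [0, 1)")
  if (any(c(gait_amp, harmonic_ratio, noise_std) < 0))
    stop("amplitudes must be nonnegative")
  spec
}

# Centered moving average with edge padding: turns the 0/1 regime masks
# into 0.25 s cross-fades so regime changes are not step discontinuities
# the classifier could key on.
smooth_mask <- function(w, k) {
  if (k <= 1L) return(w)
  n <- length(w)
  padded <- c(rep(w[1L], k), w, rep(w[n], k))
  cs <- cumsum(padded)
  win <- 2L * (k %/% 2L) + 1L
  sm <- (cs[(win):(length(cs))] - c(0, cs[1:(length(cs) - win)])) / win
  sm[(k + 1L - k %/% 2L):(k + n - k %/% 2L)]
}

# Lay blocks (standing + FoG) sequentially inside the task interval with
# random gait gaps between them (stick-breaking on the leftover time).
place_blocks <- function(task_start, task_end, durations) {
  task <- task_end - task_start
  slack <- task - sum(durations)
  if (slack < 0.1 * task)
    stop("cannot fit ", length(durations), " blocks totalling ",
         round(sum(durations), 1), " s into a ", round(task, 1),
         " s task; use shorter episode durations or a longer recording")
  ngap <- length(durations) + 1L
  gaps <- slack * diff(sort(c(0, stats::runif(ngap - 1L), 1)))
  starts <- numeric(length(durations))
  pos <- task_start
  for (i in seq_along(durations)) {
    pos <- pos + gaps[i]
    starts[i] <- pos
    pos <- pos + durations[i]
  }
  starts
}

#' Simulate one subject's recording
#'
#' Builds a 9-channel recording in the DAPHNet dialect. Gait segments are
#' gravity plus stride/stance sinusoids (both riding the vertical axis so
#' the acceleration magnitude carries them at first order, with smaller
#' cross-talk copies on the horizontal axes) plus white noise; FoG segments
#' replace the gait sinusoids with 2-3 seeded trembling components in the
#' freezing band at `fog_amp_scale` of the gait amplitude; standing
#' segments are gravity plus noise only. Regimes cross-fade over 0.25 s.
#' Annotation is 2 during FoG, 1 during gait and standing within the task,
#' 0 in the lead-in/lead-out margins. Thigh and trunk channels are
#' attenuated copies of the ankle with independent noise (format
#' completeness; only the ankle drives analysis).
#'
#' @param spec a [sim_spec()].
#' @return A `fog_recording` with attributes `regimes` (data frame of
#'   `start_s`, `end_s`, `regime`) and `spec`.
#' @export
simulate_subject <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  fs <- spec$fs_hz
  n <- round(spec$duration_s * fs)
  t <- (0:(n - 1)) / fs
  task_start <- spec$margin_s
  task_end <- spec$duration_s - spec$margin_s
  if (task_end - task_start < 10)
    stop("task interval too short; increase duration_s")

  fog_dur <- if (spec$fog_episodes > 0)
    stats::runif(spec$fog_episodes, spec$fog_dur_range[1L],
                 spec$fog_dur_range[2L])
  else numeric(0)
  n_stand <- if (spec$stand_fraction > 0) 2L else 0L
  stand_dur <- rep(spec$stand_fraction * (task_end - task_start) /
                     max(n_stand, 1L), n_stand)
  durs <- c(fog_dur, stand_dur)
  kinds <- c(rep("fog", length(fog_dur)), rep("stand", length(stand_dur)))
  if (length(durs)) {
    ord <- sample(length(durs))
    durs <- durs[ord]; kinds <- kinds[ord]
    starts <- place_blocks(task_start, task_end, durs)
  } else starts <- numeric(0)

  regime <- rep("gait", n)
  regime[t < task_start | t >= task_end] <- "margin"
  for (i in seq_along(starts))
    regime[t >= starts[i] & t < starts[i] + durs[i]] <- kinds[i]

  ramp <- round(0.25 * fs)
  w_gait <- smooth_mask(as.numeric(regime == "gait"), ramp)
  w_fog <- smooth_mask(as.numeric(regime == "fog"), ramp)

  ph <- stats::runif(4, 0, 2 * pi)
  gait_v <- spec$gait_amp * sin(2 * pi * spec$stride_hz * t + ph[1L]) +
    spec$harmonic_ratio * spec$gait_amp *
      sin(2 * pi * spec$stance_hz * t + ph[2L])
  gait_h <- 0.3 * spec$gait_amp * sin(2 * pi * spec$stride_hz * t + ph[3L])

  ncomp <- sample(2:3, 1L)
  fog_f <- stats::runif(ncomp, spec$fog_band[1L], spec$fog_band[2L])
  fog_ph <- stats::runif(ncomp, 0, 2 * pi)
  fog_a <- spec$fog_amp_scale * spec$gait_amp / ncomp
  fog_v <- rowSums(vapply(seq_len(ncomp), function(j)
    fog_a * sin(2 * pi * fog_f[j] * t + fog_ph[j]), numeric(n)))
  fog_h <- 0.3 * fog_v

  noise <- function() stats::rnorm(n, 0, spec$noise_std)
  az <- spec$gravity_g + w_gait * gait_v + w_fog * fog_v + noise()
  ax <- w_gait * gait_h + w_fog * fog_h + noise()
  ay <- 0.5 * w_gait * gait_h + noise()

  ankle <- cbind(ax, ay, az) * 1000
  thigh <- 0.6 * ankle + matrix(stats::rnorm(3 * n, 0,
                                             spec$noise_std * 500), n, 3)
  trunk <- 0.3 * ankle + matrix(stats::rnorm(3 * n, 0,
                                             spec$noise_std * 500), n, 3)
  accel <- round(cbind(ankle, thigh, trunk))

  ann <- integer(n) + 1L
  ann[regime == "margin"] <- 0L
  ann[regime == "fog"] <- 2L

  rec <- fog_recording(time_ms = floor(t * 1000), accel_mg = accel,
                       annotation = ann,
                       subject_id = sprintf("sim%03d", spec$seed %% 1000L),
                       sample_rate_hz = fs)
  r <- rle(regime)
  ends <- cumsum(r$lengths)
  attr(rec, "regimes") <- data.frame(
    start_s = c(0, ends[-length(ends)]) / fs, end_s = ends / fs,
    regime = r$values)
  attr(rec, "spec") <- spec
  rec
}

#' Simulate a multi-subject cohort
#'
#' Draws per-subject parameter jitter (stride frequency, amplitudes,
#' harmonic ratio) around a base specification and gives every subject its
#' own derived seed. A stated fraction of subjects can be made FoG-free,
#' mirroring cohorts where not every patient freezes.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param base_spec a [sim_spec()] the cohort varies around.
#' @param jitter relative perturbation half-width (default 0.1: each
#'   jittered parameter is scaled by a factor in \[0.9, 1.1\]).
#' @param seed cohort seed; subject i uses `seed * 1000 + i`.
#' @param fog_free_fraction fraction of subjects (rounded) simulated with
#'   zero FoG episodes; these are the last subjects in the list.
#' @return list of `fog_recording` objects with subject ids `"S01"`, ...
#' @export
simulate_cohort <- function(n_subjects, base_spec = sim_spec(),
                            jitter = 0.1, seed = 1L,
                            fog_free_fraction = 0) {
  stopifnot(n_subjects >= 1L)
  n_free <- round(fog_free_fraction * n_subjects)
  set.seed(seed)
  jit <- function(x) x * stats::runif(1L, 1 - jitter, 1 + jitter)
  lapply(seq_len(n_subjects), function(i) {
    sp <- base_spec
    sp$stride_hz <- jit(sp$stride_hz)
    sp$stance_hz <- 2 * sp$stride_hz
    sp$gait_amp <- jit(sp$gait_amp)
    sp$harmonic_ratio <- min(jit(sp$harmonic_ratio), 0.95)
    sp$fog_amp_scale <- min(max(jit(sp$fog_amp_scale), 0.05), 0.95)
    if (i > n_subjects - n_free) sp$fog_episodes <- 0L
    sp$seed <- seed * 1000L + i
    rec <- simulate_subject(sp)
    rec$subject_id <- sprintf("S%02d", i)
    rec
  })
}

#' Ground-truth episode table of a simulated recording
#'
#' @param rec a recording from [simulate_subject()].
#' @return data frame of FoG episodes (`subject`, `start_s`, `end_s`).
#' @export
episode_table <- function(rec) {
  reg <- attr(rec, "regimes")
  if (is.null(reg)) stop("recording carries no regime ground truth")
  fog <- reg[reg$regime == "fog", , drop = FALSE]
  data.frame(subject = rec$subject_id, start_s = fog$start_s,
             end_s = fog$end_s, row.names = NULL)
}

#' Check the spectral signatures of a simulated recording
#'
#' Reports, per regime, whether the generated signal shows the structure
#' the detector assumes: every pure gait window's highest spectral peak in
#' the 0.5-3 Hz locomotion band; at least 80 % of FoG windows peaking in
#' the 3-8 Hz freezing band; standing total power below 10 % of gait total
#' power. Windows are 4 s slices lying entirely inside one regime segment
#' (shrunk by the 0.25 s cross-fade). Failed expectations are reported in
#' the returned checks, not raised; regimes absent from the recording are
#' flagged `NA`.
#'
#' @param rec a `fog_recording`.
#' @param regimes regime table; defaults to the simulator's ground truth
#'   attribute.
#' @param window_s,step_s window geometry (defaults 4 and 0.5 s).
#' @return list with per-regime window counts, `gait_peak_frac`,
#'   `fog_peak_frac`, `stand_gait_power_ratio`, and a logical `checks`
#'   vector (`gait`, `fog`, `standing`; `NA` where a regime is missing).
#' @export
spectral_validate <- function(rec, regimes = attr(rec, "regimes"),
                              window_s = 4, step_s = 0.5) {
  if (is.null(regimes)) stop("no regime table available")
  fs <- rec$sample_rate_hz
  l <- samples_or_stop(window_s, fs, "window length")
  s <- samples_or_stop(step_s, fs, "step")
  mag <- magnitude(rec)
  pad <- 0.3                      # skip the cross-fade edges
  pure_windows <- function(kind) {
    seg <- regimes[regimes$regime == kind, , drop = FALSE]
    out <- list()
    for (i in seq_len(nrow(seg))) {
      a <- ceiling((seg$start_s[i] + pad) * fs)
      b <- floor((seg$end_s[i] - pad) * fs)
      for (st in window_starts(b - a + 1L, l, s))
        out[[length(out) + 1L]] <- mag[(a + st + 1L):(a + st + l)]
    }
    out
  }
  peak_fracs <- function(wins, band) {
    if (!length(wins)) return(NA_real_)
    hits <- vapply(wins, function(w) {
      f <- spectral_peaks(w, fs)[["hfp_hz"]]
      f >= band[1L] && f <= band[2L]
    }, logical(1))
    mean(hits)
  }
  mean_power <- function(wins) {
    if (!length(wins)) return(NA_real_)
    mean(vapply(wins, function(w) band_power(w, c(0.25, fs / 2 - 1e-9), fs),
                numeric(1)))
  }
  gw <- pure_windows("gait"); fw <- pure_windows("fog")
  sw <- pure_windows("stand")
  gait_frac <- peak_fracs(gw, LOCO_BAND)
  fog_frac <- peak_fracs(fw, FREEZE_BAND)
  ratio <- mean_power(sw) / mean_power(gw)
  list(n_windows = c(gait = length(gw), fog = length(fw),
                     stand = length(sw)),
       gait_peak_frac = gait_frac, fog_peak_frac = fog_frac,
       stand_gait_power_ratio = ratio,
       checks = c(gait = if (is.na(gait_frac)) NA else gait_frac == 1,
                  fog = if (is.na(fog_frac)) NA else fog_frac >= 0.8,
                  standing = if (is.na(ratio)) NA else ratio < 0.1))
}
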