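# DAPHNet-dialect I/O and the core recording container.

DAPHNET_NCOL <- 11L
CHANNEL_NAMES <- c("ankle_x", "ankle_y", "ankle_z",
                   "thigh_x", "thigh_y", "thigh_z",
                   "trunk_x", "trunk_y", "trunk_z")

#' Construct a gait recording
#'
#' A recording holds timestamped 9-channel accelerometry (milli-g) plus a
#' per-sample annotation: 0 for non-experimental periods, 1 for movement
#' without freezing, 2 for movement with freezing of gait (FoG). Channel
#' order is ankle(x,y,z), thigh(x,y,z), trunk(x,y,z).
#'
#' @param time_ms strictly increasing integer timestamps in milliseconds.
#' @param accel_mg numeric matrix, N samples x 9 channels, in milli-g.
#' @param annotation integer vector of length N with values in {0, 1, 2}.
#' @param subject_id subject identifier string.
#' @param sample_rate_hz sampling rate in Hz (64 for DAPHNet and the
#'   simulator).
#' @return An object of class `fog_recording`.
#' @export
fog_recording <- function(time_ms, accel_mg, annotation,
                          subject_id = "S01", sample_rate_hz = 64) {
  accel_mg <- as.matrix(accel_mg)
  if (length(accel_mg) == 0L) accel_mg <- matrix(numeric(0), 0L, DAPHNET_NCOL - 2L)
  colnames(accel_mg) <- CHANNEL_NAMES
  rec <- structure(
    list(subject_id = as.character(subject_id),
         sample_rate_hz = as.numeric(sample_rate_hz),
         time_ms = as.numeric(time_ms),
         accel_mg = accel_mg,
         annotation = as.integer(annotation)),
    class = "fog_recording")
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  n <- length(rec$time_ms)
  if (nrow(rec$accel_mg) != n || length(rec$annotation) != n)
    stop("recording fields have inconsistent lengths (time: ", n,
         ", accel: ", nrow(rec$accel_mg), ", annotation: ",
         length(rec$annotation), ")")
  if (ncol(rec$accel_mg) != DAPHNET_NCOL - 2L)
    stop("accel_mg must have 9 channels, got ", ncol(rec$accel_mg))
  if (n > 1L && any(diff(rec$time_ms) <= 0))
    stop("time_ms must be strictly increasing")
  bad <- which(!(rec$annotation %in% c(0L, 1L, 2L)))
  if (length(bad))
    stop("annotation values must be 0, 1 or 2; first offending sample: ",
         bad[1L], " (value ", rec$annotation[bad[1L]], ")")
  if (!is.finite(rec$sample_rate_hz) || rec$sample_rate_hz <= 0)
    stop("sample_rate_hz must be positive")
  invisible(rec)
}

#' @export
print.fog_recording <- function(x, ...) {
  n <- length(x$time_ms)
  dur <- if (n) (x$time_ms[n] - x$time_ms[1L]) / 1000 else 0
  cat("<fog_recording> subject ", x$subject_id, ": ", n, " samples at ",
      x$sample_rate_hz, " Hz (", round(dur, 1), " s)\n", sep = "")
  if (n) {
    tab <- table(factor(x$annotation, levels = 0:2))
    cat("  annotation 0/1/2: ", paste(tab, collapse = " / "), "\n", sep = "")
  }
  invisible(x)
}

#' Number of samples in a recording
#' @param rec a `fog_recording`.
#' @return integer sample count.
#' @export
n_samples <- function(rec) length(rec$time_ms)

#' Read a DAPHNet-format recording
#'
#' Parses the plain-text dialect of the DAPHNet freezing-of-gait dataset:
#' one sample per line, 11 whitespace-separated numeric fields (timestamp in
#' ms, nine acceleration channels in milli-g, annotation in {0,1,2}).
#' Blank lines and lines starting with `#` are skipped.
#'
#' @param path file to read.
#' @param subject_id subject label to attach; defaults to the file name
#'   without extension.
#' @param sample_rate_hz sampling rate of the file (64 Hz for DAPHNet).
#' @return A [fog_recording()].
#' @export
read_daphnet <- function(path, subject_id = NULL, sample_rate_hz = 64) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (!length(keep))
    return(fog_recording(numeric(0), matrix(numeric(0), 0, 9), integer(0),
                         subject_id, sample_rate_hz))
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  nf <- lengths(fields)
  if (any(nf != DAPHNET_NCOL))
    stop("parse error at line ", keep[which(nf != DAPHNET_NCOL)[1L]],
         ": expected ", DAPHNET_NCOL, " fields, found ",
         nf[which(nf != DAPHNET_NCOL)[1L]])
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = DAPHNET_NCOL, byrow = TRUE)
  if (anyNA(m)) {
    badrow <- which(apply(m, 1L, anyNA))[1L]
    stop("parse error at line ", keep[badrow], ": non-numeric field")
  }
  fog_recording(time_ms = m[, 1L], accel_mg = m[, 2:10, drop = FALSE],
                annotation = m[, 11L], subject_id = subject_id,
                sample_rate_hz = sample_rate_hz)
}

#' Write a recording in DAPHNet format
#'
#' Inverse of [read_daphnet()]: single-space-separated fields, one sample per
#' line, no header. Numeric fields are written so that a read-back reproduces
#' them exactly.
#'
#' @param rec a `fog_recording`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_daphnet <- function(rec, path) {
  validate_recording(rec)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  if (n_samples(rec) > 0L) {
    m <- cbind(rec$time_ms, rec$accel_mg, rec$annotation)
    writeLines(apply(format(m, trim = TRUE, scientific = FALSE,
                            digits = 15), 1L, paste, collapse = " "), con)
  }
  invisible(path)
}

#' Convert raw ADC counts to acceleration in g
#'
#' The acquisition front end samples each axis with a 16-bit ADC over a
#' +/-4 g full-scale range, i.e. 8192 counts per g. Values beyond full scale
#' saturate at +/-4 g rather than erroring.
#'
#' @param raw integer ADC counts (vectorized).
#' @return acceleration in g, clamped to \[-4, 4\].
#' @export
counts_to_g <- function(raw) {
  pmax(pmin(raw / 8192, 4), -4)
}

#' Split a recording into contiguous blocks
#'
#' The timestamp column is used for gap detection only: a gap of more than
#' two sample periods splits the recording into independent contiguous
#' blocks, so that no analysis window ever straddles a recording dropout.
#' No resampling is performed.
#'
#' @param rec a `fog_recording`.
#' @return list of `fog_recording` blocks (a single-element list when the
#'   recording is gap-free).
#' @export
split_contiguous <- function(rec) {
  n <- n_samples(rec)
  if (n <= 1L) return(list(rec))
  period_ms <- 1000 / rec$sample_rate_hz
  breaks <- which(diff(rec$time_ms) > 2 * period_ms)
  if (!length(breaks)) return(list(rec))
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n)
  lapply(seq_along(starts), function(i) {
    idx <- starts[i]:ends[i]
    fog_recording(rec$time_ms[idx], rec$accel_mg[idx, , drop = FALSE],
                  rec$annotation[idx], rec$subject_id, rec$sample_rate_hz)
  })
}
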