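# Zero-phase filtering and resampling.

#' Zero-phase band-pass filter
#'
#' Butterworth high-pass and low-pass applied forward-backward
#' (`signal::filtfilt`), giving zero phase distortion and doubled rolloff.
#' The default band is 0.1–40 Hz.
#'
#' @param rec A [new_recording()] object (or a numeric matrix/vector with
#'   `sample_rate` given).
#' @param low_hz,high_hz Band edges in Hz; `0 < low < high < Nyquist`.
#' @param sample_rate Required when `rec` is not a recording.
#' @return Filtered object of the same type.
#' @export
bandpass_filter <- function(rec, low_hz = 0.1, high_hz = 40,
                            sample_rate = NULL) {
  is_rec <- inherits(rec, "ContinuousRecording")
  sr <- if (is_rec) rec$sample_rate else sample_rate
  if (is.null(sr)) stop("sample_rate required for matrix input")
  nyq <- sr / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("invalid band: need 0 < low < high < Nyquist (", nyq, " Hz)")
  hp <- signal::butter(2, low_hz / nyq, type = "high")
  lp <- signal::butter(4, high_hz / nyq, type = "low")
  x <- if (is_rec) rec$data else rbind(rec)
  # demean first: a large DC step at the record edges excites long filter
  # transients at a 0.1-Hz cutoff
  out <- t(apply(x, 1L, function(ch)
    signal::filtfilt(lp, signal::filtfilt(hp, ch - mean(ch)))))
  if (is_rec) { rec$data <- out; rownames(rec$data) <- rec$channel_names; rec }
  else if (is.matrix(rec)) out else drop(out)
}

#' Zero-phase high-pass filter
#'
#' @inheritParams bandpass_filter
#' @param cutoff_hz High-pass edge in Hz.
#' @export
highpass_filter <- function(rec, cutoff_hz = 1, sample_rate = NULL) {
  is_rec <- inherits(rec, "ContinuousRecording")
  sr <- if (is_rec) rec$sample_rate else sample_rate
  if (is.null(sr)) stop("sample_rate required for matrix input")
  if (cutoff_hz <= 0 || cutoff_hz >= sr / 2) stop("invalid cutoff")
  hp <- signal::butter(2, cutoff_hz / (sr / 2), type = "high")
  x <- if (is_rec) rec$data else rbind(rec)
  out <- t(apply(x, 1L, function(ch) signal::filtfilt(hp, ch)))
  if (is_rec) { rec$data <- out; rownames(rec$data) <- rec$channel_names; rec }
  else if (is.matrix(rec)) out else drop(out)
}

# integer-factor decimation with an 8th-order zero-phase anti-alias low-pass
.decimate <- function(x, factor) {
  if (factor == 1L) return(x)
  lp <- signal::butter(4, 0.8 / factor, type = "low")
  if (is.matrix(x)) {
    y <- t(apply(x, 1L, function(ch) signal::filtfilt(lp, ch)))
    y[, seq(1L, ncol(y), by = factor), drop = FALSE]
  } else {
    y <- signal::filtfilt(lp, x)
    y[seq(1L, length(y), by = factor)]
  }
}

#' Downsample a recording by an integer factor
#'
#' @param rec A [new_recording()] object.
#' @param to Target rate (Hz); must divide the current rate.
#' @return Recording at the new rate (telemetry/triggers resampled).
#' @export
downsample_recording <- function(rec, to = 250) {
  stopifnot(inherits(rec, "ContinuousRecording"))
  fac <- rec$sample_rate / to
  if (fac != round(fac)) stop("target rate must divide the current rate")
  fac <- as.integer(fac)
  data <- .decimate(rec$data, fac)
  tel <- rec$telemetry
  if (!is.null(tel)) tel <- tel[seq(1L, nrow(tel), by = fac), , drop = FALSE]
  out <- new_recording(data, to, rec$channel_names, telemetry = tel)
  if (!is.null(rec$trigger_samples)) {
    trg <- rec$trigger_samples
    trg$sample <- trg$sample %/% fac
    out$trigger_samples <- trg
  }
  out
}
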