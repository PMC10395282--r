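#' Continuous multichannel EEG recording
#'
#' Container for a continuous EEG recording with optional sample-aligned
#' driving telemetry and known-position trigger points. Data are stored as a
#' channels x samples matrix in microvolts; sample indices are 0-based,
#' onsets in seconds, track distances in meters.
#'
#' @param data Numeric matrix, channels x samples (microvolts).
#' @param sample_rate Sampling rate in Hz.
#' @param channel_names Character vector, one unique label per row of `data`.
#' @param telemetry Optional data.frame with one row per EEG sample
#'   (columns `velocity_kmh`, `steering_deg`, optionally `extrapolated`).
#' @param trigger_samples Optional data.frame with columns `sample`
#'   (0-based EEG sample index, strictly increasing) and `distance_m`.
#' @return An object of class `ContinuousRecording`.
#' @export
new_recording <- function(data, sample_rate, channel_names,
                          telemetry = NULL, trigger_samples = NULL) {
  if (!is.matrix(data)) data <- rbind(data)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a single positive number")
  if (length(channel_names) != nrow(data))
    stop("channel_names length (", length(channel_names),
         ") does not match data rows (", nrow(data), ")")
  if (anyDuplicated(channel_names))
    stop("channel_names must be unique")
  rownames(data) <- channel_names
  if (!is.null(telemetry)) {
    if (nrow(telemetry) != ncol(data))
      stop("telemetry must have one row per EEG sample (",
           nrow(telemetry), " vs ", ncol(data), ")")
  }
  if (!is.null(trigger_samples)) {
    stopifnot(all(c("sample", "distance_m") %in% names(trigger_samples)))
    if (is.unsorted(trigger_samples$sample, strictly = TRUE))
      stop("trigger samples must be strictly increasing")
    if (any(trigger_samples$sample < 0 | trigger_samples$sample >= ncol(data)))
      stop("trigger samples outside recording")
  }
  structure(list(data = data, sample_rate = sample_rate,
                 channel_names = channel_names, telemetry = telemetry,
                 trigger_samples = trigger_samples),
            class = "ContinuousRecording")
}

#' @export
print.ContinuousRecording <- function(x, ...) {
  cat(sprintf("<ContinuousRecording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sample_rate,
              ncol(x$data) / x$sample_rate))
  if (!is.null(x$telemetry)) cat("  telemetry: aligned velocity/steering\n")
  if (!is.null(x$trigger_samples))
    cat(sprintf("  triggers: %d known-position points\n",
                nrow(x$trigger_samples)))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)

#' Attach low-rate telemetry to a recording
#'
#' Driving telemetry is transcribed at 100 Hz while the EEG runs at 500 Hz;
#' this aligns the two by linear interpolation onto the EEG sample grid.
#' Samples outside the telemetry span are filled with the edge value and
#' flagged in the `extrapolated` column.
#'
#' @param rec A [new_recording()] object.
#' @param telemetry data.frame with columns `time_s`, `velocity_kmh`,
#'   `steering_deg` (native telemetry rate, typically 100 Hz).
#' @param trigger_table Optional data.frame with columns `time_s` and
#'   `distance_m`: known-position trigger points, converted to EEG sample
#'   indices.
#' @return The recording with `$telemetry` (and `$trigger_samples`) set.
#' @export
attach_telemetry <- function(rec, telemetry, trigger_table = NULL) {
  stopifnot(inherits(rec, "ContinuousRecording"))
  if (is.null(telemetry) || nrow(telemetry) == 0L)
    stop("telemetry is empty")
  stopifnot(all(c("time_s", "velocity_kmh", "steering_deg") %in% names(telemetry)))
  t_eeg <- (seq_len(n_samples(rec)) - 1L) / rec$sample_rate
  if (min(telemetry$time_s) > max(t_eeg) || max(telemetry$time_s) < 0)
    stop("telemetry timeline does not overlap the recording")
  v <- approx(telemetry$time_s, telemetry$velocity_kmh, t_eeg, rule = 2)$y
  s <- approx(telemetry$time_s, telemetry$steering_deg, t_eeg, rule = 2)$y
  outside <- t_eeg < min(telemetry$time_s) | t_eeg > max(telemetry$time_s)
  rec$telemetry <- data.frame(velocity_kmh = v, steering_deg = s,
                              extrapolated = outside)
  if (!is.null(trigger_table)) {
    stopifnot(all(c("time_s", "distance_m") %in% names(trigger_table)))
    smp <- round(trigger_table$time_s * rec$sample_rate)
    keep <- smp >= 0 & smp < n_samples(rec)
    rec$trigger_samples <- data.frame(sample = smp[keep],
                                      distance_m = trigger_table$distance_m[keep])
  }
  rec
}

#' Ocular event table constructor
#'
#' Events are stored as a data.frame, one row per blink, saccade onset or
#' fixation onset. Blink rows carry `direction = "none"`; saccade and
#' fixation rows carry a left/right direction and an inward/outward type
#' once labelled.
#'
#' @param sample 0-based EEG sample indices.
#' @param kind One of `"blink"`, `"saccade_onset"`, `"fixation_onset"`.
#' @param direction `"left"`, `"right"` or `"none"`.
#' @param sacc_type `"outward"`, `"inward"` or `"none"`.
#' @param quality Fit R^2 or template correlation in `[0, 1]`.
#' @param load Optional task-load label (`"low"`, `"medium"`, `"high"` or NA).
#' @return data.frame of class `ocular_events`.
#' @export
ocular_events <- function(sample, kind, direction = "none",
                          sacc_type = "none", quality = NA_real_,
                          load = NA_character_) {
  kinds <- c("blink", "saccade_onset", "fixation_onset")
  if (!all(kind %in% kinds))
    stop("kind must be one of: ", paste(kinds, collapse = ", "))
  n <- length(sample)
  kind <- rep_len(kind, n); direction <- rep_len(direction, n)
  sacc_type <- rep_len(sacc_type, n); quality <- rep_len(quality, n)
  load <- rep_len(load, n)
  df <- data.frame(sample = as.integer(sample), kind = kind,
                   direction = direction, sacc_type = sacc_type,
                   quality = quality, load = load,
                   stringsAsFactors = FALSE)
  df <- df[order(df$sample), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("ocular_events", "data.frame")
  df
}
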