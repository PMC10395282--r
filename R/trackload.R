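# Track position reconstruction, 10-m segmentation, wavelet band power and
# task-load terciles, and per-load behavioral summaries.

#' Reconstruct track position from velocity and trigger points
#'
#' Velocity (km/h) is integrated (trapezoid rule) into raw distance; because
#' low-rate transcription biases the integral, the raw distances are morphed
#' piecewise-linearly so that the reconstructed distance at every trigger
#' sample equals its known distance exactly. Before the first and after the
#' last trigger the nearest interval's scaling is extended.
#'
#' @param velocity Velocity trace in km/h, one value per EEG sample.
#' @param sample_rate Hz.
#' @param trigger_samples data.frame with `sample` (0-based) and
#'   `distance_m`, at least 2 rows, distances strictly increasing.
#' @return Numeric vector: distance (m) at every sample, monotone
#'   non-decreasing.
#' @export
reconstruct_position <- function(velocity, sample_rate, trigger_samples) {
  if (nrow(trigger_samples) < 2) stop("need at least 2 trigger points")
  if (is.unsorted(trigger_samples$distance_m, strictly = TRUE))
    stop("trigger distances must be strictly increasing")
  v_ms <- velocity / 3.6
  raw <- cumsum((v_ms + c(v_ms[1], v_ms[-length(v_ms)])) / 2) / sample_rate
  idx <- trigger_samples$sample + 1L
  known <- trigger_samples$distance_m
  d <- raw
  n_tr <- length(idx)
  scale1 <- (known[2] - known[1]) / (raw[idx[2]] - raw[idx[1]])
  d[1:idx[1]] <- known[1] - (raw[idx[1]] - raw[1:idx[1]]) * scale1
  for (k in seq_len(n_tr - 1)) {
    span <- idx[k]:idx[k + 1]
    sc <- (known[k + 1] - known[k]) / (raw[idx[k + 1]] - raw[idx[k]])
    d[span] <- known[k] + (raw[span] - raw[idx[k]]) * sc
  }
  last <- idx[n_tr]
  if (last < length(raw)) {
    scn <- (known[n_tr] - known[n_tr - 1]) /
      (raw[idx[n_tr]] - raw[idx[n_tr - 1]])
    span <- last:length(raw)
    d[span] <- known[n_tr] + (raw[span] - raw[last]) * scn
  }
  cummax(pmax(d, 0))
}

#' Cut the track into fixed-length spatial segments
#'
#' Half-open 10-m bins `[i*len, (i+1)*len)` covering `[0, max_distance)`;
#' each sample of the distance trace is assigned to exactly one segment.
#'
#' @param distance Distance trace (m per sample).
#' @param seg_len Segment length (m), default 10.
#' @param max_distance Analyzed track length (m); defaults to the final
#'   distance. A 50-km drive yields 5000 segments.
#' @return data.frame of class `track_segments`: `segment` (0-based),
#'   `start_m`, `end_m`, `first_sample`, `last_sample` (0-based, -1 if the
#'   segment contains no sample), `n_samples`.
#' @export
segment_track <- function(distance, seg_len = 10,
                          max_distance = max(distance)) {
  if (seg_len <= 0) stop("seg_len must be positive")
  n_seg <- floor(max_distance / seg_len)
  if (n_seg < 1) {
    warning("track shorter than one segment")
    return(structure(data.frame(segment = integer(0), start_m = numeric(0),
                                end_m = numeric(0), first_sample = integer(0),
                                last_sample = integer(0),
                                n_samples = integer(0)),
                     class = c("track_segments", "data.frame")))
  }
  bin <- floor(distance / seg_len)
  inside <- bin >= 0 & bin < n_seg
  first <- rep(-1L, n_seg); last <- rep(-1L, n_seg); cnt <- integer(n_seg)
  tab <- which(inside)
  if (length(tab)) {
    b <- bin[tab] + 1L
    first_idx <- tapply(tab, b, min)
    last_idx <- tapply(tab, b, max)
    counts <- tapply(tab, b, length)
    ii <- as.integer(names(first_idx))
    first[ii] <- as.integer(first_idx) - 1L
    last[ii] <- as.integer(last_idx) - 1L
    cnt[ii] <- as.integer(counts)
  }
  structure(data.frame(segment = seq_len(n_seg) - 1L,
                       start_m = (seq_len(n_seg) - 1) * seg_len,
                       end_m = seq_len(n_seg) * seg_len,
                       first_sample = first, last_sample = last,
                       n_samples = cnt),
            class = c("track_segments", "data.frame"))
}

#' Continuous Morlet wavelet power
#'
#' Complex Morlet convolution (FFT-based) on a linear frequency grid,
#' default 2–30 Hz in 29 steps, with the number of cycles increasing
#' linearly from 3 (lowest) to 8 (highest frequency). Returns power
#' (amplitude squared). Samples within 3 temporal SDs of either edge are
#' reported in the `edge_samples` attribute.
#'
#' @param rec A [new_recording()] object (or matrix + `sample_rate`).
#' @param f_min,f_max,n_freqs Frequency grid.
#' @param cycles Length-2: cycles at `f_min` and `f_max`.
#' @param channels Optional subset of channels.
#' @param sample_rate Required for matrix input.
#' @param downsample Integer power-of-two factor: the power traces are
#'   returned on every `downsample`-th sample. Because the Morlet kernels
#'   are band-limited well below `sample_rate / (2 * downsample)`, the
#'   decimation is exact (performed in the frequency domain); factors up to
#'   8 at 500 Hz keep all content below 62.5 Hz.
#' @return 3-D array channels x freqs x time with dimnames, attributes
#'   `freqs`, `edge_samples` (per frequency, on the output grid) and
#'   `sample_rate` (output rate).
#' @export
cwt_power <- function(rec, f_min = 2, f_max = 30, n_freqs = 29,
                      cycles = c(3, 8), channels = NULL,
                      sample_rate = NULL, downsample = 1L) {
  is_rec <- inherits(rec, "ContinuousRecording")
  sr <- if (is_rec) rec$sample_rate else sample_rate
  if (is.null(sr)) stop("sample_rate required for matrix input")
  x <- if (is_rec) rec$data else rbind(rec)
  if (!is.null(channels)) {
    miss <- setdiff(channels, rownames(x))
    if (length(miss)) stop("missing channel(s): ", paste(miss, collapse = ", "))
    x <- x[channels, , drop = FALSE]
  }
  n <- ncol(x)
  freqs <- seq(f_min, f_max, length.out = n_freqs)
  if (n < 3 * sr / f_min)
    stop("recording shorter than 3 cycles of the lowest frequency")
  cyc <- seq(cycles[1], cycles[2], length.out = n_freqs)
  fac <- as.integer(downsample)
  if (fac < 1 || bitwAnd(fac, fac - 1L) != 0L)
    stop("downsample must be a power of two")
  sigma_f <- freqs / cyc
  # the analytic (one-sided) spectrum must fit below the folded band edge
  if (fac > 1 && sr / fac < max(freqs + 4 * sigma_f) * 1.1)
    stop("downsample factor too large for the frequency grid")
  out <- .cwt_core(x, sr, freqs, cyc, fac)
  attr(out, "freqs") <- freqs
  attr(out, "edge_samples") <- ceiling(3 * cyc / (2 * pi * freqs) * sr / fac)
  attr(out, "sample_rate") <- sr / fac
  out
}

.cwt_core <- function(x, sr, freqs, cyc, fac = 1L) {
  n <- ncol(x)
  sigma_f <- freqs / cyc
  nf <- nextn(n + round(sr), 2)
  fgrid <- (seq_len(nf) - 1) / nf * sr
  fgrid[fgrid > sr / 2] <- fgrid[fgrid > sr / 2] - sr
  n_out <- length(seq(1L, n, by = fac))
  nk <- if (fac == 1L) nf else nf %/% fac
  out <- array(0, dim = c(nrow(x), length(freqs), n_out),
               dimnames = list(rownames(x), NULL, NULL))
  # frequency-domain Gaussians of analytic Morlet wavelets, shared across
  # channels; only the retained (positive-frequency) band is needed
  Hs <- lapply(seq_along(freqs), function(j)
    exp(-(fgrid[seq_len(nk)] - freqs[j])^2 / (2 * sigma_f[j]^2)) * 2)
  for (k in seq_len(nrow(x))) {
    X <- fft(c(x[k, ], numeric(nf - n)))[seq_len(nk)]
    for (j in seq_along(freqs)) {
      conv <- fft(X * Hs[[j]], inverse = TRUE) / nf
      out[k, j, ] <- Mod(conv[seq_len(n_out)])^2
    }
  }
  out
}

#' Z-transform power traces over time
#'
#' Each channel x frequency trace is standardized to mean 0 and SD 1 over
#' the entire recording.
#'
#' @param power Array from [cwt_power()].
#' @return Array of the same shape (attributes preserved).
#' @export
zscore_trace <- function(power) {
  d <- dim(power)
  flat <- matrix(power, nrow = d[1] * d[2])  # (ch*freq) x time
  m <- rowMeans(flat)
  s <- sqrt(rowSums((flat - m)^2) / (d[3] - 1))
  if (any(s < 1e-300)) {
    bad <- which(s < 1e-300)[1]
    ch <- (bad - 1) %% d[1] + 1
    fq <- (bad - 1) %/% d[1] + 1
    stop("zero-variance power trace at channel ",
         dimnames(power)[[1]][ch] %||% ch, ", frequency bin ", fq)
  }
  out <- array((flat - m) / s, dim = d)
  attributes(out) <- attributes(power)
  out
}

#' Average z-power per segment and smooth along the track
#'
#' Per-segment mean over the segment's sample span, then a centered moving
#' average over ±`smooth_segments` segments (default ±5, i.e. ±50 m),
#' shrinking symmetrically at the track edges. Segments without samples get
#' NaN and are excluded downstream.
#'
#' @param zpower Array from [zscore_trace()].
#' @param segments [segment_track()] output **on the same sample grid**.
#' @param smooth_segments Half-width of the moving average (segments).
#' @return Array channels x freqs x segments.
#' @export
segment_average_and_smooth <- function(zpower, segments,
                                       smooth_segments = 5) {
  d <- dim(zpower)
  n_seg <- nrow(segments)
  # flatten to (time) x (channel*freq) and use grouped row sums
  flat <- matrix(zpower, nrow = d[1] * d[2])  # (ch*freq) x time
  seg_idx <- rep(NA_integer_, d[3])
  for (s in which(segments$n_samples > 0))
    seg_idx[(segments$first_sample[s]:segments$last_sample[s]) + 1L] <- s
  use <- !is.na(seg_idx)
  sums <- rowsum(t(flat[, use, drop = FALSE]), seg_idx[use])  # seg x (ch*freq)
  counts <- segments$n_samples[as.integer(rownames(sums))]
  means <- matrix(NaN, n_seg, d[1] * d[2])
  means[as.integer(rownames(sums)), ] <- sums / counts
  seg_mean <- array(t(means), dim = c(d[1], d[2], n_seg),
                    dimnames = c(dimnames(zpower)[1:2], list(NULL)))
  attr(seg_mean, "freqs") <- attr(zpower, "freqs")
  if (smooth_segments > 0)
    seg_mean <- .smooth_segment_values(seg_mean, segments, smooth_segments)
  seg_mean
}

# centered moving average over +-k segments, shrinking symmetrically at the
# track edges; empty segments stay NaN
.smooth_segment_values <- function(seg_mean, segments, smooth_segments) {
  d <- dim(seg_mean)
  n_seg <- d[3]
  means <- t(matrix(seg_mean, nrow = d[1] * d[2]))  # seg x (ch*freq)
  k <- 2L * smooth_segments + 1L
  sm <- stats::filter(means, rep(1 / k, k), sides = 2)
  for (s in c(seq_len(min(smooth_segments, n_seg)),
              seq(max(1L, n_seg - smooth_segments + 1L), n_seg))) {
    h <- min(smooth_segments, s - 1L, n_seg - s)
    sm[s, ] <- colMeans(means[(s - h):(s + h), , drop = FALSE],
                        na.rm = TRUE)
  }
  bad <- which(is.na(sm[, 1]) & segments$n_samples > 0)
  for (s in bad) {
    h <- min(smooth_segments, s - 1L, n_seg - s)
    sm[s, ] <- colMeans(means[(s - h):(s + h), , drop = FALSE],
                        na.rm = TRUE)
  }
  sm[segments$n_samples == 0, ] <- NaN
  out <- array(t(as.matrix(sm)), dim = d, dimnames = dimnames(seg_mean))
  attr(out, "freqs") <- attr(seg_mean, "freqs")
  out
}

#' Frontal theta and posterior alpha cluster power per segment
#'
#' Theta = mean over the 4–7 Hz bins and the frontal cluster (F3, Fz, F4,
#' FC1, FC2); alpha = mean over the 8–12 Hz bins and the posterior cluster
#' (P3, Pz, P4, PO9, PO10, O1, Oz, O2).
#'
#' @param seg_values Array from [segment_average_and_smooth()] with channel
#'   dimnames and a `freqs` attribute.
#' @param theta_band,alpha_band Band limits in Hz (inclusive).
#' @return data.frame `segment`, `theta_z`, `alpha_z`, `score`
#'   (= alpha_z - theta_z).
#' @export
band_cluster_power <- function(seg_values, theta_band = c(4, 7),
                               alpha_band = c(8, 12)) {
  cl <- driveload_clusters()
  chs <- dimnames(seg_values)[[1]]
  freqs <- attr(seg_values, "freqs")
  need <- c(cl$frontal_theta, cl$posterior_alpha)
  miss <- setdiff(need, chs)
  if (length(miss))
    stop("missing cluster channel(s): ", paste(miss, collapse = ", "))
  th_f <- which(freqs >= theta_band[1] & freqs <= theta_band[2])
  al_f <- which(freqs >= alpha_band[1] & freqs <= alpha_band[2])
  n_seg <- dim(seg_values)[3]
  theta <- apply(seg_values[cl$frontal_theta, th_f, , drop = FALSE], 3, mean)
  alpha <- apply(seg_values[cl$posterior_alpha, al_f, , drop = FALSE], 3, mean)
  data.frame(segment = seq_len(n_seg) - 1L, theta_z = theta,
             alpha_z = alpha, score = alpha - theta)
}

#' Assign task-load terciles from per-subject segment scores
#'
#' The per-segment score is alpha_z - theta_z; the median across subjects
#' is split into rank terciles: the highest-score third is low load
#' (predominant alpha), the lowest third high load (predominant theta).
#' Ties are broken by segment index; all-NaN segments stay unassigned.
#'
#' @param scores Matrix subjects x segments (a single subject may be given
#'   as a vector), or a list of [band_cluster_power()] data.frames on an
#'   identical segment grid.
#' @return data.frame of class `load_map`: `segment`, `score` (across-
#'   subject median), `load` (`"low"/"medium"/"high"` or NA), plus attribute
#'   `cutpoints`.
#' @export
assign_task_load <- function(scores) {
  if (is.list(scores) && !is.data.frame(scores) && !is.matrix(scores)) {
    segs <- lapply(scores, `[[`, "segment")
    if (!all(vapply(segs, identical, TRUE, segs[[1]])))
      stop("subjects must share an identical segment grid")
    scores <- do.call(rbind, lapply(scores, `[[`, "score"))
  }
  if (is.vector(scores)) scores <- rbind(scores)
  med <- apply(scores, 2L, median, na.rm = TRUE)
  n <- length(med)
  load <- rep(NA_character_, n)
  ok <- is.finite(med)
  if (sum(ok) >= 3) {
    # score is alpha - theta: highest score = predominant alpha = LOW load
    load[ok] <- c(high = "low", medium = "medium", low = "high")[
      .tercile_labels(-med[ok])]
  }
  cuts <- if (sum(ok) >= 3)
    quantile(med[ok], c(1 / 3, 2 / 3), names = FALSE) else c(NA, NA)
  structure(data.frame(segment = seq_len(n) - 1L, score = med, load = load),
            cutpoints = cuts, class = c("load_map", "data.frame"))
}

#' Per-load behavioral summaries
#'
#' Mean driving velocity, steering acceleration (mean |second difference| of
#' the steering angle times rate^2, deg/s^2, computed on the native
#' telemetry grid), and blink / saccade rates per minute (saccades split by
#' type), per load level.
#'
#' @param rec Recording with aligned telemetry.
#' @param distance Distance trace from [reconstruct_position()].
#' @param segments [segment_track()] output.
#' @param load_map [assign_task_load()] output.
#' @param events [ocular_events()] with detected blinks/saccades.
#' @param telemetry_rate Native telemetry rate (Hz), default 100.
#' @return data.frame: one row per load level with `velocity_kmh`,
#'   `steering_acc`, `blinks_min`, `saccades_out_min`, `saccades_in_min`,
#'   `dwell_min` (minutes spent in that load level).
#' @export
summarize_behavior <- function(rec, distance, segments, load_map, events,
                               telemetry_rate = 100) {
  stopifnot(!is.null(rec$telemetry))
  sr <- rec$sample_rate
  n <- n_samples(rec)
  seg_of <- findInterval(distance, segments$start_m,
                         rightmost.closed = FALSE) - 1L
  seg_of[seg_of < 0 | seg_of >= nrow(segments)] <- NA
  load_of <- load_map$load[seg_of + 1L]
  lv <- c("low", "medium", "high")
  dec <- max(1L, round(sr / telemetry_rate))
  native <- seq(1L, n, by = dec)
  steer <- rec$telemetry$steering_deg[native]
  acc <- abs(diff(diff(steer))) * telemetry_rate^2
  acc_load <- load_of[native][-c(1, 2)]
  ev_load <- load_of[pmin(n, events$sample + 1L)]
  out <- lapply(lv, function(L) {
    sel <- which(load_of == L)
    dwell_min <- length(sel) / sr / 60
    if (!length(sel))
      return(data.frame(load = L, velocity_kmh = NaN, steering_acc = NaN,
                        blinks_min = 0, saccades_out_min = 0,
                        saccades_in_min = 0, dwell_min = 0))
    nb <- sum(events$kind == "blink" & ev_load == L, na.rm = TRUE)
    no <- sum(events$kind == "saccade_onset" & events$sacc_type == "outward" &
                ev_load == L, na.rm = TRUE)
    ni <- sum(events$kind == "saccade_onset" & events$sacc_type == "inward" &
                ev_load == L, na.rm = TRUE)
    data.frame(load = L,
               velocity_kmh = mean(rec$telemetry$velocity_kmh[sel]),
               steering_acc = mean(acc[which(acc_load == L)], na.rm = TRUE),
               blinks_min = nb / dwell_min,
               saccades_out_min = no / dwell_min,
               saccades_in_min = ni / dwell_min,
               dwell_min = dwell_min)
  })
  do.call(rbind, out)
}

#' Track-load pipeline for one subject
#'
#' Convenience wrapper: reconstruct position, segment the track, wavelet
#' power on the analysis clusters, z-transform, segment-average, smooth
#' (±50 m) and extract the theta/alpha cluster scores.
#'
#' @param rec Recording with telemetry and trigger samples attached.
#' @param max_distance Analyzed track length (m).
#' @param downsample Power-of-two decimation factor for the wavelet power
#'   traces (see [cwt_power()]); the band of interest ends at 30 Hz, so a
#'   factor of 4 at 500 Hz is lossless for practical purposes.
#' @param smooth_segments Moving-average half width.
#' @param native_segments Also return the native-rate segment table (only
#'   behavior summaries need it).
#' @return List: `scores` ([band_cluster_power()] data.frame), `segments`
#'   (if requested), `distance` (at the recording's native rate).
#' @export
trackload_pipeline <- function(rec, max_distance, downsample = 4L,
                               smooth_segments = 5,
                               frequencies = c("bands", "full"),
                               native_segments = TRUE) {
  stopifnot(!is.null(rec$telemetry), !is.null(rec$trigger_samples))
  frequencies <- match.arg(frequencies)
  distance <- reconstruct_position(rec$telemetry$velocity_kmh,
                                   rec$sample_rate, rec$trigger_samples)
  cl <- driveload_clusters()
  chans <- unique(c(cl$frontal_theta, cl$posterior_alpha))
  if (frequencies == "full") {
    pw <- cwt_power(rec, channels = chans, downsample = downsample)
  } else {
    # only the theta (4-7 Hz) and alpha (8-12 Hz) bins of the 2-30-Hz grid
    # enter the load score; computing just those bins (with the cycle
    # counts they have on the full grid) gives an identical result
    fr <- c(4:7, 8:12)
    cyc <- 3 + (fr - 2) / 28 * 5
    pw <- .cwt_core(rec$data[chans, , drop = FALSE], rec$sample_rate,
                    fr, cyc, as.integer(downsample))
    attr(pw, "freqs") <- fr
    attr(pw, "sample_rate") <- rec$sample_rate / downsample
  }
  dist_w <- distance[seq(1L, length(distance), by = downsample)]
  segs_w <- segment_track(dist_w, 10, max_distance)
  # z-scoring is affine per bin, so it commutes with segment averaging:
  # averaging the raw power first avoids materializing the z array
  # (equality with the explicit zscore_trace route is covered by a test)
  sv <- segment_average_and_smooth(pw, segs_w, smooth_segments = 0)
  d <- dim(pw)
  flat <- matrix(pw, nrow = d[1] * d[2])
  mns <- rowMeans(flat)
  sds <- sqrt(rowSums((flat - mns)^2) / (d[3] - 1))
  sv <- (sv - array(mns, dim = dim(sv))) / array(sds, dim = dim(sv))
  if (smooth_segments > 0) {
    attr(sv, "freqs") <- attr(pw, "freqs")
    sv <- .smooth_segment_values(sv, segs_w, smooth_segments)
  }
  attr(sv, "freqs") <- attr(pw, "freqs")
  out <- list(scores = band_cluster_power(sv), distance = distance)
  if (native_segments)
    out$segments <- segment_track(distance, 10, max_distance)
  out
}
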