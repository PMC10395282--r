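# Eye-event-locked epoching, component measurement (with jackknife peak
# scoring) and lateralized measures.

#' Label events with the task load of their track segment
#'
#' @param events [ocular_events()].
#' @param distance Distance trace (m per sample) of the same recording.
#' @param load_map [assign_task_load()] output.
#' @return Events with the `load` column filled.
#' @export
label_event_load <- function(events, distance, load_map) {
  seg <- floor(distance[pmin(length(distance), events$sample + 1L)] / 10)
  ok <- seg >= 0 & seg < nrow(load_map)
  events$load <- NA_character_
  events$load[ok] <- load_map$load[seg[ok] + 1L]
  events
}

#' Epoch a recording around ocular events
#'
#' Extracts -500..1000 ms windows (configurable) around blinks, fixation
#' onsets or saccade onsets and subtracts the lock-specific baseline:
#' blink-locked -400..-200 ms (relative to the blink maximum),
#' fixation-locked -200..0 ms (saccade occlusion), saccade-locked
#' -400..-200 ms. `baseline = NULL` skips baseline correction (used for the
#' lateralized tonic measures, whose analysis window coincides with the
#' saccade baseline window). Events without a load label, or whose window
#' leaves the recording, are dropped and counted.
#'
#' @param rec A [new_recording()] object.
#' @param events [ocular_events()] with load labels.
#' @param lock_kind `"blink"`, `"fixation"` or `"saccade"`.
#' @param window Epoch limits (ms).
#' @param baseline Baseline window (ms) or `NA` for the lock default or
#'   `NULL` for none.
#' @param require_load Drop events with NA load (default TRUE).
#' @return `EventLockedSet`: list with `data` (events x channels x time),
#'   `times` (ms), `lock_kind`, `meta` (per-event load/direction/type),
#'   `baseline`, `dropped` (counts).
#' @export
epoch_events <- function(rec, events, lock_kind = c("blink", "fixation",
                                                    "saccade"),
                         window = c(-500, 1000), baseline = NA,
                         require_load = TRUE) {
  lock_kind <- match.arg(lock_kind)
  kind_map <- c(blink = "blink", fixation = "fixation_onset",
                saccade = "saccade_onset")
  ev <- events[events$kind == kind_map[lock_kind], , drop = FALSE]
  if (length(baseline) == 1 && is.na(baseline))
    baseline <- switch(lock_kind, blink = c(-400, -200),
                       fixation = c(-200, 0), saccade = c(-400, -200))
  sr <- rec$sample_rate
  i0 <- round(window[1] / 1000 * sr); i1 <- round(window[2] / 1000 * sr)
  times <- (i0:i1) / sr * 1000
  n <- n_samples(rec)
  dropped <- c(no_load = 0L, bounds = 0L)
  if (require_load) {
    dropped["no_load"] <- sum(is.na(ev$load))
    ev <- ev[!is.na(ev$load), , drop = FALSE]
  }
  ctr <- ev$sample + 1L
  ok <- ctr + i0 >= 1L & ctr + i1 <= n
  dropped["bounds"] <- sum(!ok)
  ev <- ev[ok, , drop = FALSE]; ctr <- ctr[ok]
  n_ev <- nrow(ev)
  dat <- array(0, dim = c(n_ev, nrow(rec$data), length(times)),
               dimnames = list(NULL, rec$channel_names, NULL))
  for (e in seq_len(n_ev))
    dat[e, , ] <- rec$data[, (ctr[e] + i0):(ctr[e] + i1), drop = FALSE]
  if (!is.null(baseline)) {
    bsel <- which(times >= baseline[1] & times <= baseline[2])
    bl <- apply(dat[, , bsel, drop = FALSE], c(1, 2), mean)
    dat <- dat - as.vector(bl)  # recycles over the time dimension
  }
  structure(list(data = dat, times = times, lock_kind = lock_kind,
                 meta = data.frame(load = ev$load, direction = ev$direction,
                                   sacc_type = ev$sacc_type,
                                   sample = ev$sample),
                 baseline = baseline, dropped = dropped),
            class = "EventLockedSet")
}

#' Average an event-locked set within condition cells
#'
#' @param set An [epoch_events()] result (the `meta` may include a
#'   `subject` column added by the caller).
#' @param by Metadata columns defining the cells.
#' @return List: `cells` (data.frame with `n_events`), `avg` (cells x
#'   channels x time array), `times`, `lock_kind`.
#' @export
grand_average <- function(set, by = c("load")) {
  key <- interaction(set$meta[by], drop = FALSE, sep = "|", lex.order = TRUE)
  levs <- levels(key)
  d <- dim(set$data)
  avg <- array(NaN, dim = c(length(levs), d[2], d[3]),
               dimnames = list(levs, dimnames(set$data)[[2]], NULL))
  n_ev <- integer(length(levs))
  for (i in seq_along(levs)) {
    sel <- which(key == levs[i])
    n_ev[i] <- length(sel)
    if (!length(sel)) { warning("empty cell: ", levs[i]); next }
    avg[i, , ] <- colMeans(set$data[sel, , , drop = FALSE])
  }
  parts <- do.call(rbind, strsplit(levs, "|", fixed = TRUE))
  cells <- data.frame(parts, stringsAsFactors = FALSE)
  names(cells) <- by
  cells$n_events <- n_ev
  list(cells = cells, avg = avg, times = set$times,
       lock_kind = set$lock_kind)
}

#' Component measurement specification
#'
#' @param name Component name.
#' @param window Detection window (ms).
#' @param cluster Electrode labels to average.
#' @param polarity `"positive"` / `"negative"` (signed extremum) or
#'   `"mean"` (window mean).
#' @param smooth_ms Half-width (ms) of a moving average applied to the
#'   cluster waveform before extremum detection; ignored for `"mean"`
#'   measures. Default 12 ms — standard practice to stabilize peak scoring
#'   against residual noise in the averages.
#' @return List of class `component_measure`.
#' @export
component_measure <- function(name, window, cluster, polarity,
                              smooth_ms = 12) {
  stopifnot(polarity %in% c("positive", "negative", "mean"))
  if (polarity == "mean") smooth_ms <- 0
  structure(list(name = name, window = window, cluster = cluster,
                 polarity = polarity, smooth_ms = smooth_ms),
            class = "component_measure")
}

#' ERP component specifications per lock kind
#'
#' The detection windows and electrode clusters of the blink-locked and
#' fixation-locked components: occipital N1 and P2, parietal P2,
#' fronto-central N2, and (fixation only) the occipital lambda response P1.
#'
#' @param lock_kind `"blink"` or `"fixation"`.
#' @return Named list of [component_measure()] objects.
#' @export
table_components <- function(lock_kind = c("blink", "fixation")) {
  lock_kind <- match.arg(lock_kind)
  cl <- driveload_clusters()
  if (lock_kind == "blink")
    list(N1 = component_measure("N1", c(20, 200), cl$occipital, "negative"),
         P2_parietal = component_measure("P2_parietal", c(80, 200),
                                         cl$parietal, "positive"),
         P2_occipital = component_measure("P2_occipital", c(80, 250),
                                          cl$occipital, "positive"),
         N2 = component_measure("N2", c(100, 600), cl$frontocentral,
                                "negative"))
  else
    list(P1_lambda = component_measure("P1_lambda", c(0, 200), cl$occipital,
                                       "positive"),
         N1 = component_measure("N1", c(20, 200), cl$occipital, "negative"),
         P2_parietal = component_measure("P2_parietal", c(100, 300),
                                         cl$parietal, "positive"),
         P2_occipital = component_measure("P2_occipital", c(100, 400),
                                          cl$occipital, "positive"),
         N2 = component_measure("N2", c(150, 400), cl$frontocentral,
                                "negative"))
}

#' Measure a component on condition averages
#'
#' Cluster-mean waveform per cell, then the signed extremum (peak
#' components) or the window mean within the detection window.
#'
#' @param averages A [grand_average()] result.
#' @param spec A [component_measure()].
#' @return data.frame: the cells with a `value` column (uV).
#' @export
measure_component <- function(averages, spec) {
  times <- averages$times
  if (spec$window[1] < min(times) || spec$window[2] > max(times))
    stop("measurement window outside the epoch")
  chs <- match(spec$cluster, dimnames(averages$avg)[[2]])
  if (anyNA(chs)) stop("cluster channel(s) missing from the averages")
  dt <- if (length(times) > 1) times[2] - times[1] else 1
  k <- if (spec$smooth_ms > 0) 2L * round(spec$smooth_ms / dt) + 1L else 1L
  sel <- which(times >= spec$window[1] & times <= spec$window[2])
  out <- averages$cells
  out$component <- spec$name
  out$value <- vapply(seq_len(nrow(out)), function(i) {
    wf <- apply(averages$avg[i, chs, , drop = FALSE], 3, mean)
    if (k > 1) {
      wf <- as.numeric(stats::filter(wf, rep(1 / k, k), sides = 2))
      # shrink the average at the epoch edges
      nw <- length(wf)
      for (e in which(is.na(wf))) {
        h <- min(e - 1L, nw - e, (k - 1L) %/% 2L)
        wf[e] <- mean(apply(averages$avg[i, chs, (e - h):(e + h),
                                         drop = FALSE], 3, mean))
      }
    }
    w <- wf[sel]
    switch(spec$polarity, positive = max(w), negative = min(w),
           mean = mean(w))
  }, 1.0)
  out
}

#' Jackknife peak estimation over subjects
#'
#' Measures a component on each leave-one-subject-out grand average of
#' per-subject condition averages. The resulting values are analyzed with
#' [rm_anova()] using `jackknife = TRUE`, which rescales F by (n-1)^2.
#'
#' @param subject_averages List (one per subject) of [grand_average()]
#'   results on identical cells.
#' @param spec A [component_measure()].
#' @return data.frame: `subject` (the left-out subject), cells, `value`;
#'   attribute `jackknife = TRUE`.
#' @export
jackknife_peaks <- function(subject_averages, spec) {
  n <- length(subject_averages)
  if (n < 3) stop("jackknife needs at least 3 subjects")
  cells <- subject_averages[[1]]$cells
  arrs <- lapply(subject_averages, `[[`, "avg")
  total <- Reduce(`+`, arrs)
  out <- lapply(seq_len(n), function(s) {
    loo <- subject_averages[[1]]
    loo$avg <- (total - arrs[[s]]) / (n - 1)
    v <- measure_component(loo, spec)
    v$subject <- s
    v
  })
  res <- do.call(rbind, out)
  attr(res, "jackknife") <- TRUE
  res
}

#' Contra- minus ipsilateral difference of an event-locked set
#'
#' For each event with a left/right direction, the contralateral electrode
#' of each pair is the one opposite the direction (right-directed events:
#' left-hemisphere electrode). Returns the pair-averaged contra - ipsi
#' waveform per event.
#'
#' @param set An [epoch_events()] result.
#' @param pairs List of c(left, right) electrode pairs; defaults to the
#'   posterior pairs P7/P8, PO9/PO10, O1/O2.
#' @return List: `data` (events x time), `times`, `meta` (direction-carrying
#'   events only).
#' @export
contra_ipsi <- function(set, pairs = driveload_clusters()$posterior_pairs) {
  keep <- which(set$meta$direction %in% c("left", "right"))
  chs <- dimnames(set$data)[[2]]
  li <- match(vapply(pairs, `[`, "", 1L), chs)
  ri <- match(vapply(pairs, `[`, "", 2L), chs)
  if (anyNA(li) || anyNA(ri)) stop("missing pair channel(s)")
  nt <- length(set$times)
  out <- matrix(0, length(keep), nt)
  for (j in seq_along(keep)) {
    e <- keep[j]
    right_ev <- set$meta$direction[e] == "right"
    con <- if (right_ev) li else ri
    ips <- if (right_ev) ri else li
    dmat <- matrix(set$data[e, con, ], nrow = length(con)) -
      matrix(set$data[e, ips, ], nrow = length(ips))
    out[j, ] <- colMeans(dmat)
  }
  list(data = out, times = set$times, meta = set$meta[keep, , drop = FALSE])
}

#' Lateralized and fronto-central slow measures
#'
#' The phasic ERL (fixation-locked contra - ipsi mean, 80–120 ms), the
#' pre-saccadic CNV (fronto-central mean -200..-50 ms, baseline
#' -400..-200 ms) and the tonic ERL in two pre-saccadic windows
#' (-400..-200 and -200..-50 ms, contra - ipsi, no baseline), per
#' load x saccade type, ready for [rm_anova()].
#'
#' @param fix_set Fixation-locked [epoch_events()] set (default baseline).
#' @param sacc_set Saccade-locked set built with `baseline = NULL`.
#' @return data.frame: `component`, `load`, `sacc_type`, `value`.
#' @export
lateralized_measures <- function(fix_set, sacc_set) {
  cl <- driveload_clusters()
  lat_fix <- contra_ipsi(fix_set)
  lat_sac <- contra_ipsi(sacc_set)
  win_mean <- function(lat, w, meta_sel) {
    sel <- lat$times >= w[1] & lat$times <= w[2]
    rowMeans(lat$data[, sel, drop = FALSE])
  }
  cells <- expand.grid(load = c("low", "medium", "high"),
                       sacc_type = c("outward", "inward"),
                       stringsAsFactors = FALSE)
  res <- list()
  add <- function(component, vals, meta) {
    for (i in seq_len(nrow(cells))) {
      sel <- meta$load == cells$load[i] & meta$sacc_type == cells$sacc_type[i]
      res[[length(res) + 1L]] <<- data.frame(
        component = component, load = cells$load[i],
        sacc_type = cells$sacc_type[i],
        value = if (any(sel)) mean(vals[sel]) else NaN)
    }
  }
  add("phasic_ERL", win_mean(lat_fix, c(80, 120)), lat_fix$meta)
  # CNV: fronto-central cluster mean of the (baselined internally) saccade set
  chs <- match(cl$frontocentral, dimnames(sacc_set$data)[[2]])
  wf <- apply(sacc_set$data[, chs, , drop = FALSE], c(1, 3), mean)
  bsel <- sacc_set$times >= -400 & sacc_set$times <= -200
  msel <- sacc_set$times >= -200 & sacc_set$times <= -50
  cnv_vals <- rowMeans(wf[, msel, drop = FALSE]) -
    rowMeans(wf[, bsel, drop = FALSE])
  add("CNV", cnv_vals, sacc_set$meta)
  add("tonic_ERL1", win_mean(lat_sac, c(-400, -200)), lat_sac$meta)
  add("tonic_ERL2", win_mean(lat_sac, c(-200, -50)), lat_sac$meta)
  do.call(rbind, res)
}
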