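# Analytic forward model of the generator: predicts the value every
# event-locked measure reads off the injected superposition, accounting for
# deterministic within-excursion timing (saccade onset -> fixation +40 ms)
# and for cross-event leakage within a gaze excursion, marginalized over the
# uniform fixation dwell. This is the "injected amplitude" reference for
# parameter-recovery tests: overlapping components (e.g. the pre-saccadic
# CNV under the fixation baseline window) make the nominal amplitude and the
# measurable amplitude differ by construction, not by estimation error.

# shift every component amplitude by its realized jitter, mirroring how the
# generator applies one additive draw per component (tonic ERL: both
# window amplitudes share the draw)
.apply_jitter <- function(cfg, jit) {
  jv <- function(nm) {
    v <- unname(jit[nm])
    if (length(v) != 1 || is.na(v)) 0 else v
  }
  for (nm in names(cfg$components$blink))
    cfg$components$blink[[nm]]$amp <-
      cfg$components$blink[[nm]]$amp + jv(paste0("blink.", nm))
  for (nm in names(cfg$components$fixation))
    cfg$components$fixation[[nm]]$amp <-
      cfg$components$fixation[[nm]]$amp + jv(paste0("fixation.", nm))
  cfg$components$saccade$CNV$amp <-
    cfg$components$saccade$CNV$amp + jv("saccade.CNV")
  cfg$components$saccade$tonic_ERL$amp1 <-
    cfg$components$saccade$tonic_ERL$amp1 + jv("saccade.tonic_ERL")
  cfg$components$saccade$tonic_ERL$amp2 <-
    cfg$components$saccade$tonic_ERL$amp2 + jv("saccade.tonic_ERL")
  cfg$components$fixation_lat$phasic_ERL$amp <-
    cfg$components$fixation_lat$phasic_ERL$amp +
    jv("fixation_lat.phasic_ERL")
  cfg
}

# measurement definitions mirrored from the analysis conventions
.measure_defs <- function() {
  list(
    blink = list(baseline = c(-400, -200), measures = list(
      N1 = list(window = c(20, 200), polarity = "negative", frame = "occipital"),
      P2_parietal = list(window = c(80, 200), polarity = "positive", frame = "parietal"),
      P2_occipital = list(window = c(80, 250), polarity = "positive", frame = "occipital"),
      N2 = list(window = c(100, 600), polarity = "negative", frame = "frontocentral"))),
    fixation = list(baseline = c(-200, 0), measures = list(
      P1_lambda = list(window = c(0, 200), polarity = "positive", frame = "occipital"),
      N1 = list(window = c(20, 200), polarity = "negative", frame = "occipital"),
      P2_parietal = list(window = c(100, 300), polarity = "positive", frame = "parietal"),
      P2_occipital = list(window = c(100, 400), polarity = "positive", frame = "occipital"),
      N2 = list(window = c(150, 400), polarity = "negative", frame = "frontocentral"),
      phasic_ERL = list(window = c(80, 120), polarity = "mean", frame = "lateral"))),
    saccade = list(baseline = NULL, measures = list(
      CNV = list(window = c(-200, -50), polarity = "mean", frame = "frontocentral",
                 baseline = c(-400, -200)),
      tonic_ERL1 = list(window = c(-400, -200), polarity = "mean", frame = "lateral"),
      tonic_ERL2 = list(window = c(-200, -50), polarity = "mean", frame = "lateral"))))
}

# expected epoch waveform for one lock kind / condition / measurement frame
.expected_wave <- function(cfg, lock, frame, load, type, tau,
                           include_blink_artifact = TRUE) {
  cl <- driveload_clusters()
  topo <- .generator_topographies()
  w_central <- function(cluster) {
    if (frame == "lateral") return(0)
    as.numeric(cluster == frame)
  }
  # weight of a lateralized component in a central cluster frame (leakage of
  # the +1 contra-channel topography into the cluster mean); in the lateral
  # frame the component contributes its full contra-ipsi amplitude.
  w_lat <- if (frame == "lateral") 1 else mean(topo$lat_left[cl[[frame]]])
  w_veog <- if (frame == "lateral") 0 else mean(topo$veog[cl[[frame]]])

  W <- numeric(length(tau))
  add_exact <- function(fun, shift = 0, mult = 1) {
    if (frame != "lateral") mult <- abs(mult)  # direction flips only matter
    if (mult != 0) W <<- W + mult * fun(tau + shift)  # in the lateral frame
  }
  # E_g[fun(tau + shift + s*g)], g ~ U(dwell) in ms
  gs <- seq(cfg$dwell_s[1] * 1000, cfg$dwell_s[2] * 1000, length.out = 161)
  add_smear <- function(fun, shift = 0, s = -1, mult = 1) {
    if (frame != "lateral") mult <- abs(mult)
    if (mult == 0) return(invisible())
    acc <- numeric(length(tau))
    for (g in gs) acc <- acc + fun(tau + shift + s * g)
    W <<- W + mult * acc / length(gs)
  }

  comp <- cfg$components
  fixf <- function(nm, ty) {
    cc <- comp$fixation[[nm]]
    a <- cc$amp[load, ty] * w_central(cc$cluster)
    function(t) a * .gauss_wave(t, cc$lat, cc$sigma)
  }
  blinkf <- function(nm) {
    cc <- comp$blink[[nm]]
    a <- cc$amp[load] * w_central(cc$cluster)
    function(t) a * .gauss_wave(t, cc$lat, cc$sigma)
  }
  cnvf <- function(ty) {
    a <- comp$saccade$CNV$amp[load, ty] * w_central("frontocentral")
    function(t) .cnv_wave(t, a)
  }
  tonf <- function(ty) {
    v1 <- comp$saccade$tonic_ERL$amp1[load, ty]
    v2 <- comp$saccade$tonic_ERL$amp2[load, ty]
    function(t) .tonic_wave(t, v1, v2) * w_lat
  }
  pcf <- function(ty) {
    a <- comp$fixation_lat$phasic_ERL$amp[load, ty]
    function(t) .pc_wave(t, a) * w_lat
  }
  veogf <- function(t) {
    if (!include_blink_artifact) return(numeric(length(t)))
    cfg$blink_amp * w_veog * .gauss_wave(t, 0, cfg$blink_sigma_ms)
  }

  other <- function(ty) if (ty == "outward") "inward" else "outward"
  if (lock == "blink") {
    for (nm in names(comp$blink)) add_exact(blinkf(nm))
    add_exact(veogf)
  } else if (lock == "fixation") {
    for (nm in names(comp$fixation)) add_exact(fixf(nm, type))
    add_exact(cnvf(type), shift = 40)
    add_exact(tonf(type), shift = 40)
    add_exact(pcf(type))
    ot <- other(type)
    if (type == "outward") {
      # the returning inward saccade follows this fixation after the dwell g
      add_smear(cnvf(ot), shift = 0, s = -1)
      add_smear(tonf(ot), shift = 0, s = -1, mult = -1)
      for (nm in names(comp$fixation)) add_smear(fixf(nm, ot), shift = -40, s = -1)
      add_smear(pcf(ot), shift = -40, s = -1, mult = -1)
    } else {
      # the outward saccade of the same excursion precedes this fixation
      for (nm in names(comp$fixation)) add_smear(fixf(nm, ot), shift = 40, s = 1)
      add_smear(cnvf(ot), shift = 80, s = 1)
      add_smear(tonf(ot), shift = 80, s = 1, mult = -1)
      add_smear(pcf(ot), shift = 40, s = 1, mult = -1)
    }
  } else if (lock == "saccade") {
    add_exact(cnvf(type))
    add_exact(tonf(type))
    for (nm in names(comp$fixation)) add_exact(fixf(nm, type), shift = -40)
    add_exact(pcf(type), shift = -40)
    ot <- other(type)
    if (type == "outward") {
      add_smear(cnvf(ot), shift = -40, s = -1)
      add_smear(tonf(ot), shift = -40, s = -1, mult = -1)
      for (nm in names(comp$fixation)) add_smear(fixf(nm, ot), shift = -80, s = -1)
      add_smear(pcf(ot), shift = -80, s = -1, mult = -1)
    } else {
      for (nm in names(comp$fixation)) add_smear(fixf(nm, ot), shift = 0, s = 1)
      add_smear(cnvf(ot), shift = 40, s = 1)
      add_smear(tonf(ot), shift = 40, s = 1, mult = -1)
      add_smear(pcf(ot), shift = 0, s = 1, mult = -1)
    }
  }
  W
}

#' Expected event-locked measure values for a generator configuration
#'
#' Computes, for every component measure, the value the measurement
#' conventions (epoch windows, baselines, peak/mean rules) read off the
#' noiseless injected superposition — i.e. the effective injected amplitude
#' including deterministic component overlap within a gaze excursion.
#'
#' @param cfg A [subject_config()].
#' @param blink_artifact Include the blink EOG artifact in the prediction
#'   (set FALSE when the measured data had ocular components removed).
#' @param jitter Optional named vector of realized per-component amplitude
#'   offsets (e.g. the across-subject mean of the `jitter` entries of a
#'   cohort's ground truths): the injected amplitude of a finite cohort is
#'   the nominal value plus its realized jitter mean.
#' @return data.frame with `lock_kind`, `component`, `load`, `sacc_type`
#'   and `expected` (uV).
#' @export
expected_component_measures <- function(cfg = subject_config(),
                                        blink_artifact = TRUE,
                                        jitter = NULL) {
  if (!is.null(jitter)) cfg <- .apply_jitter(cfg, jitter)
  defs <- .measure_defs()
  tau <- seq(-500, 1000, by = 2)  # the 500-Hz epoch grid
  rows <- list()
  for (lock in names(defs)) {
    dl <- defs[[lock]]
    types <- if (lock == "blink") "none" else c("outward", "inward")
    for (load in c("low", "medium", "high")) for (ty in types) {
      waves <- list()
      for (nm in names(dl$measures)) {
        md <- dl$measures[[nm]]
        key <- md$frame
        if (is.null(waves[[key]]))
          waves[[key]] <- .expected_wave(cfg, lock, key, load,
                                         if (ty == "none") "outward" else ty,
                                         tau, blink_artifact)
        w <- waves[[key]]
        bl <- md$baseline %||% dl$baseline
        if (!is.null(bl))
          w <- w - mean(w[tau >= bl[1] & tau <= bl[2]])
        if (md$polarity != "mean") {
          # mirror measure_component's peak-scoring smoothing on the 500-Hz
          # epoch grid (13 taps at 2 ms)
          k <- 2L * round(12 / 2) + 1L
          ws <- as.numeric(stats::filter(w, rep(1 / k, k), sides = 2))
          ws[is.na(ws)] <- w[is.na(ws)]
          w <- ws
        }
        sel <- w[tau >= md$window[1] & tau <= md$window[2]]
        val <- switch(md$polarity,
                      positive = max(sel), negative = min(sel),
                      mean = mean(sel))
        rows[[length(rows) + 1L]] <-
          data.frame(lock_kind = lock, component = nm, load = load,
                     sacc_type = ty, expected = val)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
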