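# Synthetic driving-EEG generator: 1/f background, demand-modulated posterior
# alpha and frontal theta, blink and saccade EOG artifacts, and injected
# eye-event-locked components with known amplitudes per load level and
# saccade type.

#' Subject-level generator configuration
#'
#' All knobs of [simulate_recording()] with their default study conditions.
#' `snr` is defined as the amplitude of the largest injected component
#' (the 7-uV lambda response) divided by the per-channel RMS of the 1/f
#' background.
#'
#' @param snr Signal-to-noise ratio (see above). `Inf` disables background
#'   noise.
#' @param alpha_amp,theta_amp Oscillation source amplitudes (uV, RMS scale)
#'   at demand 0.
#' @param alpha_mod,theta_mod Fractional modulation of the oscillation
#'   envelopes across the demand range: alpha shrinks, theta grows.
#' @param blink_amp Blink EOG amplitude (uV at Fp1/Fp2).
#' @param blink_sigma_ms Blink Gaussian width (ms).
#' @param blink_rate_base,blink_rate_slope Blink rate per minute at demand 0
#'   and its (negative) change to demand 1.
#' @param sacc_rate_base,sacc_rate_slope Gaze-excursion (outward saccade)
#'   rate per minute at demand 0 and its change to demand 1.
#' @param sacc_amp_uV The three discrete saccade EOG amplitude classes (uV).
#' @param sacc_sigma_ms Width of the Gaussian-integral saccade step; 9.32 ms
#'   puts the 10%-peak-velocity crossings at +-20 ms (40-ms saccades).
#' @param dwell_s Range of the uniform fixation dwell between an outward
#'   saccade's fixation and the returning inward saccade (s).
#' @param alpha_coherence Variance share of the posterior alpha carrier
#'   common to both hemispheres (interhemispheric coherence; posterior
#'   alpha is strongly bilaterally coherent in real EEG).
#' @param alpha_supp Fractional suppression of contralateral posterior alpha
#'   in the 800 ms before an inward saccade.
#' @param amp_jitter_sd Between-subject SD (uV) added to every injected
#'   component amplitude.
#' @param components Injected component table; see [erp_component_table()].
#' @return List of class `subject_config`.
#' @export
subject_config <- function(snr = 5, alpha_amp = 2, theta_amp = 1.5,
                           alpha_mod = 0.5, theta_mod = 0.6,
                           blink_amp = 100, blink_sigma_ms = 50,
                           blink_rate_base = 12.2, blink_rate_slope = -4.5,
                           sacc_rate_base = 13.5, sacc_rate_slope = 5,
                           sacc_amp_uV = c(40, 80, 120),
                           sacc_sigma_ms = 9.32,
                           dwell_s = c(0.4, 1.2), alpha_coherence = 0.7,
                           alpha_supp = 0.35,
                           amp_jitter_sd = 0.2,
                           components = erp_component_table()) {
  structure(as.list(environment()), class = "subject_config")
}

#' Injected event-locked component table
#'
#' Default amplitudes follow the grand-mean pattern of the study conditions:
#' blink-locked N1/P2/N2, fixation-locked lambda (P1), N1, parietal and
#' occipital P2, fronto-central N2 (per load level, and per saccade type for
#' fixations), the pre-saccadic CNV, the tonic event-related lateralization
#' (two window amplitudes) and the post-fixation phasic ERL (N1pc).
#' Amplitudes are in microvolts; latencies and widths in ms.
#'
#' @return Nested list: `$blink`, `$fixation` (cluster components),
#'   `$saccade` (CNV + tonic ERL), `$fixation_lat` (phasic ERL).
#' @export
erp_component_table <- function() {
  lv <- c("low", "medium", "high")
  m3 <- function(x) setNames(x, lv)
  m32 <- function(out, inw)
    matrix(c(out, inw), 3, 2, dimnames = list(lv, c("outward", "inward")))
  list(
    blink = list(
      N1 = list(cluster = "occipital", lat = 110, sigma = 12,
                amp = m3(c(-1.72, -1.20, -0.62))),
      P2_parietal = list(cluster = "parietal", lat = 140, sigma = 12,
                         amp = m3(c(1.61, 1.65, 1.58))),
      P2_occipital = list(cluster = "occipital", lat = 180, sigma = 12,
                          amp = m3(c(2.26, 2.07, 1.97))),
      N2 = list(cluster = "frontocentral", lat = 300, sigma = 25,
                amp = m3(c(-0.64, -0.83, -0.73)))),
    fixation = list(
      P1_lambda = list(cluster = "occipital", lat = 90, sigma = 12,
                       amp = m32(c(7.51, 7.22, 7.25), c(5.98, 6.30, 6.67))),
      N1 = list(cluster = "occipital", lat = 150, sigma = 12,
                amp = m32(c(-1.45, -1.58, -1.02), c(-0.21, 0.21, 0.49))),
      P2_parietal = list(cluster = "parietal", lat = 200, sigma = 15,
                         amp = m32(c(0.82, 0.58, 0.59), c(1.60, 1.81, 1.72))),
      P2_occipital = list(cluster = "occipital", lat = 250, sigma = 15,
                          amp = m32(c(4.66, 4.36, 4.46), c(4.74, 5.22, 5.41))),
      N2 = list(cluster = "frontocentral", lat = 275, sigma = 25,
                amp = m32(c(-1.65, -1.28, -1.26), c(-0.39, -0.21, -0.21)))),
    saccade = list(
      CNV = list(cluster = "frontocentral",
                 amp = m32(c(0.07, -0.09, -0.06), c(-0.66, -0.93, -0.81))),
      tonic_ERL = list(lateral = TRUE,
                       amp1 = m32(c(0.15, -0.06, 0.13), c(-0.14, -0.33, -0.35)),
                       amp2 = m32(c(0.18, -0.01, 0.20), c(-0.22, -0.37, -0.34)))),
    fixation_lat = list(
      phasic_ERL = list(lateral = TRUE,
                        amp = m32(c(0.82, 0.99, 1.00), c(-0.11, -0.14, -0.30)))))
}

# ---- waveform shapes (t in ms relative to the locking event) --------------

.gauss_wave <- function(t, lat, sigma) exp(-(t - lat)^2 / (2 * sigma^2))

# CNV: smooth rise -240..-204, plateau -204..-46, fall -46..-20; normalized
# so the mean over [-200, -50] equals 1.
.cnv_shape <- function(t) {
  s <- numeric(length(t))
  s[t >= -204 & t <= -46] <- 1
  r <- t >= -240 & t < -204
  s[r] <- (t[r] + 240) / 36
  f <- t > -46 & t <= -20
  s[f] <- (-20 - t[f]) / 26
  s
}
.cnv_norm <- local({
  g <- seq(-200, -50, by = 0.5)
  mean(.cnv_shape(g))
})
.cnv_wave <- function(t, amp) amp * .cnv_shape(t) / .cnv_norm

# tonic ERL: ramp 0 at -460 -> v1 by -404, hold, short blend to v2 at -198,
# hold, fall to 0 by -20. Window means over [-400,-200] / [-200,-50] are v1
# and v2 up to the (tiny) blend overlap, which the forward model resolves.
.tonic_wave <- function(t, v1, v2) {
  w <- numeric(length(t))
  r <- t >= -460 & t < -404; w[r] <- v1 * (t[r] + 460) / 56
  w[t >= -404 & t < -202] <- v1
  b <- t >= -202 & t < -198
  w[b] <- v1 + (v2 - v1) * (t[b] + 202) / 4
  w[t >= -198 & t < -48] <- v2
  f <- t >= -48 & t <= -20
  w[f] <- v2 * (-20 - t[f]) / 28
  w
}

# phasic ERL (N1pc): raised cosine on [60, 140], normalized so the mean over
# [80, 120] equals 1.
.pc_shape <- function(t) {
  s <- numeric(length(t))
  r <- t >= 60 & t <= 140
  s[r] <- 0.5 * (1 - cos(2 * pi * (t[r] - 60) / 80))
  s
}
.pc_norm <- local({
  g <- seq(80, 120, by = 0.5)
  mean(.pc_shape(g))
})
.pc_wave <- function(t, amp) amp * .pc_shape(t) / .pc_norm

# ---- topographies ---------------------------------------------------------

.zero_mean_topo <- function(weights, montage = driveload_montage()) {
  topo <- setNames(numeric(length(montage)), montage)
  topo[names(weights)] <- weights
  comp <- .compensation_channels()
  free <- setdiff(comp, names(weights))
  topo[free] <- topo[free] - sum(topo) / length(free)
  topo
}

.generator_topographies <- function() {
  montage <- driveload_montage()
  cl <- driveload_clusters()
  cluster_topo <- function(chs) {
    w <- setNames(rep(1, length(chs)), chs)
    .zero_mean_topo(w, montage)
  }
  lat_topo <- function(side) {
    chs <- vapply(cl$posterior_pairs, `[`, "", if (side == "left") 1L else 2L)
    cluster_topo(chs)
  }
  veog <- setNames(numeric(length(montage)), montage)
  veog[c("Fp1", "Fp2")] <- 1
  veog[c("F3", "F4")] <- 0.4
  veog[c("F7", "F8")] <- 0.35
  veog["Fz"] <- 0.3
  veog[c("FC1", "FC2")] <- 0.15
  veog[c("FC5", "FC6")] <- 0.1
  veog["Cz"] <- 0.05
  heog <- setNames(numeric(length(montage)), montage)
  heog[c("F7", "F8")] <- c(-1, 1)
  heog[c("Fp1", "Fp2")] <- c(-0.4, 0.4)
  heog[c("F3", "F4")] <- c(-0.2, 0.2)
  heog[c("FC5", "FC6")] <- c(-0.15, 0.15)
  alpha_l <- .zero_mean_topo(c(O1 = 1, PO9 = 0.9, P3 = 0.7, P7 = 0.6,
                               Oz = 0.45, Pz = 0.3), montage)
  alpha_r <- .zero_mean_topo(c(O2 = 1, PO10 = 0.9, P4 = 0.7, P8 = 0.6,
                               Oz = 0.45, Pz = 0.3), montage)
  theta <- .zero_mean_topo(c(F3 = 0.8, Fz = 1, F4 = 0.8, FC1 = 0.7,
                             FC2 = 0.7), montage)
  list(veog = veog, heog = heog, alpha_left = alpha_l, alpha_right = alpha_r,
       theta = theta,
       occipital = cluster_topo(cl$occipital),
       parietal = cluster_topo(cl$parietal),
       frontocentral = cluster_topo(cl$frontocentral),
       lat_left = lat_topo("left"), lat_right = lat_topo("right"))
}

# ---- event scheduling -----------------------------------------------------

# renewal process with dead time and demand-dependent target rate (per min):
# hazard after the dead time is set so the realized rate matches the target.
.schedule_renewal <- function(t_grid, rate_per_min, dead_s, t_min, t_max) {
  n <- length(t_grid)
  dt <- t_grid[2] - t_grid[1]
  haz <- 1 / pmax(60 / pmax(rate_per_min, 0.1) - dead_s, 0.05)
  events <- numeric(0)
  t <- t_min
  while (t < t_max) {
    i <- min(n, max(1L, floor(t / dt) + 1L))
    h <- haz[i]
    gap <- rexp(1, h)
    t <- t + gap
    if (t >= t_max) break
    events <- c(events, t)
    t <- t + dead_s
  }
  events
}

# ---- main generator -------------------------------------------------------

#' Simulate a continuous driving-EEG recording with ground truth
#'
#' Renders a 32-channel, 500-Hz recording over the span of a telemetry
#' trace: 1/f background noise, posterior alpha (per hemisphere) whose
#' envelope falls with route demand, frontal theta rising with demand,
#' Gaussian blink EOG artifacts (rate falling with demand), saccadic EOG
#' steps of three amplitude classes organized as outward/inward gaze
#' excursions (rate rising with demand), injected event-locked components
#' per load level and saccade type, pre-saccadic CNV and tonic
#' lateralization, post-fixation phasic lateralization, and contralateral
#' alpha suppression before inward saccades.
#'
#' @param route A [simulate_route()] profile.
#' @param telemetry A [simulate_telemetry()] trace over that route.
#' @param subject A [subject_config()].
#' @param seed Integer seed; output is deterministic given the seed. Event
#'   schedules and noise are drawn from separate streams derived from it,
#'   so a `render = "events_only"` twin of a recording carries exactly the
#'   same events and injected components.
#' @param sample_rate EEG sampling rate (Hz).
#' @param channels Optional subset of montage channels to render (the
#'   ground truth is unaffected); default renders the full montage.
#' @param render `"full"` or `"events_only"` (no background, no
#'   oscillations: the noiseless twin used as a recovery reference).
#' @return List with `recording` (a [new_recording()] with telemetry and
#'   triggers attached) and `ground_truth` (events with true samples,
#'   per-segment demand terciles, injected component table, source traces,
#'   topographies, config).
#' @export
simulate_recording <- function(route, telemetry, subject = subject_config(),
                               seed = 1, sample_rate = 500,
                               channels = driveload_montage(),
                               render = c("full", "events_only")) {
  stopifnot(inherits(route, "RouteProfile"))
  render <- match.arg(render)
  montage <- driveload_montage()
  if (!all(channels %in% montage))
    stop("montage mismatch: unknown channel(s) ",
         paste(setdiff(channels, montage), collapse = ", "))
  noise_seed <- (seed %% 1000000007L) + 1000000007L  # separate stream
  set.seed(seed)
  tel_rate <- attr(telemetry, "rate") %||% 100
  n <- nrow(telemetry) * round(sample_rate / tel_rate)
  t_eeg <- (seq_len(n) - 1) / sample_rate
  dist <- approx(telemetry$time_s, telemetry$distance_m, t_eeg, rule = 2)$y
  u_t <- route$demand(dist)

  # ground-truth per-segment demand and tercile load
  n_seg <- floor(route$total_distance / 10)
  seg_demand <- route$demand((seq_len(n_seg) - 1) * 10 + 5)
  seg_load <- .tercile_labels(-seg_demand)  # high demand -> "high" load
  segment_demand <- data.frame(segment = seq_len(n_seg) - 1L,
                               demand = seg_demand, load = seg_load)
  seg_of_sample <- pmin(n_seg - 1L, pmax(0L, floor(dist / 10)))
  load_of_sample <- seg_load[seg_of_sample + 1L]

  cfg <- subject
  topo <- .generator_topographies()
  ch_idx <- match(channels, montage)
  data <- matrix(0, length(channels), n, dimnames = list(channels, NULL))

  # --- event schedules (schedule RNG stream) --------------------------
  t_lo <- 1.5; t_hi <- n / sample_rate - 1.5
  blink_rate <- cfg$blink_rate_base + cfg$blink_rate_slope * u_t
  blink_t <- .schedule_renewal(t_eeg, blink_rate, dead_s = 0.3,
                               t_min = t_lo, t_max = t_hi)
  exc_rate <- cfg$sacc_rate_base + cfg$sacc_rate_slope * u_t
  dwell_mid <- mean(cfg$dwell_s)
  exc_t <- .schedule_renewal(t_eeg, exc_rate,
                             dead_s = dwell_mid + 0.28 + 0.2,
                             t_min = t_lo, t_max = t_hi)
  n_exc <- length(exc_t)
  dwell <- runif(n_exc, cfg$dwell_s[1], cfg$dwell_s[2])
  side <- sample(c("left", "right"), n_exc, replace = TRUE)
  amp_class <- sample(3L, n_exc, replace = TRUE)
  blink_jit_a <- runif(length(blink_t), 0.9, 1.1)
  blink_jit_s <- runif(length(blink_t), 0.9, 1.1)
  jit <- .component_jitter(cfg)

  # --- background and oscillations (noise RNG stream) -----------------
  set.seed(noise_seed)
  env_alpha <- cfg$alpha_amp * (1 - cfg$alpha_mod * u_t)
  env_theta <- cfg$theta_amp * (1 + cfg$theta_mod * u_t)
  supp_l <- rep(1, n); supp_r <- rep(1, n)
  if (render == "events_only") {
    alpha_l_carrier <- numeric(n); alpha_r_carrier <- numeric(n)
    theta_src <- numeric(n)
  } else {
    bg_rms <- 7 / cfg$snr
    if (is.finite(bg_rms) && bg_rms > 0) {
      nf <- nextn(n, 2)
      f <- c(1e-3, seq_len(nf - 1)) * sample_rate / nf
      shape <- 1 / sqrt(pmax(f, 0.5))
      shape[f > sample_rate / 2] <- shape[nf - which(f > sample_rate / 2) + 2]
      for (k in seq_along(channels)) {
        w <- fft(rnorm(nf))
        x <- Re(fft(w * shape, inverse = TRUE))[seq_len(n)]
        data[k, ] <- data[k, ] + x / sd(x) * bg_rms
      }
    }
    # narrowband Gaussian noise synthesized in the frequency domain
    carrier <- function(lo, hi) {
      nf <- nextn(n, 2)
      f <- (seq_len(nf) - 1) * sample_rate / nf
      f[f > sample_rate / 2] <- sample_rate - f[f > sample_rate / 2]
      win <- 0.5 * (1 + cos(pi * pmin(1, pmax(0, (lo - f) / 0.8)))) *
             0.5 * (1 + cos(pi * pmin(1, pmax(0, (f - hi) / 0.8))))
      x <- Re(fft(fft(rnorm(nf)) * win, inverse = TRUE))[seq_len(n)]
      x / sd(x)
    }
    rho <- cfg$alpha_coherence %||% 0.7
    alpha_shared <- carrier(8.5, 11.5)
    alpha_l_carrier <- sqrt(rho) * alpha_shared +
      sqrt(1 - rho) * carrier(8.5, 11.5)
    alpha_r_carrier <- sqrt(rho) * alpha_shared +
      sqrt(1 - rho) * carrier(8.5, 11.5)
    theta_src <- carrier(4.5, 7) * env_theta
  }

  # --- EOG sources ----------------------------------------------------
  veog <- numeric(n)
  sigma_s <- cfg$sacc_sigma_ms / 1000
  # gaze position = cumulated hard steps (cumsum of deltas) plus a local
  # erf-shaped correction around each step center
  step_delta <- numeric(n)
  step_corr <- numeric(n)
  add_step <- function(t0, amp) {
    ic <- min(n, max(1L, round(t0 * sample_rate) + 1L))
    step_delta[ic] <<- step_delta[ic] + amp
    i0 <- max(1L, floor((t0 - 5 * sigma_s) * sample_rate))
    i1 <- min(n, ceiling((t0 + 5 * sigma_s) * sample_rate))
    idx <- i0:i1
    hard <- as.numeric(idx >= ic)
    step_corr[idx] <<- step_corr[idx] +
      amp * (stats::pnorm((t_eeg[idx] - t0) / sigma_s) - hard)
  }
  for (j in seq_along(blink_t)) {
    s_b <- cfg$blink_sigma_ms / 1000 * blink_jit_s[j]
    i0 <- max(1L, floor((blink_t[j] - 5 * s_b) * sample_rate))
    i1 <- min(n, ceiling((blink_t[j] + 5 * s_b) * sample_rate))
    idx <- i0:i1
    veog[idx] <- veog[idx] + cfg$blink_amp * blink_jit_a[j] *
      exp(-(t_eeg[idx] - blink_t[j])^2 / (2 * s_b^2))
  }
  # 10%-of-peak-velocity crossings of the Gaussian-integral step sit at
  # +-sigma*sqrt(2*ln 10): 40 ms saccade duration for the default width
  sacc_dur <- 2 * sqrt(2 * log(10)) * sigma_s
  half <- sacc_dur / 2
  out_on <- exc_t                 # outward saccade onset
  out_c <- out_on + half          # step center (velocity max)
  out_fix <- out_on + sacc_dur    # offset = fixation onset
  in_on <- out_fix + dwell
  in_c <- in_on + half
  in_fix <- in_on + sacc_dur
  sgn <- ifelse(side == "right", 1, -1)
  for (j in seq_len(n_exc)) {
    a <- cfg$sacc_amp_uV[amp_class[j]] * sgn[j]
    add_step(out_c[j], a)
    add_step(in_c[j], -a)
  }
  pos <- cumsum(step_delta) + step_corr

  # --- contralateral alpha suppression before inward saccades ---------
  if (cfg$alpha_supp > 0) {
    for (j in seq_len(n_exc)) {
      # inward saccade direction is opposite the excursion side; the
      # suppressed hemisphere is contralateral to that direction, i.e. the
      # excursion side itself. left excursion -> inward rightward -> left hemi.
      w0 <- in_on[j] - 0.8; w1 <- in_on[j] - 0.05
      i0 <- max(1L, floor(w0 * sample_rate)); i1 <- min(n, ceiling(w1 * sample_rate))
      if (i1 <= i0) next
      idx <- i0:i1
      edge <- pmin(1, pmin(t_eeg[idx] - w0, w1 - t_eeg[idx]) / 0.1)
      fac <- 1 - cfg$alpha_supp * pmax(0, edge)
      if (side[j] == "left") supp_l[idx] <- supp_l[idx] * fac
      else supp_r[idx] <- supp_r[idx] * fac
    }
  }
  alpha_l_src <- alpha_l_carrier * env_alpha * supp_l
  alpha_r_src <- alpha_r_carrier * env_alpha * supp_r

  add_source <- function(src, tp) {
    w <- tp[ch_idx]
    nz <- which(w != 0)
    if (length(nz)) data[nz, ] <<- data[nz, , drop = FALSE] + outer(w[nz], src)
  }
  add_source(veog, topo$veog)
  add_source(pos, topo$heog)
  add_source(alpha_l_src, topo$alpha_left)
  add_source(alpha_r_src, topo$alpha_right)
  add_source(theta_src, topo$theta)

  # --- injected event-locked components -------------------------------
  sample_of <- function(t) pmin(n, pmax(1L, round(t * sample_rate) + 1L))
  load_at <- function(t) load_of_sample[sample_of(t)]
  add_wave <- function(tp, t0, t_ms, w) {
    smp <- round((t0 + t_ms / 1000) * sample_rate) + 1L
    ok <- smp >= 1L & smp <= n
    if (!any(ok)) return(invisible())
    wvec <- tp[ch_idx]
    nz <- which(wvec != 0)
    if (!length(nz)) return(invisible())
    data[nz, smp[ok]] <<- data[nz, smp[ok], drop = FALSE] +
      outer(wvec[nz], w[ok])
  }
  gms <- seq(-60, 60, by = 2)  # gaussian support grid, +-5 sigma for s=12
  blink_load <- load_at(blink_t)
  for (nm in names(cfg$components$blink)) {
    cc <- cfg$components$blink[[nm]]
    tg <- seq(cc$lat - 5 * cc$sigma, cc$lat + 5 * cc$sigma, by = 2)
    shape <- .gauss_wave(tg, cc$lat, cc$sigma)
    for (j in seq_along(blink_t)) {
      a <- cc$amp[blink_load[j]] + jit[paste0("blink.", nm)]
      add_wave(topo[[cc$cluster]], blink_t[j], tg, a * shape)
    }
  }
  fix_t <- c(out_fix, in_fix)
  fix_type <- rep(c("outward", "inward"), each = n_exc)
  fix_dir <- c(side, ifelse(side == "left", "right", "left"))
  fix_load <- load_at(fix_t)
  for (nm in names(cfg$components$fixation)) {
    cc <- cfg$components$fixation[[nm]]
    tg <- seq(cc$lat - 5 * cc$sigma, cc$lat + 5 * cc$sigma, by = 2)
    shape <- .gauss_wave(tg, cc$lat, cc$sigma)
    for (j in seq_along(fix_t)) {
      a <- cc$amp[fix_load[j], fix_type[j]] + jit[paste0("fixation.", nm)]
      add_wave(topo[[cc$cluster]], fix_t[j], tg, a * shape)
    }
  }
  sac_on <- c(out_on, in_on)
  sac_type <- fix_type
  sac_dir <- c(side, ifelse(side == "left", "right", "left"))
  sac_load <- load_at(sac_on)
  cnv <- cfg$components$saccade$CNV
  tg_cnv <- seq(-260, 0, by = 2)
  for (j in seq_along(sac_on)) {
    a <- cnv$amp[sac_load[j], sac_type[j]] + jit["saccade.CNV"]
    add_wave(topo[[cnv$cluster]], sac_on[j], tg_cnv, .cnv_wave(tg_cnv, a))
  }
  ton <- cfg$components$saccade$tonic_ERL
  tg_ton <- seq(-470, -10, by = 2)
  for (j in seq_along(sac_on)) {
    v1 <- ton$amp1[sac_load[j], sac_type[j]] + jit["saccade.tonic_ERL"]
    v2 <- ton$amp2[sac_load[j], sac_type[j]] + jit["saccade.tonic_ERL"]
    tp <- if (sac_dir[j] == "right") topo$lat_left else topo$lat_right
    add_wave(tp, sac_on[j], tg_ton, .tonic_wave(tg_ton, v1, v2))
  }
  pc <- cfg$components$fixation_lat$phasic_ERL
  tg_pc <- seq(55, 145, by = 2)
  for (j in seq_along(fix_t)) {
    a <- pc$amp[fix_load[j], fix_type[j]] + jit["fixation_lat.phasic_ERL"]
    tp <- if (fix_dir[j] == "right") topo$lat_left else topo$lat_right
    add_wave(tp, fix_t[j], tg_pc, .pc_wave(tg_pc, a))
  }

  # --- assemble -------------------------------------------------------
  trig100 <- attr(telemetry, "trigger_table")
  trig <- data.frame(sample = round(trig100$time_s * sample_rate),
                     distance_m = trig100$distance_m)
  rec <- new_recording(data, sample_rate, channels)
  rec <- attach_telemetry(rec, telemetry)
  rec$trigger_samples <- trig[trig$sample < n & trig$sample >= 0, ]

  events <- ocular_events(
    sample = c(sample_of(blink_t) - 1L, sample_of(sac_on) - 1L,
               sample_of(fix_t) - 1L),
    kind = c(rep("blink", length(blink_t)),
             rep("saccade_onset", length(sac_on)),
             rep("fixation_onset", length(fix_t))),
    direction = c(rep("none", length(blink_t)), sac_dir, fix_dir),
    sacc_type = c(rep("none", length(blink_t)), sac_type, fix_type),
    quality = 1,
    load = c(blink_load, sac_load, fix_load))

  gt <- list(events = events, segment_demand = segment_demand,
             injected_components = cfg$components,
             jitter = jit,
             sources = list(veog = veog, heog = pos,
                            alpha_left_env = env_alpha * supp_l,
                            alpha_right_env = env_alpha * supp_r),
             topographies = topo,
             timing = list(blink_t = blink_t, out_on = out_on, in_on = in_on,
                           out_fix = out_fix, in_fix = in_fix, dwell = dwell,
                           side = side, amp_class = amp_class,
                           sacc_dur = sacc_dur),
             config = cfg, seed = seed, sample_rate = sample_rate)
  list(recording = rec, ground_truth = gt)
}

# per-subject additive amplitude jitter, one draw per component
.component_jitter <- function(cfg) {
  nms <- c(paste0("blink.", names(cfg$components$blink)),
           paste0("fixation.", names(cfg$components$fixation)),
           "saccade.CNV", "saccade.tonic_ERL", "fixation_lat.phasic_ERL")
  setNames(rnorm(length(nms), 0, cfg$amp_jitter_sd), nms)
}

# rank-based terciles of a score vector (ascending thirds; ties broken by
# index). Returns "low"/"medium"/"high" where the highest scores get "high".
.tercile_labels <- function(neg_score) {
  n <- length(neg_score)
  ord <- order(neg_score, seq_len(n))
  sizes <- diff(floor(n * (0:3) / 3))
  lab <- rep(c("high", "medium", "low"), sizes)
  out <- character(n)
  out[ord] <- lab
  out
}

#' Simulate a multi-subject driving-EEG cohort
#'
#' All subjects drive the same route; telemetry (the individual drive) and
#' EEG are regenerated per subject from derived seeds.
#'
#' @param route A [simulate_route()] profile.
#' @param n_subjects Number of subjects.
#' @param seed Integer master seed.
#' @param subject A [subject_config()] shared by all subjects.
#' @param channels Optional channel subset to render.
#' @return List of per-subject lists (`recording`, `ground_truth`,
#'   `telemetry`).
#' @export
simulate_cohort <- function(route, n_subjects = 15, seed = 1,
                            subject = subject_config(),
                            channels = driveload_montage()) {
  lapply(seq_len(n_subjects), function(s) {
    tel <- simulate_telemetry(route, seed = (seed %% 10000L) * 100L + s)
    sim <- simulate_recording(route, tel, subject = subject,
                              seed = (seed %% 10000L) * 100L + 50L + s,
                              channels = channels)
    sim$telemetry <- tel
    sim
  })
}
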