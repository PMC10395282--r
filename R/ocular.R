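# Blink detection by Gaussian fits, saccade detection by velocity peaks and
# template correlation, and direction / inward-outward labelling — all on
# the activation traces of the ocular independent components.

#' Detect eye blinks by Gaussian fits
#'
#' Candidate peaks above a robust amplitude threshold are fit with a
#' Gaussian on a ±400-ms window (samples nearer to a different candidate
#' are excluded from the fit so adjacent blinks do not spoil each other).
#' Fits are retained iff R^2 >= `r2_min` and the fitted width lies in
#' `sigma_range_ms`; the event sample is the fitted center.
#'
#' @param v_trace Vertical-eye IC activation (numeric vector). Polarity is
#'   normalized internally so blink deflections are positive (majority sign
#'   of suprathreshold peaks).
#' @param sample_rate Hz.
#' @param threshold_k Robust threshold: median + `threshold_k` * MAD.
#' @param r2_min Minimum goodness of fit.
#' @param sigma_range_ms Accepted Gaussian widths (ms).
#' @return List with `events` ([ocular_events()], kind `"blink"`) and
#'   `fits` (data.frame amplitude/center/sigma_ms/r2 per retained blink).
#' @export
detect_blinks <- function(v_trace, sample_rate, threshold_k = 4,
                          r2_min = 0.9, sigma_range_ms = c(25, 150)) {
  n <- length(v_trace)
  if (sd(v_trace) < 1e-12) {
    warning("zero-variance vertical-eye trace; no blinks detected")
    return(list(events = ocular_events(integer(0), character(0)),
                fits = data.frame()))
  }
  thr <- median(v_trace) + threshold_k * mad(v_trace)
  thr_neg <- median(v_trace) - threshold_k * mad(v_trace)
  n_pos <- sum(diff(sign(diff(v_trace))) < 0 & v_trace[-c(1, n)] > thr)
  n_neg <- sum(diff(sign(diff(v_trace))) > 0 & v_trace[-c(1, n)] < thr_neg)
  x <- if (n_neg > n_pos) -v_trace else v_trace
  thr <- median(x) + threshold_k * mad(x)
  is_peak <- c(FALSE, diff(sign(diff(x))) < 0, FALSE) & x > thr
  cand <- which(is_peak)
  # noise makes many local maxima on one blink top: group candidates with
  # gaps under 50 ms (noise maxima recur every few samples, so a blink's
  # cloud never splits) and keep each group's largest sample
  if (length(cand) > 1) {
    grp <- cumsum(c(1, diff(cand) >= 0.05 * sample_rate))
    cand <- vapply(split(cand, grp), function(g) g[which.max(x[g])], 1L)
    cand <- unname(sort(cand))
  }
  if (!length(cand))
    return(list(events = ocular_events(integer(0), character(0)),
                fits = data.frame()))
  win <- round(0.4 * sample_rate)
  fit_one <- function(c0, y, restrict = FALSE) {
    idx <- max(1L, c0 - win):min(n, c0 + win)
    if (restrict && length(cand) > 1) {
      # first pass: keep only samples nearer to this candidate
      near <- vapply(idx, function(i) cand[which.min(abs(cand - i))], 1L)
      idx <- idx[near == c0]
    }
    tt <- (idx - c0) / sample_rate * 1000
    yy <- y[idx]
    df <- data.frame(tt = tt, yy = yy)
    fit <- tryCatch(
      minpack.lm::nlsLM(yy ~ A * exp(-(tt - mu)^2 / (2 * s^2)) + b,
                        data = df,
                        start = list(A = y[c0], mu = 0, s = 50,
                                     b = median(yy)),
                        lower = c(0, -200, 5, -Inf),
                        upper = c(Inf, 200, 400, Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    p <- coef(fit)
    r2 <- 1 - sum(residuals(fit)^2) / sum((yy - mean(yy))^2)
    data.frame(amplitude = p[["A"]],
               center = c0 + p[["mu"]] / 1000 * sample_rate,
               sigma_ms = p[["s"]], r2 = r2)
  }
  # first pass on the raw trace; second pass refits each candidate with the
  # other candidates' fitted Gaussians subtracted, so adjacent blinks do
  # not bias each other's center
  pass1 <- lapply(cand, fit_one, y = x, restrict = TRUE)
  fits <- lapply(seq_along(cand), function(i) {
    f <- pass1[[i]]
    if (is.null(f)) return(NULL)
    others <- which(vapply(pass1, Negate(is.null), TRUE))
    others <- setdiff(others, i)
    near <- others[abs(cand[others] - cand[i]) < 2L * win]
    if (!length(near)) return(f)
    y <- x
    idx <- max(1L, cand[i] - win):min(n, cand[i] + win)
    for (j in near) {
      fj <- pass1[[j]]
      y[idx] <- y[idx] - fj$amplitude *
        exp(-((idx - fj$center) / sample_rate * 1000)^2 /
              (2 * fj$sigma_ms^2))
    }
    fit_one(cand[i], y) %||% f
  })
  fits <- do.call(rbind, fits)
  if (is.null(fits) || !nrow(fits))
    return(list(events = ocular_events(integer(0), character(0)),
                fits = data.frame()))
  ok <- fits$r2 >= r2_min & fits$sigma_ms >= sigma_range_ms[1] &
    fits$sigma_ms <= sigma_range_ms[2]
  fits <- fits[ok, , drop = FALSE]
  # two candidates on one broad blink top converge to the same center:
  # keep the better fit of any pair closer than 150 ms
  if (nrow(fits) > 1) {
    fits <- fits[order(fits$center), , drop = FALSE]
    keep <- rep(TRUE, nrow(fits))
    for (i in seq_len(nrow(fits))[-1]) {
      prev <- max(which(keep[seq_len(i - 1)]))
      if (fits$center[i] - fits$center[prev] < 0.15 * sample_rate) {
        if (fits$r2[i] > fits$r2[prev]) keep[prev] <- FALSE else keep[i] <- FALSE
      }
    }
    fits <- fits[keep, , drop = FALSE]
  }
  smp <- pmin(n - 1L, pmax(0L, as.integer(round(fits$center)) - 1L))
  list(events = ocular_events(sample = smp,
                              kind = rep("blink", nrow(fits)),
                              quality = fits$r2),
       fits = fits)
}

# smoothed derivative (velocity) of a trace, units / s
.trace_velocity <- function(x, sample_rate, smooth_ms = 8) {
  k <- max(1L, round(smooth_ms / 1000 * sample_rate))
  if (k > 1) {
    kern <- rep(1 / k, k)
    xs <- as.numeric(stats::filter(x, kern, sides = 2))
    # hold the edge values instead of zeroing (a zero edge on a nonzero
    # trace would fabricate a huge velocity spike)
    na <- is.na(xs)
    xs[na] <- x[na]
    x <- xs
  }
  c(0, diff(x)) * sample_rate
}

#' Find saccade candidates from the horizontal-eye IC
#'
#' Local maxima of the absolute smoothed trace derivative above a robust
#' velocity threshold, with a refractory period.
#'
#' @param h_trace Horizontal-eye IC activation.
#' @param sample_rate Hz.
#' @param threshold_k Robust threshold: median(|v|) + k * MAD(|v|).
#' @param refractory_ms Minimum candidate separation (ms).
#' @return Integer vector of candidate samples (1-based, velocity maxima).
#' @export
find_saccade_candidates <- function(h_trace, sample_rate, threshold_k = 6,
                                    refractory_ms = 100) {
  v <- abs(.trace_velocity(h_trace, sample_rate))
  if (max(v) < 1e-12) return(integer(0))
  thr <- median(v) + threshold_k * mad(v)
  peaks <- which(c(FALSE, diff(sign(diff(v))) < 0, FALSE) & v > thr)
  if (!length(peaks)) return(integer(0))
  refr <- round(refractory_ms / 1000 * sample_rate)
  keep <- integer(0)
  last <- -Inf
  for (p in peaks[order(-v[peaks])]) {
    if (all(abs(p - keep) >= refr)) keep <- c(keep, p)
  }
  sort(keep)
}

#' Build saccade templates from candidate snippets
#'
#' Candidate snippets (centered on the velocity maximum) are grouped into
#' three amplitude classes by k-means on their peak-to-peak amplitude (seeded
#' deterministically with amplitude quantiles), averaged per class after
#' orienting each snippet positive-going, and unit-normalized. Templates
#' must be monotone over their central half-span (automated replacement for
#' a visual saccade-shape check); non-monotone templates raise a warning.
#'
#' @param h_trace Horizontal-eye IC activation.
#' @param candidates Candidate samples from [find_saccade_candidates()].
#' @param sample_rate Hz.
#' @param len_ms Template length (ms).
#' @return List of 3 templates, each a list with `waveform` (unit norm) and
#'   `amplitude_class` (`"small"`, `"medium"`, `"large"`) and `mean_p2p`.
#' @export
build_saccade_templates <- function(h_trace, candidates, sample_rate,
                                    len_ms = 200) {
  if (length(candidates) < 9)
    stop("need at least 9 saccade candidates to build templates; ",
         "record a longer stretch")
  half <- round(len_ms / 2000 * sample_rate)
  n <- length(h_trace)
  ok <- candidates - half >= 1 & candidates + half <= n
  candidates <- candidates[ok]
  snips <- t(vapply(candidates, function(c0)
    h_trace[(c0 - half):(c0 + half)], numeric(2 * half + 1)))
  # orient positive-going
  rising <- snips[, 2 * half + 1] > snips[, 1]
  snips[!rising, ] <- -snips[!rising, , drop = FALSE]
  snips <- snips - rowMeans(snips)
  p2p <- apply(snips, 1L, function(v) diff(range(v)))
  centers <- quantile(p2p, c(1, 3, 5) / 6, names = FALSE)
  if (diff(range(p2p)) < 1e-9 * max(p2p)) {
    warning("all saccade candidates have equal amplitude; ",
            "templates are degenerate")
    cl <- rep(1L, length(p2p))
    means <- rep(mean(p2p), 3)
    groups <- list(seq_along(p2p), seq_along(p2p), seq_along(p2p))
  } else {
    km <- kmeans(p2p, centers = matrix(unique(centers), ncol = 1))
    ord <- order(km$centers)
    cl <- match(km$cluster, ord)
    means <- km$centers[ord]
    groups <- split(seq_along(p2p), cl)
    # if fewer than 3 distinct clusters formed, reuse nearest
    groups <- lapply(1:3, function(k) groups[[min(k, length(groups))]])
    means <- means[pmin(1:3, length(means))]
  }
  labs <- c("small", "medium", "large")
  templates <- lapply(1:3, function(k) {
    wf <- colMeans(snips[groups[[k]], , drop = FALSE])
    wf <- wf / sqrt(sum(wf^2))
    # step-shape check: over the central half-span the cumulative drawdown
    # must stay below 5% of the template range (tolerates flat-span noise)
    core <- wf[(half - round(half / 2)):(half + round(half / 2))]
    core <- stats::filter(core, rep(1 / 3, 3))  # de-jitter before the check
    core <- core[!is.na(core)]
    drawdown <- max(cummax(core) - core)
    if (drawdown > 0.05 * diff(range(wf)))
      warning("template ", labs[k], " is not monotone over its central span")
    list(waveform = wf, amplitude_class = labs[k], mean_p2p = means[k])
  })
  templates
}

# rolling Pearson correlation of a template against a trace (template
# centered), via running sums
.rolling_cor <- function(x, w) {
  L <- length(w)
  n <- length(x)
  w <- w - mean(w)
  sw <- sqrt(sum(w^2))
  ones <- rep(1, L)
  sx <- as.numeric(stats::filter(x, ones, sides = 2))
  sxx <- as.numeric(stats::filter(x^2, ones, sides = 2))
  sxy <- as.numeric(stats::filter(x, rev(w), sides = 2))
  varx <- sxx - sx^2 / L
  r <- sxy / (sqrt(pmax(varx, 1e-12)) * sw)
  r[is.na(r)] <- 0
  r
}

#' Detect saccades by template correlation
#'
#' Velocity candidates (see [find_saccade_candidates()]) are confirmed
#' where the maximum absolute sliding correlation over the three templates
#' exceeds `r_min` (non-maximum suppression within `refractory_ms`).
#' Onset and offset are the crossings of 10% of peak velocity, measured on
#' the matched template (whose center is its velocity maximum) and anchored
#' at the correlation peak; the offset is emitted as a fixation-onset
#' event.
#'
#' @param h_trace Horizontal-eye IC activation.
#' @param templates From [build_saccade_templates()].
#' @param sample_rate Hz.
#' @param r_min Correlation threshold (default 0.8).
#' @param refractory_ms Non-maximum suppression window (ms).
#' @param candidates Optional velocity-candidate samples; recomputed from
#'   the trace when omitted with a permissive threshold (`candidate_k`) —
#'   the correlation gate supplies the specificity, so the velocity stage
#'   must not lose small-amplitude saccades.
#' @param candidate_k Robust-threshold multiplier for the internal
#'   candidate pass.
#' @return [ocular_events()] with paired `saccade_onset` / `fixation_onset`
#'   rows (`quality` = template correlation).
#' @export
detect_saccades <- function(h_trace, templates, sample_rate, r_min = 0.8,
                            refractory_ms = 100, candidates = NULL,
                            candidate_k = 3, amp_min_frac = 0.5) {
  n <- length(h_trace)
  if (is.null(candidates))
    candidates <- find_saccade_candidates(h_trace, sample_rate,
                                          threshold_k = candidate_k,
                                          refractory_ms = refractory_ms)
  rmat <- vapply(templates, function(tp) .rolling_cor(h_trace, tp$waveform),
                 numeric(n))
  r <- apply(abs(rmat), 1L, max)
  refr <- round(refractory_ms / 1000 * sample_rate)
  # confirm each velocity candidate at the best correlation peak nearby;
  # correlation is scale-invariant, so a local amplitude floor (relative to
  # the smallest template class) rejects step-shaped noise ripples
  w <- round(0.02 * sample_rate)
  half_t <- (length(templates[[1]]$waveform) - 1L) %/% 2L
  amp_floor <- amp_min_frac *
    min(vapply(templates, `[[`, 1.0, "mean_p2p"))
  keep <- integer(0)
  for (p0 in candidates) {
    i0 <- max(1L, p0 - w); i1 <- min(n, p0 + w)
    p <- i0 - 1L + which.max(r[i0:i1])
    a0 <- max(1L, p - half_t); a1 <- min(n, p + half_t)
    local_p2p <- diff(range(h_trace[a0:a1]))
    if (r[p] > r_min && local_p2p >= amp_floor &&
        all(abs(p - keep) >= refr)) keep <- c(keep, p)
  }
  if (!length(keep))
    return(ocular_events(integer(0), character(0)))
  keep <- sort(keep)
  # onset/offset: 10%-of-peak-velocity crossings, measured on the clean
  # matched template (whose center is its velocity maximum) and anchored at
  # the correlation peak. Raw per-sample crossings are unusable for the
  # small amplitude class once broadband noise rides on the trace.
  tpl_cross <- lapply(templates, function(tp) {
    w <- tp$waveform
    vt <- c(0, diff(w))
    vt <- as.numeric(stats::filter(vt, rep(1 / 3, 3), sides = 2))
    vt[is.na(vt)] <- 0
    vm <- which.max(abs(vt))
    lim <- 0.1 * abs(vt[vm])
    on <- vm
    while (on > 1L && abs(vt[on - 1L]) > lim) on <- on - 1L
    off <- vm
    while (off < length(vt) && abs(vt[off + 1L]) > lim) off <- off + 1L
    c(d_on = vm - on, d_off = off - vm, vm = vm)
  })
  best_tpl <- apply(abs(rmat), 1L, which.max)
  oo <- t(vapply(keep, function(p) {
    tc <- tpl_cross[[best_tpl[p]]]
    c(on = max(1L, p - tc[["d_on"]]),
      off = min(n, p + tc[["d_off"]]), r = r[p])
  }, c(on = 1, off = 1, r = 1)))
  ocular_events(
    sample = c(oo[, "on"], oo[, "off"]) - 1L,
    kind = rep(c("saccade_onset", "fixation_onset"), each = nrow(oo)),
    quality = rep(oo[, "r"], 2))
}

#' Label saccade direction and inward/outward type
#'
#' Direction is the sign of the position change between onset and offset
#' (positive trace = rightward once polarity is calibrated); a saccade is
#' outward if the offset is farther from the central fixation (the running
#' median of the trace) than the onset, inward otherwise. Saccades whose
#' eccentricity change is below 5% of their amplitude are left as type
#' `"none"`. Fixation-onset rows inherit direction and type from their
#' saccade.
#'
#' @param events Paired events from [detect_saccades()].
#' @param h_trace Horizontal-eye IC activation (calibrated polarity).
#' @param sample_rate Hz.
#' @param center_window_s Running-median window for the central fixation
#'   position (s); windows longer than the trace use the global median.
#' @return The events with `direction` and `sacc_type` filled in.
#' @export
label_saccades <- function(events, h_trace, sample_rate,
                           center_window_s = 600) {
  n <- length(h_trace)
  k <- round(center_window_s * sample_rate)
  center <- if (k >= n) rep(median(h_trace), n) else {
    k <- k + (1 - k %% 2)
    as.numeric(stats::runmed(h_trace, k))
  }
  ons <- which(events$kind == "saccade_onset")
  offs <- which(events$kind == "fixation_onset")
  sm <- round(0.004 * sample_rate)
  posat <- function(i) {
    idx <- max(1L, i - sm):min(n, i + sm)
    mean(h_trace[idx])
  }
  for (j in seq_along(ons)) {
    i_on <- events$sample[ons[j]] + 1L
    i_off <- events$sample[offs[j]] + 1L
    p_on <- posat(i_on); p_off <- posat(i_off)
    ctr <- center[i_on]
    dir <- if (p_off > p_on) "right" else "left"
    amp <- abs(p_off - p_on)
    decc <- abs(p_off - ctr) - abs(p_on - ctr)
    ty <- if (abs(decc) < 0.05 * amp) "none"
          else if (decc > 0) "outward" else "inward"
    events$direction[c(ons[j], offs[j])] <- dir
    events$sacc_type[c(ons[j], offs[j])] <- ty
  }
  events
}

#' Calibrate horizontal-eye IC polarity from its scalp pattern
#'
#' Returns +1 or -1 such that multiplying the activation by it makes
#' positive deflections rightward (topography weight at F7 minus F8
#' negative).
#'
#' @param ica An [decompose_ica()] result.
#' @param ic Index of the horizontal-eye IC.
#' @return +1 or -1.
#' @export
heog_polarity <- function(ica, ic) {
  ch <- ica$channel_names
  w <- ica$mixing[, ic]
  d <- w[match("F7", ch)] - w[match("F8", ch)]
  if (is.na(d)) stop("montage lacks F7/F8; cannot calibrate polarity")
  if (d < 0) 1 else -1
}
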