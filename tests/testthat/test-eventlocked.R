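# Epoching, grand averages, component measurement, jackknife scoring, and
# lateralized (contra - ipsi) derivations.

# tiny recording with the channels the measures need
flat_rec <- function(n_ch = 11, n = 20000, sr = 500) {
  new_recording(matrix(0, n_ch, n), sr,
                c("O1", "O2", "Oz", "Cz", "P7", "P8", "FC1", "FC2", "Fz",
                  "PO9", "PO10")[seq_len(n_ch)])
}

test_that("epoching windows, baselines and exclusions behave as stated", {
  rec <- flat_rec()
  rec$data[] <- 3  # constant offset everywhere
  ev <- ocular_events(c(50, 5000, 10000), "blink", load = "low")
  set <- epoch_events(rec, ev, "blink")
  # event at sample 50 leaves the window: dropped
  expect_equal(dim(set$data)[1], 2)
  expect_equal(set$dropped[["bounds"]], 1)
  expect_equal(length(set$times), 751)
  expect_equal(range(set$times), c(-500, 1000))
  # constant offset: baseline-corrected mean over the baseline window is 0
  bsel <- set$times >= -400 & set$times <= -200
  expect_lt(max(abs(set$data[, , bsel])), 1e-12)
  # all-zero after correction for a constant channel
  expect_lt(max(abs(set$data)), 1e-12)
  # events without load labels are dropped and counted
  ev2 <- ocular_events(c(5000, 10000), "blink", load = c("low", NA))
  set2 <- epoch_events(rec, ev2, "blink")
  expect_equal(dim(set2$data)[1], 1)
  expect_equal(set2$dropped[["no_load"]], 1)
  # baseline idempotence: re-baselining is a no-op
  rec$data[] <- rnorm(length(rec$data))
  set3 <- epoch_events(rec, ev, "blink")
  bsel3 <- which(set3$times >= -400 & set3$times <= -200)
  bl <- apply(set3$data[, , bsel3, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(bl)), 1e-10)
})

test_that("noiseless injected fixation waveform is recovered exactly", {
  sim <- clean_sim()
  gt <- sim$ground_truth
  set <- epoch_events(sim$recording, gt$events, "fixation")
  avg <- grand_average(set, by = c("load", "sacc_type"))
  # occipital P1 peak within a sample of its injected latency
  cl <- driveload_clusters()
  i <- which(avg$cells$load == "high" & avg$cells$sacc_type == "outward")
  wf <- apply(avg$avg[i, cl$occipital, , drop = FALSE], 3, mean)
  pk <- avg$times[which.max(wf)]
  expect_lt(abs(pk - 90), 4)
})

test_that("grand averages reduce noise like 1/sqrt(N) and conserve counts", {
  rec <- flat_rec()
  set.seed(71)
  rec$data[] <- rnorm(length(rec$data))
  smp <- seq(1000, 19000, by = 400)
  ev <- ocular_events(smp, "blink", load = "low")
  set <- epoch_events(rec, ev, "blink", baseline = NULL)
  avg <- grand_average(set, by = "load")
  expect_equal(sum(avg$cells$n_events), length(smp))
  rms1 <- sqrt(mean(set$data[1, 1, ]^2))
  rmsN <- sqrt(mean(avg$avg[1, 1, ]^2))
  expect_equal(rmsN, rms1 / sqrt(length(smp)), tolerance = 0.35)
  # two identical events average to themselves
  rec2 <- flat_rec()
  rec2$data[1, ] <- sin((1:20000) / 50)
  ev2 <- ocular_events(c(5000, 5000), "blink", load = "low")
  set2 <- epoch_events(rec2, ev2, "blink", baseline = NULL)
  avg2 <- grand_average(set2, by = "load")
  expect_equal(avg2$avg[1, 1, ], set2$data[1, 1, ])
})

test_that("component measurement takes signed extrema or window means on
          the cluster waveform", {
  rec <- flat_rec()
  sr <- 500
  times <- ((-250):500) / sr * 1000
  # -3 uV Gaussian trough at 100 ms on the occipital cluster
  tr <- -3 * exp(-(times - 100)^2 / (2 * 20^2))
  for (ch in c("O1", "O2", "Oz")) {
    idx <- 5000 + ((-250):500)
    rec$data[ch, idx] <- tr
  }
  ev <- ocular_events(5000 - 1, "blink", load = "low")  # 0-based
  set <- epoch_events(rec, ev, "blink")
  avg <- grand_average(set, by = "load")
  # unsmoothed: exact trough; default smoothing: known attenuation
  raw_spec <- component_measure("N1", c(20, 200), c("O1", "Oz", "O2"),
                                "negative", smooth_ms = 0)
  expect_equal(measure_component(avg, raw_spec)$value, -3,
               tolerance = 0.002)
  att <- mean(exp(-(seq(-12, 12, by = 2))^2 / (2 * 20^2)))
  n1 <- measure_component(avg, table_components("blink")$N1)
  expect_equal(n1$value, -3 * att, tolerance = 0.01)
  # flat zero waveform: all components 0 (occipital clusters available)
  rec0 <- flat_rec()
  set0 <- epoch_events(rec0, ev, "blink")
  avg0 <- grand_average(set0, by = "load")
  for (sp in table_components("blink")[c("N1", "P2_occipital", "N2")])
    expect_equal(measure_component(avg0, sp)$value, 0)
  # window mean of a linear ramp a*t equals a * window midpoint
  recr <- flat_rec()
  a <- 0.01
  recr$data["Cz", ] <- a * ((seq_len(20000) - 5000) / sr * 1000)
  setr <- epoch_events(recr, ev, "blink", baseline = NULL)
  avgr <- grand_average(setr, by = "load")
  cnv <- measure_component(avgr, component_measure("CNV", c(-200, -50),
                                                   "Cz", "mean"))
  expect_equal(cnv$value, a * (-125), tolerance = 1e-6)
  # window outside the epoch errors
  expect_error(measure_component(avgr, component_measure("x", c(900, 1200),
                                                         "Cz", "mean")),
               "outside")
})

test_that("jackknife peaks: degenerate equality, precondition, and the
          rescaled-F equivalence for mean amplitudes", {
  # identical subjects: every leave-one-out value equals the full average
  rec <- flat_rec()
  tr <- 2 * exp(-((((-250):500) / 0.5) - 100)^2 / (2 * 30^2))
  sub_avg <- list()
  sim <- clean_sim()
  set <- epoch_events(sim$recording, sim$ground_truth$events, "blink")
  avg <- grand_average(set, by = "load")
  for (s in 1:5) sub_avg[[s]] <- avg
  spec <- table_components("blink")$P2_occipital
  jk <- jackknife_peaks(sub_avg, spec)
  full <- measure_component(avg, spec)
  for (s in 1:5)
    expect_equal(jk$value[jk$subject == s],
                 full$value[match(jk$load[jk$subject == s], full$load)],
                 tolerance = 1e-12)
  expect_error(jackknife_peaks(sub_avg[1:2], spec), "3 subjects")
  # mean-amplitude measures: jackknife-corrected F equals conventional F
  set.seed(72)
  n <- 15
  vals <- matrix(rnorm(n * 3, rep(c(1, 1.4, 1.8), each = n), 0.5), n, 3)
  fac <- data.frame(load = c("low", "medium", "high"))
  conv <- rm_anova(vals, fac)
  loo <- t(vapply(seq_len(n), function(s) colMeans(vals[-s, ]), numeric(3)))
  jkF <- rm_anova(loo, fac, jackknife = TRUE)
  expect_equal(jkF$F, conv$F, tolerance = 0.01)
})

test_that("contra-ipsi differencing is zero for symmetric data, negates
          under direction flips, and recovers injected lateralization", {
  rec <- flat_rec()
  set.seed(73)
  common <- rnorm(20000)
  rec$data["P7", ] <- common
  rec$data["P8", ] <- common
  ev <- ocular_events(c(4000, 8000), "fixation_onset",
                      direction = c("left", "right"),
                      sacc_type = "outward", load = "low")
  set <- epoch_events(rec, ev, "fixation")
  lat <- contra_ipsi(set, pairs = list(c("P7", "P8")))
  expect_lt(max(abs(lat$data)), 1e-12)
  # -1 uV contralateral deflection covering 80-120 ms for a right-directed
  # event (event sample 8000 0-based = column 8001)
  rec2 <- flat_rec()
  times_idx <- 8001 + (40:60)
  rec2$data["P7", times_idx] <- -1   # left hemisphere = contra for "right"
  set2 <- epoch_events(rec2, ev, "fixation")
  lat2 <- contra_ipsi(set2, pairs = list(c("P7", "P8")))
  sel <- lat2$times >= 80 & lat2$times <= 120
  expect_equal(mean(lat2$data[2, sel]), -1, tolerance = 1e-9)
  # flipping the direction flips the sign
  ev3 <- ev; ev3$direction <- c("right", "left")
  set3 <- epoch_events(rec2, ev3, "fixation")
  lat3 <- contra_ipsi(set3, pairs = list(c("P7", "P8")))
  expect_equal(lat3$data[2, ], -lat2$data[2, ], tolerance = 1e-12)
  # direction "none" events are excluded
  ev4 <- ev; ev4$direction <- c("none", "right")
  lat4 <- contra_ipsi(epoch_events(rec2, ev4, "fixation"),
                      pairs = list(c("P7", "P8")))
  expect_equal(nrow(lat4$data), 1)
})

test_that("lateralized measures recover the generator's inward/outward
          pattern on noiseless data", {
  sim <- clean_sim()
  gt <- sim$ground_truth
  fset <- epoch_events(sim$recording, gt$events, "fixation")
  sset <- epoch_events(sim$recording, gt$events, "saccade",
                       baseline = NULL)
  lm_ <- lateralized_measures(fset, sset)
  cnv_in <- mean(lm_$value[lm_$component == "CNV" &
                             lm_$sacc_type == "inward"])
  cnv_out <- mean(lm_$value[lm_$component == "CNV" &
                              lm_$sacc_type == "outward"])
  expect_lt(cnv_in, cnv_out)      # CNV larger (more negative) inward
  t1_in <- mean(lm_$value[lm_$component == "tonic_ERL1" &
                            lm_$sacc_type == "inward"])
  t1_out <- mean(lm_$value[lm_$component == "tonic_ERL1" &
                             lm_$sacc_type == "outward"])
  expect_lt(t1_in, t1_out)        # tonic ERL more negative inward
  ph_out <- mean(lm_$value[lm_$component == "phasic_ERL" &
                             lm_$sacc_type == "outward"])
  ph_in <- mean(lm_$value[lm_$component == "phasic_ERL" &
                            lm_$sacc_type == "inward"])
  expect_gt(ph_out, ph_in)        # N1pc larger for outward
  # CNV of flat data is 0
  rec0 <- flat_rec()
  ev0 <- ocular_events(c(4000, 8000), "saccade_onset",
                       direction = "left", sacc_type = "inward",
                       load = "low")
  ev0f <- ocular_events(c(4020, 8020), "fixation_onset",
                        direction = "left", sacc_type = "inward",
                        load = "low")
  lm0 <- lateralized_measures(
    epoch_events(rec0, rbind(ev0f), "fixation"),
    epoch_events(rec0, rbind(ev0), "saccade", baseline = NULL))
  expect_true(all(lm0$value[is.finite(lm0$value)] == 0))
})

test_that("event load labels come from the segment containing the sample", {
  lm_ <- structure(data.frame(segment = 0:9,
                              score = rnorm(10),
                              load = rep(c("low", "high"), 5)),
                   class = c("load_map", "data.frame"))
  dist <- seq(0, 99.99, length.out = 2000)  # 100 m over 2000 samples
  ev <- ocular_events(c(10, 1999), "blink")
  ev2 <- label_event_load(ev, dist, lm_)
  expect_equal(ev2$load, c("low", "high"))
})
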