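# Position morphing, spatial segmentation, wavelet band power, task-load
# terciles and behavioral summaries.

test_that("position reconstruction is exact at triggers, also under
          velocity bias, and idempotent for consistent input", {
  sr <- 500
  n <- sr * 120
  v <- rep(90, n)  # 25 m/s
  true_d <- (seq_len(n) - 1) * 25 / sr
  trig <- data.frame(sample = c(500L, 20000L, 50000L),
                     distance_m = true_d[c(501, 20001, 50001)])
  d <- reconstruct_position(v, sr, trig)
  expect_lt(max(abs(d[trig$sample + 1] - trig$distance_m)), 1e-9)
  expect_lt(max(abs(d - true_d)), 0.1)
  # +5% multiplicative bias: triggers exact, mid-interval error bounded
  d_b <- reconstruct_position(v * 1.05, sr, trig)
  expect_lt(max(abs(d_b[trig$sample + 1] - trig$distance_m)), 1e-9)
  expect_lt(max(abs(d_b - true_d)[500:50001]), 0.05 * 30000 * 0.05)
  # idempotence: re-deriving a velocity consistent with d changes nothing
  v_c <- c(diff(d), 25 / sr * 1) * sr * 3.6
  d2 <- reconstruct_position(v_c, sr, trig)
  expect_lt(max(abs(d2 - d)), 1e-6)
  expect_true(all(diff(d_b) >= 0))
  expect_error(reconstruct_position(v, sr,
                                    data.frame(sample = c(1L, 10L),
                                               distance_m = c(5, 2))),
               "increasing")
  expect_error(reconstruct_position(v, sr,
                                    data.frame(sample = 1L,
                                               distance_m = 5)),
               "2 trigger")
})

test_that("segmentation covers the track in half-open 10-m bins", {
  # 50-km drive at constant speed: exactly 5000 segments
  d <- seq(0, 50000, length.out = 500001)
  segs <- segment_track(d, 10, 50000)
  expect_equal(nrow(segs), 5000)
  expect_equal(segs$start_m, seq(0, 49990, by = 10))
  # every in-range sample in exactly one segment
  expect_equal(sum(segs$n_samples), sum(d < 50000))
  # 10-m drive: one segment
  expect_equal(nrow(segment_track(seq(0, 10, by = 0.1), 10, 10)), 1)
  expect_warning(s0 <- segment_track(seq(0, 5, by = 0.1), 10, 5),
                 "shorter")
  expect_equal(nrow(s0), 0)
  # arbitrary speed profile: boundaries match a brute-force scan
  set.seed(31)
  d2 <- cumsum(runif(5000, 0, 0.08))
  segs2 <- segment_track(d2, 10)
  bf_first <- vapply(seq_len(nrow(segs2)), function(i)
    which(d2 >= segs2$start_m[i] & d2 < segs2$end_m[i])[1] - 1L, 1L)
  expect_equal(segs2$first_sample, unname(bf_first))
})

test_that("Morlet power peaks at the stimulus frequency and scales
          quadratically", {
  sr <- 250
  t <- (0:(30 * sr - 1)) / sr
  x <- rbind(sin(2 * pi * 10 * t))
  rownames(x) <- "O1"
  pw <- cwt_power(x, sample_rate = sr)
  freqs <- attr(pw, "freqs")
  mid <- seq(5 * sr, 25 * sr)
  prof <- apply(pw[1, , mid], 1, mean)
  expect_equal(freqs[which.max(prof)], 10)
  expect_equal(dim(pw)[2], 29)
  expect_equal(freqs, seq(2, 30, by = 1))
  # zero signal -> zero power; doubling amplitude -> 4x power
  expect_equal(max(cwt_power(rbind(O1 = rep(0, 3000)),
                             sample_rate = sr)), 0)
  pw2 <- cwt_power(2 * x, sample_rate = sr)
  expect_equal(pw2[1, , mid], 4 * pw[1, , mid], tolerance = 1e-6)
  expect_error(cwt_power(rbind(O1 = rnorm(100)), sample_rate = sr),
               "shorter")
})

test_that("z-transform standardizes each trace and is affine-invariant", {
  set.seed(32)
  pw <- array(abs(rnorm(2 * 3 * 1000)), dim = c(2, 3, 1000),
              dimnames = list(c("O1", "O2"), NULL, NULL))
  z <- zscore_trace(pw)
  for (k in 1:2) for (j in 1:3) {
    expect_lt(abs(mean(z[k, j, ])), 1e-10)
    expect_lt(abs(sd(z[k, j, ]) - 1), 1e-10)
  }
  z2 <- zscore_trace(pw * 3 + 7)
  expect_equal(z2[, , ], z[, , ], tolerance = 1e-10)
  pw[1, 2, ] <- 5
  expect_error(zscore_trace(pw), "zero-variance.*O1.*2")
})

test_that("segment averaging and the ±50-m smoother behave like the stated
          convolution", {
  n_seg <- 40
  d <- seq(0, n_seg * 10 - 0.01, length.out = 4000)
  segs <- segment_track(d, 10, n_seg * 10)
  # constant input stays constant
  pw <- array(2, dim = c(1, 1, 4000), dimnames = list("O1", NULL, NULL))
  sv <- segment_average_and_smooth(pw, segs)
  expect_equal(as.vector(sv[1, 1, ]), rep(2, n_seg))
  # unit impulse at one segment spreads 1/11 over the 11-segment window
  z <- array(0, dim = c(1, 1, 4000), dimnames = list("O1", NULL, NULL))
  sel <- (segs$first_sample[20]:segs$last_sample[20]) + 1
  z[1, 1, sel] <- 1
  sv2 <- segment_average_and_smooth(z, segs)
  expect_equal(as.vector(sv2[1, 1, 15:25]), rep(1 / 11, 11),
               tolerance = 1e-12)
  expect_equal(unname(sv2[1, 1, 14]), 0)
  # edge windows shrink symmetrically: segment 1 averages segments 1 only,
  # segment 2 averages 1..3, ...
  z3 <- array(0, dim = c(1, 1, 4000), dimnames = list("O1", NULL, NULL))
  z3[1, 1, (segs$first_sample[1]:segs$last_sample[1]) + 1] <- 1
  sv3 <- segment_average_and_smooth(z3, segs)
  expect_equal(unname(sv3[1, 1, 1]), 1)
  expect_equal(unname(sv3[1, 1, 2]), 1 / 3)
  expect_equal(unname(sv3[1, 1, 3]), 1 / 5)
})

test_that("cluster band power equals a brute-force mean over the listed
          channels and bins", {
  cl <- driveload_clusters()
  chans <- unique(c(cl$frontal_theta, cl$posterior_alpha))
  set.seed(33)
  sv <- array(rnorm(length(chans) * 29 * 20),
              dim = c(length(chans), 29, 20),
              dimnames = list(chans, NULL, NULL))
  attr(sv, "freqs") <- seq(2, 30)
  sc <- band_cluster_power(sv)
  bf_theta <- apply(sv[cl$frontal_theta, which(2:30 >= 4 & 2:30 <= 7) +
                         0, , drop = FALSE], 3, mean)
  th_bins <- which(seq(2, 30) >= 4 & seq(2, 30) <= 7)
  al_bins <- which(seq(2, 30) >= 8 & seq(2, 30) <= 12)
  bf_theta <- apply(sv[cl$frontal_theta, th_bins, , drop = FALSE], 3, mean)
  bf_alpha <- apply(sv[cl$posterior_alpha, al_bins, , drop = FALSE], 3, mean)
  expect_equal(sc$theta_z, bf_theta, tolerance = 1e-12)
  expect_equal(sc$alpha_z, bf_alpha, tolerance = 1e-12)
  expect_equal(sc$score, bf_alpha - bf_theta, tolerance = 1e-12)
  # uniform power: theta == alpha
  sv2 <- array(1, dim = dim(sv), dimnames = dimnames(sv))
  attr(sv2, "freqs") <- seq(2, 30)
  sc2 <- band_cluster_power(sv2)
  expect_equal(sc2$score, rep(0, 20))
  expect_error(band_cluster_power(sv[1:3, , ]), "missing cluster")
})

test_that("tercile assignment partitions segments with balanced counts and
          deterministic tie-breaks", {
  # strictly decreasing score: first third low, last third high
  sc <- seq(3000, 1)
  lm_ <- assign_task_load(rbind(sc))
  expect_equal(lm_$load[1:1000], rep("low", 1000))
  expect_equal(lm_$load[2001:3000], rep("high", 1000))
  # 5000 segments: counts in {1666, 1667}
  set.seed(34)
  lm2 <- assign_task_load(rbind(rnorm(5000)))
  expect_true(all(table(lm2$load) %in% c(1666, 1667)))
  # ties broken by segment index, deterministically
  lm3a <- assign_task_load(rbind(rep(1, 9)))
  lm3b <- assign_task_load(rbind(rep(1, 9)))
  expect_identical(lm3a$load, lm3b$load)
  expect_true(all(table(lm3a$load) == 3))
  # NaN segments stay unassigned
  v <- rnorm(30); v[5] <- NA
  lm4 <- assign_task_load(rbind(v, v))
  expect_true(is.na(lm4$load[5]))
  expect_equal(sum(is.na(lm4$load)), 1)
  # across-subject median is what is classified
  s1 <- c(1, 2, 3, 4, 5, 6); s2 <- c(6, 5, 4, 3, 2, 1); s3 <- c(1, 2, 3, 4, 5, 6)
  lm5 <- assign_task_load(rbind(s1, s2, s3))
  expect_equal(lm5$score, apply(rbind(s1, s2, s3), 2, median))
})

test_that("behavioral summaries follow the generator couplings", {
  sim <- small_sim()
  gt <- sim$ground_truth
  rec <- sim$recording
  dist <- approx(sim$telemetry$time_s, sim$telemetry$distance_m,
                 (seq_len(ncol(rec$data)) - 1) / 500, rule = 2)$y
  segs <- segment_track(dist, 10, sim$route$total_distance)
  lm_ <- gt$segment_demand
  names(lm_)[names(lm_) == "demand"] <- "score"
  beh <- summarize_behavior(rec, dist, segs, lm_, gt$events)
  expect_equal(beh$load, c("low", "medium", "high"))
  # velocity decreases, steering acceleration increases with load
  expect_gt(beh$velocity_kmh[1], beh$velocity_kmh[3])
  expect_lt(beh$steering_acc[1], beh$steering_acc[3])
  # no events -> zero rates
  beh0 <- summarize_behavior(rec, dist, segs, lm_,
                             ocular_events(integer(0), character(0)))
  expect_true(all(beh0$blinks_min == 0))
  expect_true(all(beh0$saccades_out_min == 0))
  # constant velocity everywhere -> equal per-load means
  rec2 <- rec
  rec2$telemetry$velocity_kmh <- 90
  beh2 <- summarize_behavior(rec2, dist, segs, lm_, gt$events)
  expect_true(all(abs(beh2$velocity_kmh - 90) < 1e-9))
})

test_that("end-to-end load recovery beats 90% on the desk cohort and the
          band shortcut equals the full grid", {
  sim <- small_sim()
  tp <- trackload_pipeline(sim$recording,
                           max_distance = sim$route$total_distance,
                           downsample = 8)
  tpf <- trackload_pipeline(sim$recording,
                            max_distance = sim$route$total_distance,
                            downsample = 8, frequencies = "full")
  expect_equal(tp$scores$score, tpf$scores$score, tolerance = 1e-12)
  # the pipeline's fused averaging equals the composed modular operations
  pw <- cwt_power(sim$recording,
                  channels = dimnames(sim$recording$data)[[1]],
                  downsample = 8)
  dist <- reconstruct_position(sim$recording$telemetry$velocity_kmh, 500,
                               sim$recording$trigger_samples)
  segs <- segment_track(dist[seq(1, length(dist), by = 8)], 10,
                        sim$route$total_distance)
  sv <- segment_average_and_smooth(zscore_trace(pw), segs)
  sc <- band_cluster_power(sv)
  expect_equal(tp$scores$score, sc$score, tolerance = 1e-12)
  # single subject is noisier; the multi-subject criterion lives in the
  # acceptance suite. Here: strong positive association with demand rank.
  gt <- sim$ground_truth$segment_demand
  expect_lt(cor(tp$scores$score, gt$demand, use = "complete.obs"), -0.5)
})
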