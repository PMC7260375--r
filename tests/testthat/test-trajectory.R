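minjerk_recording <- function(T = 1.2, L = 0.25, fs = 1000) {
  t <- seq(0, T + 1, by = 1 / fs)
  tau <- pmin(1, pmax(0, (t - 0.5) / T))
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  pos <- cbind(L * s, 0, 0)
  recording(t, pos, rep(0.3, length(t)), integer(length(t)), default_board())
}

test_that("preprocessing: constant position has zero velocity and jerk", {
  t <- seq(0, 2, by = 1e-3)
  rec <- recording(t, cbind(0.1, 0.2, 0.05)[rep(1, length(t)), ],
                   rep(0.3, length(t)), integer(length(t)), default_board())
  pre <- preprocess(rec)
  expect_lt(max(abs(pre$v)), 1e-9)
  expect_lt(max(abs(pre$j)), 1e-6)
})

test_that("2 Hz sinusoid: velocity amplitude within 2% of 2*pi*f*A", {
  fs <- 1000; A <- 0.05; f0 <- 2
  t <- seq(0, 5, by = 1 / fs)
  rec <- recording(t, cbind(A * sin(2 * pi * f0 * t), 0, 0),
                   rep(0.3, length(t)), integer(length(t)), default_board())
  pre <- preprocess(rec)
  vamp <- max(pre$v[1000:4000])
  expect_lt(abs(vamp - 2 * pi * f0 * A) / (2 * pi * f0 * A), 0.02)
})

test_that("a 20 Hz component is attenuated by more than 20 dB", {
  fs <- 1000
  t <- seq(0, 4, by = 1 / fs)
  x <- 0.02 * sin(2 * pi * 20 * t)
  y <- metricsieve:::lowpass8(x, fs)
  mid <- 1000:3000
  expect_lt(max(abs(y[mid])) / 0.02, 10^(-20 / 20))
})

test_that("dimensionless jerk: minimum-jerk optimum 720, dilation invariant", {
  fs <- 1000
  for (T in c(0.8, 1.6)) for (L in c(0.1, 0.3)) {
    tau <- seq(0, 1, by = 1 / (T * fs))
    j <- L / T^3 * (60 - 360 * tau + 360 * tau^2)
    expect_equal(dimensionless_jerk(j, fs, L), 720, tolerance = 1e-3)
  }
  expect_equal(log_jerk(0.1 / 1^3 * (60 - 360 * seq(0, 1, 1e-3) +
                                       360 * seq(0, 1, 1e-3)^2), 1000, 0.1),
               log(720), tolerance = 1e-4)
  expect_true(is.na(dimensionless_jerk(rnorm(100), 1000, 0)))
})

test_that("SPARC is non-positive and degrades with submovements", {
  fs <- 1000
  tau <- seq(0, 1, by = 1 / fs)
  v1 <- 30 * tau^2 * (1 - tau)^2
  s1 <- sparc(v1, fs)
  expect_lte(s1, 0)
  # superimpose a delayed second submovement
  v2 <- v1 + 0.6 * c(rep(0, 600), v1[1:(length(v1) - 600)])
  s2 <- sparc(v2, fs)
  expect_lt(s2, s1)
  # and a third makes it worse again
  v3 <- v2 + 0.4 * c(rep(0, 300), v1[1:(length(v1) - 300)])
  expect_lt(sparc(v3, fs), s2)
})

test_that("velocity-peak counting uses prominence", {
  tau <- seq(0, 1, by = 1e-3)
  v <- 30 * tau^2 * (1 - tau)^2
  expect_equal(metricsieve:::count_velocity_peaks(v), 1)
  v2 <- v * (1 + 0.001 * sin(200 * tau))   # sub-prominence ripples ignored
  expect_equal(metricsieve:::count_velocity_peaks(v2), 1)
  v3 <- c(v, 0.6 * v[-1])   # two temporally separated submovements
  expect_gte(metricsieve:::count_velocity_peaks(v3), 2)
})

test_that("minimum-jerk transport: one peak, time-to-peak 0.5, straight path", {
  g <- gen_recording(pegs = 1:2, seed = 1)
  pre <- preprocess(g$recording)
  seg <- segment_phases(g$recording, pre)
  km <- kinematic_metrics(pre, seg, g$recording$geometry, 2)
  expect_equal(km$num_velocity_peaks_tp, 1)
  expect_equal(km$time_to_max_velocity_tp, 0.5, tolerance = 0.02)
  expect_equal(km$dist_to_max_velocity_tp, 0.5, tolerance = 0.02)
  expect_equal(km$path_length_ratio_tp, 1, tolerance = 1e-3)
  expect_lte(km$path_length_ratio_tp, 1 + 1e-9)
  expect_gt(km$velocity_max_tp, km$velocity_mean_tp)
  expect_gt(km$throughput_tp, 0)
  # straight path: negligible trajectory error and initial angle
  expect_lt(km$trajectory_error_max_tp, 1e-4)
  expect_lt(km$initial_mov_angle_t3_tp, 2)
})

test_that("semicircular path has length ratio 2/pi", {
  fs <- 1000
  t <- seq(0, 3, by = 1 / fs)
  theta <- pi * pmin(1, pmax(0, (t - 0.5) / 2))
  rec <- recording(t, cbind(0.1 * cos(theta), 0.1 * sin(theta), 0),
                   rep(0.3, length(t)), integer(length(t)), default_board())
  pre <- preprocess(rec)
  mov <- which(pre$v > 0.005)
  shortest <- sqrt(sum((pre$position[max(mov), ] - pre$position[min(mov), ])^2))
  covered <- pre$d[max(mov)] - pre$d[min(mov)]
  expect_equal(shortest / covered, 2 / pi, tolerance = 0.01)
})

test_that("submovement injection strictly worsens SPARC and jerk", {
  g1 <- gen_recording(pegs = 1:2, seed = 3)
  g2 <- gen_recording(pegs = 1:2,
                      submovement = list(peg = 2, amplitude = 0.03, at = 0.55),
                      seed = 3)
  p1 <- preprocess(g1$recording); p2 <- preprocess(g2$recording)
  k1 <- kinematic_metrics(p1, segment_phases(g1$recording, p1),
                          g1$recording$geometry, 2)
  k2 <- kinematic_metrics(p2, segment_phases(g2$recording, p2),
                          g2$recording$geometry, 2)
  expect_lt(k2$sparc_tp, k1$sparc_tp)
  expect_gt(k2$jerk_tp, k1$jerk_tp)
})

test_that("scripted recordings are segmented within 50 ms of ground truth", {
  g <- gen_recording(pegs = 1:3, seed = 1)
  pre <- preprocess(g$recording)
  seg <- segment_phases(g$recording, pre)
  expect_lt(seg_worst_err(g, pre, seg), 0.05)
  # robust to measurement noise
  gn <- gen_recording(pegs = 1:3, pos_noise_sd = 3e-4, force_noise_sd = 0.05,
                      seed = 4)
  pn <- preprocess(gn$recording)
  expect_lt(seg_worst_err(gn, pn, segment_phases(gn$recording, pn)), 0.05)
  # a recording that never reaches the force threshold has no transports
  rec0 <- gen_recording(pegs = 1, seed = 2)$recording
  rec0$grip_force <- pmin(rec0$grip_force, 1.5)
  rec0$active_peg <- integer(length(rec0$time))
  seg0 <- segment_phases(rec0)
  expect_equal(sum(seg0$phase == "transport"), 0)
})

test_that("grip-force metrics: constant hold, sigmoid rise, drops", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  rec <- recording(t, cbind(0.1, 0, 0)[rep(1, length(t)), ],
                   rep(5, length(t)), rep(1L, length(t)), default_board())
  pre <- preprocess(rec)
  idx <- 200:1800
  expect_equal(mean(pre$force[idx]), 5, tolerance = 1e-6)
  expect_lt(mean(abs(pre$force_rate[idx])), 1e-6)
  expect_equal(metricsieve:::count_rate_extrema(pre$force_rate[idx]), 0)
  # one smooth sigmoidal rise -> one rate peak inside the buildup interval
  g <- gen_recording(pegs = 1:2, seed = 5)
  pg <- preprocess(g$recording)
  sg <- segment_phases(g$recording, pg)
  kn <- kinetic_metrics(pg, sg, g$recording$geometry, 2)
  expect_equal(kn$gf_rate_num_peaks_buildup, 1)
  expect_gt(kn$gf_buildup_duration, 0.1)
  expect_gt(kn$gf_mean_tp, 2)
  # scripted mid-transport dip -> one dropped peg, only for that peg
  gd <- gen_recording(pegs = 1:3, drops = 2, seed = 6)
  pd <- preprocess(gd$recording)
  sd_ <- segment_phases(gd$recording, pd)
  expect_equal(kinetic_metrics(pd, sd_, gd$recording$geometry, 2)$dropped_pegs, 1)
  expect_equal(kinetic_metrics(pd, sd_, gd$recording$geometry, 1)$dropped_pegs, 0)
})

test_that("metrics are stable under downsampling to 250 Hz", {
  g <- gen_recording(pegs = 2, seed = 7)
  rec <- g$recording
  keep <- seq(1, length(rec$time), by = 4)
  rec250 <- recording(rec$time[keep], rec$position[keep, ],
                      rec$grip_force[keep], rec$active_peg[keep],
                      rec$geometry)
  k1k <- kinematic_metrics(pre <- preprocess(rec),
                           segment_phases(rec, pre), rec$geometry, 2)
  k250 <- kinematic_metrics(pre2 <- preprocess(rec250),
                            segment_phases(rec250, pre2), rec250$geometry, 2)
  for (m in c("path_length_ratio_tp", "velocity_max_tp", "time_to_max_velocity_tp"))
    expect_equal(k250[[m]], k1k[[m]], tolerance = 0.02)
})

test_that("recordings round-trip through the delimited-text writer", {
  g <- gen_recording(pegs = 1, seed = 8)
  dir <- withr::local_tempdir()
  sp <- file.path(dir, "rec.csv"); gp <- file.path(dir, "geom.yaml")
  write_recording(g$recording, sp, gp)
  rec2 <- read_recording(sp, gp)
  expect_equal(rec2$position, g$recording$position, tolerance = 1e-6)
  expect_identical(rec2$active_peg, g$recording$active_peg)
  expect_equal(rec2$geometry$tolerance, 0.003)
})

test_that("full observation extraction emits aggregate-ready rows", {
  obs <- extract_observations(gen_recording(pegs = 1:3, seed = 9)$recording,
                              subject_id = "sx", side = "left")
  expect_true(all(c("subject_id", "side", "session", "repetition", "peg",
                    "metric_name", "value") %in% names(obs)))
  expect_true(all(is.finite(obs$value)))
  expect_equal(unique(obs$subject_id), "sx")
  expect_gt(obs$value[obs$metric_name == "task_completion_time"], 0)
  expect_equal(obs$value[obs$metric_name == "number_of_dropped_pegs"], 0)
  agg <- aggregate_trials(obs)
  expect_true("path_length_ratio_tp" %in% agg$metric_name)
})
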