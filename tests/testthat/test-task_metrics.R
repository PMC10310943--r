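test_that("bcea matches the determinant form and handles degenerate input", {
  set.seed(101)
  pts <- cbind(rnorm(500), 0.5 * rnorm(500) + 0.3 * rnorm(500))
  for (P in c(0.68, 0.95)) {
    # independent formulation: pi * chi2_2(P) * sqrt(det(S))
    expect_equal(bcea(pts, P),
                 pi * (-2 * log(1 - P)) * sqrt(det(cov(pts))),
                 tolerance = 1e-12)
  }
  expect_equal(bcea(matrix(1, 5, 2), 0.68), 0)
  expect_error(bcea(pts[1:2, ], 0.68), "3 points")
  expect_error(bcea(pts, 1.2), "P must be")
})

test_that("bcea Monte-Carlo coverage is within 0.02 of nominal", {
  set.seed(202)
  n <- 10000
  x <- cbind(rnorm(n), rnorm(n) * 1.4 + 0.5 * rnorm(n))
  S <- cov(x)
  xc <- sweep(x, 2, colMeans(x))
  mahal <- rowSums((xc %*% solve(S)) * xc)
  for (P in c(0.68, 0.95)) {
    inside <- mean(mahal <= -2 * log(1 - P))
    expect_lt(abs(inside - P), 0.02)
  }
})

test_that("bcea95 / bcea68 equals ln(0.05)/ln(0.32) for any point set", {
  set.seed(77)
  for (i in 1:5) {
    pts <- cbind(rnorm(50, sd = runif(1, 0.1, 3)),
                 rnorm(50, sd = runif(1, 0.1, 3)))
    expect_equal(bcea(pts, 0.95) / bcea(pts, 0.68),
                 log(0.05) / log(0.32), tolerance = 1e-12)
  }
})

test_that("fixation metrics recover noise dispersion and intrusion rate", {
  sc <- make_schedule("fixation", seed = 1)
  prof <- subject_profile(intrusion_rate = 0, blink_rate = 0,
                          fixation_noise_sd = 0.5)
  sds <- replicate(10, NA_real_)
  for (i in 1:10) {
    sim <- synth_gaze(sc, prof, seed = 500 + i)
    fm <- fixation_metrics(sim$recording, sc)
    sds[i] <- (fm$sd_h + fm$sd_v) / 2
    if (i == 1) {
      expect_equal(fm$intrusion_rate, 0)
      expect_gt(fm$bcea95, fm$bcea68)
      expect_equal(fm$n_trials_used, 5)
    }
  }
  # dispersion close to the generating noise SD (drift adds a little)
  expect_lt(abs(mean(sds) - 0.5) / 0.5, 0.1)
})

test_that("intrusion rate is injected count over analysed time", {
  # noiseless fixation with 3 hand-placed square-wave jerks in 7 s
  fs <- 60
  t <- seq(0, 7, by = 1 / fs)
  x <- numeric(length(t))
  for (o in c(2, 3.5, 5)) x[t >= o & t < o + 0.2] <- 1
  set.seed(8)
  rec <- gaze_recording("one", "fixation",
                        data.frame(t = t, x = x + rnorm(length(t), 0, 0.05),
                                   y = rnorm(length(t), 0, 0.05),
                                   valid = TRUE), fs)
  sched <- trial_schedule(data.frame(
    trial_id = 1, target_x = 0, target_y = 0, fixation_onset = 0,
    target_onset = 0, target_duration = 7, trial_end = 7,
    eccentricity_class = "n/a"), "fixation")
  fm <- fixation_metrics(rec, sched)
  expect_equal(fm$n_trials_used, 1)
  expect_equal(fm$intrusion_rate, 3 / 6.8, tolerance = 0.01)
})

test_that("noise-free steady gaze gives zero BCEA", {
  rec <- make_fixation_trace(n = 460)
  sched <- trial_schedule(data.frame(
    trial_id = 1, target_x = 0, target_y = 0, fixation_onset = 0,
    target_onset = 0, target_duration = 7, trial_end = 7,
    eccentricity_class = "n/a"), "fixation")
  fm <- fixation_metrics(rec, sched)
  expect_equal(fm$bcea68, 0)
  expect_equal(fm$bcea95, 0)
})

test_that("short fixation trials are dropped with a warning", {
  rec <- make_fixation_trace(n = 460, noise_sd = 0.1, seed = 3)
  rec$samples$valid[rec$samples$t > 0.8] <- FALSE
  sched <- trial_schedule(data.frame(
    trial_id = 1, target_x = 0, target_y = 0, fixation_onset = 0,
    target_onset = 0, target_duration = 7, trial_end = 7,
    eccentricity_class = "n/a"), "fixation")
  expect_warning(fm <- fixation_metrics(rec, sched), "dropped")
  expect_true(is.na(fm$bcea68))
  expect_equal(fm$n_trials_used, 0L)
})

test_that("pro-saccade trial arithmetic matches its definitions", {
  # single saccade landing at 9 toward a 10-degree target
  fs <- 60
  t <- seq(0, 4, by = 1 / fs)
  x <- numeric(length(t))
  x[t >= 2.2] <- 9
  rec <- gaze_recording("p", "prosaccade",
                        data.frame(t = t, x = x, y = 0, valid = TRUE), fs)
  trial <- data.frame(trial_id = 1, target_x = 10, target_y = 0,
                      fixation_onset = 0, target_onset = 2,
                      target_duration = 1.5, trial_end = 4,
                      eccentricity_class = "large")
  ev <- detect_saccades(rec)
  m <- prosaccade_trial(rec, trial, ev)
  expect_equal(m$first_gain, 0.9, tolerance = 0.01)
  expect_equal(m$first_gain_error, 1.0, tolerance = 0.05)
  expect_equal(m$n_saccades, 1)
  expect_lt(abs(m$latency - 0.2), 1.5 / fs)  # sample-grid quantisation
  expect_equal(m$status, "ok")
  expect_true(m$completed)
  expect_gte(m$time_to_target, m$latency)

  # no saccade at all -> non-responsive
  flat <- gaze_recording("f", "prosaccade",
                         data.frame(t = t, x = 0, y = 0, valid = TRUE), fs)
  m2 <- prosaccade_trial(flat, trial, detect_saccades(flat))
  expect_equal(m2$status, "non_responsive")
})

test_that("hypometric primary plus corrective gives two saccades to target", {
  sc <- make_schedule("prosaccade", seed = 2)
  prof <- subject_profile(primary_gain_mean = 0.75, primary_gain_sd = 0.01,
                          corrective_saccade_prob = 1, blink_rate = 0,
                          fixation_noise_sd = 0.1)
  sim <- synth_gaze(sc, prof, seed = 600)
  ev <- detect_saccades(sim$recording)
  large <- which(sc$eccentricity_class == "large")
  rows <- do.call(rbind, lapply(large, function(k) {
    prosaccade_trial(sim$recording, sc[k, ], ev)
  }))
  # large-eccentricity targets: gain 0.75 lands outside the 2-degree
  # window, so the corrective saccade is needed to arrive
  expect_gte(mean(rows$n_saccades[rows$completed], na.rm = TRUE), 1.5)
})

test_that("pro-saccade aggregation averages by eccentricity class", {
  trials <- data.frame(
    trial_id = 1:4, eccentricity_class = c("short", "short", "large", "large"),
    status = c("ok", "ok", "ok", "non_responsive"),
    latency = c(0.2, 0.3, 0.4, NA), time_to_target = c(0.3, 0.4, 0.5, NA),
    mean_velocity = c(100, 120, 200, NA), peak_velocity = c(150, 170, 300, NA),
    first_gain = c(0.9, 1.0, 0.8, NA), first_gain_error = c(0.5, 0.6, 1, NA),
    n_saccades = c(1, 2, 1, NA), completed = c(TRUE, TRUE, TRUE, FALSE))
  agg <- aggregate_prosaccade(trials)
  expect_equal(agg$pro_short_latency, 0.25)
  expect_equal(agg$pro_short_n_saccades, 1.5)
  expect_equal(agg$pro_large_latency, 0.4)
  expect_equal(agg$n_non_responsive, 1)

  # empty class -> NA, not zero
  short_only <- trials[trials$eccentricity_class == "short", ]
  expect_true(is.na(aggregate_prosaccade(short_only)$pro_large_latency))

  # idempotence: identical trials aggregate to the single-trial value
  one <- trials[rep(1, 3), ]
  expect_equal(aggregate_prosaccade(one)$pro_short_latency, 0.2)
})

test_that("anticipatory latencies are excluded from latency aggregates", {
  trials <- data.frame(
    trial_id = 1:2, eccentricity_class = "short",
    status = c("anticipatory", "ok"),
    latency = c(0.05, 0.3), time_to_target = c(0.2, 0.5),
    mean_velocity = c(100, 150), peak_velocity = c(200, 250),
    first_gain = c(0.8, 0.9), first_gain_error = c(1, 1),
    n_saccades = c(1, 1), completed = TRUE)
  agg <- aggregate_prosaccade(trials)
  expect_equal(agg$pro_short_latency, 0.3)       # anticipatory excluded
  expect_equal(agg$pro_short_first_gain, 0.85)   # but gain still counted
  expect_equal(agg$pro_short_n_saccades, 1)
})

test_that("anti-saccade scoring follows the direction definitions", {
  fs <- 60
  base_trial <- data.frame(
    trial_id = 1, target_x = 10, target_y = 0, fixation_onset = 0,
    target_onset = 2, target_duration = 0.1, trial_end = 9.2,
    eccentricity_class = "n/a", arrow_direction = "up", arrow_onset = 3.3,
    arrow_duration = 0.4, response_onset = 3.7, response_window = 5)
  t <- seq(0, 9.2, by = 1 / fs)

  # first saccade leftward (away from +10 target) -> correct; dwell up
  x <- numeric(length(t)); y <- numeric(length(t))
  x[t >= 2.25] <- -9
  x[t >= 4.0] <- 0
  y[t >= 4.0] <- 8
  rec <- gaze_recording("a", "antisaccade",
                        data.frame(t = t, x = x, y = y, valid = TRUE), fs)
  m <- antisaccade_trial(rec, base_trial, detect_saccades(rec))
  expect_equal(m$first_direction, "correct")
  expect_true(m$recognized_arrow)
  expect_lt(abs(m$latency - 0.25), 1.5 / fs)

  # rightward then crossing to the left before arrow offset -> corrected
  x2 <- numeric(length(t)); y2 <- numeric(length(t))
  x2[t >= 2.25] <- 9
  x2[t >= 2.75] <- -9
  x2[t >= 4.0] <- 0
  rec2 <- gaze_recording("b", "antisaccade",
                         data.frame(t = t, x = x2, y = y2, valid = TRUE), fs)
  m2 <- antisaccade_trial(rec2, base_trial, detect_saccades(rec2))
  expect_equal(m2$first_direction, "error")
  expect_true(m2$corrected)
  expect_false(m2$recognized_arrow)  # centre dwell in the response window
})

test_that("anti-saccade aggregation handles rates and degenerate cases", {
  trials <- data.frame(
    trial_id = 1:10, status = "ok",
    first_direction = c(rep("error", 4), rep("correct", 6)),
    corrected = c(TRUE, TRUE, TRUE, FALSE, rep(NA, 6)),
    recognized_arrow = rep(c(TRUE, FALSE), 5),
    latency = c(rep(0.4, 4), rep(c(0.25, 0.35), 3)))
  agg <- aggregate_antisaccade(trials)
  expect_equal(agg$anti_error_rate, 0.4)
  expect_equal(agg$anti_corrected_rate, 0.75)
  expect_equal(agg$anti_correct_latency, 0.3)
  expect_equal(agg$anti_incorrect_latency, 0.4)

  all_ok <- trials
  all_ok$first_direction <- "correct"
  agg2 <- aggregate_antisaccade(all_ok)
  expect_equal(agg2$anti_error_rate, 0)
  expect_true(is.na(agg2$anti_corrected_rate))
  expect_true(is.na(agg2$anti_incorrect_latency))
})

test_that("a programmed anti-saccade error rate is recovered", {
  sc <- make_schedule("antisaccade", seed = 3, n_trials = 40)
  prof <- subject_profile(antisaccade_error_prob = 0.25, blink_rate = 0)
  sim <- synth_gaze(sc, prof, seed = 700)
  art <- remove_artifacts(sim$recording)
  rec <- oculokit:::.median_filter_rec(art$recording)
  ev <- detect_saccades(rec, artifacts = art$artifacts)
  rows <- do.call(rbind, lapply(seq_len(nrow(sc)), function(k) {
    antisaccade_trial(rec, sc[k, ], ev)
  }))
  agg <- aggregate_antisaccade(rows)
  # binomial 95% interval for p = 0.25, n = 40: [0.125, 0.4]
  expect_gte(agg$anti_error_rate, 0.125)
  expect_lte(agg$anti_error_rate, 0.40)
})

test_that("the canonical parameter set has exactly 24 names", {
  expect_length(canonical_parameter_names(), 24)
  expect_false(anyDuplicated(canonical_parameter_names()) > 0)
})
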