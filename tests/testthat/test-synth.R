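test_that("schedules follow the task protocols", {
  pro <- make_schedule("prosaccade", seed = 1)
  expect_equal(nrow(pro), 24)
  expect_equal(sum(pro$eccentricity_class == "short"), 12)
  ecc <- sqrt(pro$target_x^2 + pro$target_y^2)
  expect_true(all(ecc %in% c(5, 6, 10, 12)))
  fixdur <- pro$target_onset - pro$fixation_onset
  expect_true(all(fixdur >= 1 & fixdur <= 3.5))
  expect_true(all(pro$target_duration == 1.5))

  fx <- make_schedule("fixation", seed = 2)
  expect_equal(nrow(fx), 5)
  expect_true(all(fx$trial_end - fx$target_onset == 7))
  expect_setequal(paste(fx$target_x, fx$target_y),
                  c("0 0", "-10 0", "10 0", "0 -14", "0 14"))

  anti <- make_schedule("antisaccade", seed = 3)
  expect_true(all(abs(anti$target_x) == 10))
  expect_true(all(anti$target_duration == 0.1))
  expect_equal(anti$arrow_onset - anti$target_onset, rep(1.3, nrow(anti)))
  expect_true(all(anti$arrow_duration == 0.4))
  expect_true(all(anti$response_window == 5))

  # determinism
  expect_identical(make_schedule("prosaccade", seed = 9),
                   make_schedule("prosaccade", seed = 9))
})

test_that("the noiseless simulator lands gaze exactly on target", {
  sc <- make_schedule("prosaccade", seed = 4)
  prof <- subject_profile(fixation_noise_sd = 0, primary_gain_mean = 1,
                          primary_gain_sd = 0, intrusion_rate = 0,
                          blink_rate = 0)
  sim <- synth_gaze(sc, prof, seed = 5)
  s <- sim$recording$samples
  # no noise, no drift: gaze sits exactly on target at each trial end
  for (k in seq_len(nrow(sc))) {
    i <- max(which(s$t <= sc$trial_end[k] - 0.01))
    expect_equal(s$x[i], sc$target_x[k], tolerance = 1e-9)
    expect_equal(s$y[i], sc$target_y[k], tolerance = 1e-9)
  }
})

test_that("simulation is bit-identical under a fixed seed", {
  sc <- make_schedule("fixation", seed = 6)
  prof <- default_profile("PD")
  a <- synth_gaze(sc, prof, seed = 77)
  b <- synth_gaze(sc, prof, seed = 77)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$truth, b$truth)
  c <- synth_gaze(sc, prof, seed = 78)
  expect_false(identical(a$recording$samples, c$recording$samples))
})

test_that("truth-log peak velocities follow the main sequence exactly", {
  sc <- make_schedule("prosaccade", seed = 8)
  prof <- default_profile("HC")
  sim <- synth_gaze(sc, prof, seed = 9)
  tr <- sim$truth
  expect_equal(tr$peak_velocity,
               prof$main_sequence_vmax *
                 (1 - exp(-tr$amplitude / prof$main_sequence_c)),
               tolerance = 1e-12)
  # latencies respect the 80 ms floor
  expect_true(all(tr$latency >= 0.08, na.rm = TRUE))
})

test_that("injected intrusion counts follow the Poisson expectation", {
  sc <- make_schedule("fixation", seed = 10)
  prof <- subject_profile(intrusion_rate = 0.5, blink_rate = 0)
  counts <- vapply(1:60, function(i) {
    sum(synth_gaze(sc, prof, seed = 1000 + i)$truth$kind == "intrusion")
  }, numeric(1))
  lambda <- 0.5 * sum(sc$trial_end - sc$target_onset - 0.2)
  # mean of 60 Poisson draws: 95% band (acquisition shifts the basis a
  # little, hence the slightly widened band)
  half <- 1.96 * sqrt(lambda / 60) + 0.05 * lambda
  expect_lt(abs(mean(counts) - lambda), half)
})

test_that("blinks appear as invalid runs at roughly the configured rate", {
  sc <- make_schedule("fixation", seed = 11)
  prof <- subject_profile(blink_rate = 6, intrusion_rate = 0)
  n_blinks <- vapply(1:20, function(i) {
    v <- synth_gaze(sc, prof, seed = 2000 + i)$recording$samples$valid
    sum(diff(c(TRUE, v)) == -1)
  }, numeric(1))
  expect_gt(mean(n_blinks), 1.5)   # 6/min over 35 s -> ~3.5 expected
  expect_lt(mean(n_blinks), 5.5)
})

test_that("cohort generation is deterministic and counts line up", {
  cfg <- cohort_config(n_per_group = 2, seed = 42)
  co <- synth_cohort(cfg)
  expect_length(co$subjects, 4)
  expect_equal(nrow(co$truth), 4)
  expect_equal(sum(vapply(co$subjects,
                          function(s) length(s$recordings), 1L)), 12)
  co2 <- synth_cohort(cohort_config(n_per_group = 2, seed = 42))
  expect_identical(co$truth, co2$truth)
  expect_identical(co$subjects[[3]]$recordings$fixation$samples,
                   co2$subjects[[3]]$recordings$fixation$samples)
})

test_that("identical group profiles give truth tables that differ only by noise", {
  prof <- default_profile("HC")
  co <- synth_cohort(cohort_config(n_per_group = 40, seed = 13,
                                   hc_profile = prof, pd_profile = prof))
  tr <- co$truth
  t_gain <- t.test(primary_gain_mean ~ group, data = tr)$statistic
  t_lat <- t.test(latency_mean ~ group, data = tr)$statistic
  expect_lt(abs(t_gain), 3)
  expect_lt(abs(t_lat), 3)
})

test_that("the PD intrusion-rate ratio is built in", {
  co <- synth_cohort(cohort_config(n_per_group = 60, seed = 14))
  tr <- co$truth
  ratio <- median(tr$intrusion_rate[tr$group == "PD"]) /
    median(tr$intrusion_rate[tr$group == "HC"])
  # generating ratio 1.887 with lognormal spread; medians are consistent
  expect_gt(ratio, 1.3)
  expect_lt(ratio, 2.7)
})

test_that("profile validation rejects out-of-range parameters", {
  expect_error(subject_profile(antisaccade_error_prob = 1.5), "probabilities")
  expect_error(subject_profile(primary_gain_mean = -0.2), "positive")
  expect_error(subject_profile(intrusion_rate = -1), "non-negative")
  expect_error(synth_gaze(make_schedule("fixation", seed = 1),
                          default_profile("HC"), sample_rate = 10), "30 Hz")
  expect_error(cohort_config(n_per_group = 5), "seed")
})
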