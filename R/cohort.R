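#' Two-group cohort configuration for the simulator
#'
#' Defines a synthetic PD / HC cohort: group sizes, group-level behaviour
#' profiles, between-subject spread, demographic distributions (ages and
#' sex ratios default to the study-like values: PD 63.8 +/- 8.2 years,
#' 32% female; HC 56.6 +/- 8.6 years, 47% female) and a latent-severity
#' model that couples the PD motor score (UPDRS-III, 0-132) negatively to
#' saccade gain and positively to the intrusion rate.
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param seed Mandatory integer seed.
#' @param hc_profile,pd_profile Group-level [subject_profile()]s.
#' @param between Named list of between-subject spread parameters:
#'   `latency_mean_sd` (s), `gain_mean_sd`, `corrective_logit_sd`,
#'   `intrusion_sdlog` (lognormal), `error_logit_sd`, `vmax_sd` (deg/s),
#'   `noise_cv`.
#' @param updrs3 Named list: `mean`, `sd` of the PD score distribution and
#'   the coupling slopes `gain_slope` (per severity z-score) and
#'   `intrusion_log_slope`.
#' @param antisaccade_trials Anti-saccade trials per subject.
#' @param sample_rate Recording rate in Hz.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 50, seed,
                          hc_profile = default_profile("HC"),
                          pd_profile = default_profile("PD"),
                          between = list(latency_mean_sd = 0.04,
                                         gain_mean_sd = 0.1,
                                         corrective_logit_sd = 1.0,
                                         intrusion_sdlog = 0.85,
                                         error_logit_sd = 0.5,
                                         vmax_sd = 50, noise_cv = 0.2),
                          updrs3 = list(mean = 27.6, sd = 13.8,
                                        gain_slope = -0.03,
                                        intrusion_log_slope = 0.25),
                          antisaccade_trials = 12, sample_rate = 60) {
  if (missing(seed)) stop("cohort_config: seed is mandatory", call. = FALSE)
  if (n_per_group < 2) stop("cohort_config: n_per_group must be >= 2",
                            call. = FALSE)
  structure(list(n_per_group = n_per_group, seed = as.integer(seed),
                 hc_profile = hc_profile, pd_profile = pd_profile,
                 between = between, updrs3 = updrs3,
                 antisaccade_trials = antisaccade_trials,
                 sample_rate = sample_rate),
            class = c("cohort_config", "list"))
}

.logit <- function(p) log(p / (1 - p))
.inv_logit <- function(z) 1 / (1 + exp(-z))

# Draw one subject's profile around the group profile.
.draw_profile <- function(base, bw, severity_z = 0, updrs3_model = NULL) {
  gain_shift <- if (!is.null(updrs3_model)) updrs3_model$gain_slope * severity_z
                else 0
  intr_shift <- if (!is.null(updrs3_model))
                  updrs3_model$intrusion_log_slope * severity_z else 0
  subject_profile(
    latency_mean = .rtrunc_norm(1, base$latency_mean, bw$latency_mean_sd,
                                lo = 0.1),
    latency_sd = base$latency_sd,
    main_sequence_vmax = .rtrunc_norm(1, base$main_sequence_vmax, bw$vmax_sd,
                                      lo = 250),
    main_sequence_c = base$main_sequence_c,
    primary_gain_mean = .rtrunc_norm(1, base$primary_gain_mean + gain_shift,
                                     bw$gain_mean_sd, lo = 0.5, hi = 1.15),
    primary_gain_sd = base$primary_gain_sd,
    corrective_saccade_prob = .inv_logit(
      stats::rnorm(1, .logit(base$corrective_saccade_prob),
                   bw$corrective_logit_sd)),
    # capped at 0.8 pairs/s: square-wave jerks need ~0.5 s of refixation
    # between pairs, so higher generating rates cannot be realised
    intrusion_rate = min(0.8, base$intrusion_rate *
      exp(stats::rnorm(1, intr_shift, bw$intrusion_sdlog))),
    intrusion_amp_mean = .rtrunc_norm(1, base$intrusion_amp_mean, 0.15,
                                      lo = 0.7),
    fixation_noise_sd = base$fixation_noise_sd *
      exp(stats::rnorm(1, 0, bw$noise_cv)),
    blink_rate = base$blink_rate,
    antisaccade_error_prob = .inv_logit(
      stats::rnorm(1, .logit(base$antisaccade_error_prob), bw$error_logit_sd)),
    correction_prob = base$correction_prob,
    recognition_prob = .inv_logit(
      stats::rnorm(1, .logit(base$recognition_prob), 0.4)))
}

#' Simulate a two-group cohort with ground truth
#'
#' Draws per-subject profiles from the group distributions, simulates all
#' three task recordings per subject, and returns a truth table holding
#' the generating values (not pipeline estimates). Per-subject simulation
#' seeds derive deterministically from `config$seed` and the subject
#' index, so identical configs give identical cohorts.
#'
#' @param config A [cohort_config()].
#' @return List with `subjects` (per subject: `subject_id`,
#'   `demographics`, `profile`, `schedules`, `recordings`, `truths`) and
#'   `truth`, a data frame of generating values per subject.
#' @export
synth_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  restore <- local_rng(config$seed)
  on.exit(restore())
  tasks <- c("fixation", "prosaccade", "antisaccade")
  subjects <- list()
  truth_rows <- list()
  idx <- 0L
  for (group in c("HC", "PD")) {
    base <- if (group == "HC") config$hc_profile else config$pd_profile
    for (i in seq_len(config$n_per_group)) {
      idx <- idx + 1L
      sid <- sprintf("%s%03d", group, i)
      if (group == "PD") {
        updrs3 <- round(.rtrunc_norm(1, config$updrs3$mean, config$updrs3$sd,
                                     lo = 0, hi = 132))
        sev_z <- (updrs3 - config$updrs3$mean) / config$updrs3$sd
        age <- round(.rtrunc_norm(1, 63.76, 8.23, lo = 45, hi = 79))
        sex <- if (stats::runif(1) < 0.322) "F" else "M"
      } else {
        updrs3 <- NA_real_
        sev_z <- 0
        age <- round(.rtrunc_norm(1, 56.64, 8.56, lo = 45, hi = 77))
        sex <- if (stats::runif(1) < 0.467) "F" else "M"
      }
      prof <- .draw_profile(base, config$between, sev_z,
                            if (group == "PD") config$updrs3 else NULL)
      sub_seed <- (config$seed %% 100000L) * 1000L + idx
      schedules <- list()
      recordings <- list()
      truths <- list()
      for (j in seq_along(tasks)) {
        task <- tasks[j]
        schedules[[task]] <- make_schedule(
          task, seed = sub_seed * 10L + j,
          n_trials = config$antisaccade_trials)
        sim <- synth_gaze(schedules[[task]], prof,
                          sample_rate = config$sample_rate,
                          seed = sub_seed * 10L + j + 5L, subject_id = sid)
        recordings[[task]] <- sim$recording
        truths[[task]] <- sim$truth
      }
      subjects[[idx]] <- list(
        subject_id = sid,
        demographics = list(group = group, age = age, sex = sex,
                            updrs3 = updrs3),
        profile = prof, schedules = schedules, recordings = recordings,
        truths = truths)
      truth_rows[[idx]] <- data.frame(
        subject_id = sid, group = group, age = age, sex = sex,
        updrs3 = updrs3, latency_mean = prof$latency_mean,
        primary_gain_mean = prof$primary_gain_mean,
        corrective_saccade_prob = prof$corrective_saccade_prob,
        intrusion_rate = prof$intrusion_rate,
        fixation_noise_sd = prof$fixation_noise_sd,
        main_sequence_vmax = prof$main_sequence_vmax,
        antisaccade_error_prob = prof$antisaccade_error_prob,
        recognition_prob = prof$recognition_prob)
    }
  }
  list(subjects = subjects, truth = do.call(rbind, truth_rows))
}

#' Extract parameter rows for every subject of a synthetic cohort
#'
#' Convenience wrapper running [extract_subject()] over a [synth_cohort()]
#' result.
#'
#' @param cohort Result of [synth_cohort()].
#' @param config A [detection_config()].
#' @return Data frame of [subject_parameters()] rows, one per subject.
#' @export
extract_cohort <- function(cohort, config = detection_config()) {
  rows <- lapply(cohort$subjects, function(sub) {
    extract_subject(sub$recordings, sub$schedules, config,
                    sub$demographics)$parameters
  })
  do.call(rbind, rows)
}
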