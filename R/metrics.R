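#' Bivariate contour ellipse area (BCEA)
#'
#' Fixation-stability measure: the area of the ellipse, fitted to the 2-D
#' gaze point cloud, that covers a fraction `P` of the points under a
#' bivariate-normal model:
#' \deqn{A = 2\pi k \sigma_H \sigma_V \sqrt{1-\rho^2}, \quad k = -\ln(1-P)}
#' with sample standard deviations and correlation. Smaller is steadier.
#'
#' @param points 2-column matrix or data frame of gaze positions (degrees).
#' @param P Coverage probability in (0, 1); 0.68 and 0.95 are reported.
#' @return Area in deg^2 (0 for a degenerate point cloud).
#' @export
#' @examples
#' set.seed(1)
#' bcea(cbind(rnorm(500), rnorm(500)), 0.68)  # ~ 2*pi*1.139 = 7.16
bcea <- function(points, P = 0.68) {
  if (P <= 0 || P >= 1) stop("bcea: P must be in (0, 1)", call. = FALSE)
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("bcea: need at least 3 points", call. = FALSE)
  sh <- stats::sd(points[, 1])
  sv <- stats::sd(points[, 2])
  if (sh == 0 || sv == 0) return(0)
  rho <- stats::cor(points[, 1], points[, 2])
  2 * pi * (-log(1 - P)) * sh * sv * sqrt(max(0, 1 - rho^2))
}

#' Canonical per-subject oculomotor parameter names
#'
#' The 24 parameters: 5 fixation, 7 pro-saccade short-eccentricity,
#' 7 pro-saccade large-eccentricity, 5 anti-saccade.
#'
#' @return Character vector of length 24.
#' @export
canonical_parameter_names <- function() {
  pro <- c("latency", "time_to_target", "mean_velocity", "peak_velocity",
           "first_gain", "first_gain_error", "n_saccades")
  c(paste0("fix_", c("bcea68", "bcea95", "sd_h", "sd_v", "intrusion_rate")),
    paste0("pro_short_", pro), paste0("pro_large_", pro),
    paste0("anti_", c("error_rate", "corrected_rate", "recognition_rate",
                      "correct_latency", "incorrect_latency")))
}

#' Fixation-task metrics
#'
#' Per trial, analysis starts once gaze has acquired the target: at the
#' later of `intrusion_skip_ms` after target onset and the first sample
#' within 3 degrees of the target (the acquiring saccade and the
#' pre-acquisition dwell at the previous location are not fixation).
#' From there, valid samples outside intrusion episodes are re-centred on
#' the trial target and summarised by 68%/95% BCEA and horizontal /
#' vertical gaze SD. The intrusion rate is total intrusions (square-wave
#' jerk pairs counted once when `swj_pair_window_s > 0`) over total
#' analysed fixation time. Fields are means across the trials; trials with
#' under 1 s of valid data are dropped with a warning.
#'
#' Dispersion (BCEA, gaze SDs) is computed on the unsmoothed samples so
#' it reflects the recorded signal; intrusion detection runs on a
#' median-filtered copy (step-preserving, noise-robust).
#'
#' @param rec An artifact-masked [gaze_recording()] (see
#'   [remove_artifacts()]), task `"fixation"`; smoothing is handled
#'   internally.
#' @param schedule The fixation [trial_schedule()].
#' @param config A [detection_config()].
#' @param artifacts Optional artifact intervals from [remove_artifacts()].
#' @return A list with `bcea68`, `bcea95`, `sd_h`, `sd_v`,
#'   `intrusion_rate` (all `NA` if every trial was dropped) plus
#'   `n_trials_used`.
#' @export
fixation_metrics <- function(rec, schedule, config = detection_config(),
                             artifacts = NULL) {
  stopifnot(inherits(rec, "gaze_recording"),
            schedule_task(schedule) == "fixation")
  s <- rec$samples
  rec_m <- .median_filter_rec(rec)
  vel <- velocity(rec_m)
  per <- list()
  n_intr <- 0L
  t_total <- 0
  for (k in seq_len(nrow(schedule))) {
    tr <- schedule[k, ]
    win <- c(tr$target_onset, tr$trial_end)
    lo <- win[1] + config$intrusion_skip_ms / 1000
    sm <- rec_m$samples
    near <- which(sm$t >= win[1] & sm$t <= win[2] & sm$valid &
                    sqrt((sm$x - tr$target_x)^2 +
                           (sm$y - tr$target_y)^2) <= 3)
    if (length(near)) lo <- max(lo, sm$t[near[1]])
    intr <- detect_intrusions(rec_m, c(lo, win[2]), config, vel = vel,
                              artifacts = artifacts)
    in_win <- s$t >= lo & s$t <= win[2] & s$valid &
      is.finite(s$x) & is.finite(s$y)
    keep <- in_win
    # exclude whole intrusion episodes: for a square-wave-jerk pair the
    # gaze sits displaced between the outward and return saccades, so the
    # exclusion must span from the first saccade's onset to the second's
    # offset, not just the transitions
    for (iv in .intrusion_spans(intr, config$swj_pair_window_s)) {
      keep <- keep & !(s$t >= iv[1] - 1 / rec$sample_rate &
                         s$t <= iv[2] + 1 / rec$sample_rate)
    }
    t_valid <- sum(in_win) / rec$sample_rate
    if (t_valid < 1) {
      warning(sprintf("fixation trial %d dropped: only %.2f s of valid data",
                      tr$trial_id, t_valid))
      next
    }
    px <- s$x[keep] - tr$target_x
    py <- s$y[keep] - tr$target_y
    per[[length(per) + 1]] <- c(
      bcea68 = bcea(cbind(px, py), 0.68),
      bcea95 = bcea(cbind(px, py), 0.95),
      sd_h = stats::sd(px), sd_v = stats::sd(py))
    n_intr <- n_intr + count_intrusions(intr, config$swj_pair_window_s)
    t_total <- t_total + t_valid
  }
  if (!length(per)) {
    return(list(bcea68 = NA_real_, bcea95 = NA_real_, sd_h = NA_real_,
                sd_v = NA_real_, intrusion_rate = NA_real_,
                n_trials_used = 0L))
  }
  m <- colMeans(do.call(rbind, per))
  list(bcea68 = unname(m["bcea68"]), bcea95 = unname(m["bcea95"]),
       sd_h = unname(m["sd_h"]), sd_v = unname(m["sd_v"]),
       intrusion_rate = n_intr / t_total, n_trials_used = length(per))
}

# Exclusion spans for intrusion events: paired opposite-direction
# saccades within the pairing window span one interval from first onset
# to second offset.
.intrusion_spans <- function(events, pair_window_s) {
  n <- nrow(events)
  if (n == 0) return(list())
  spans <- list()
  k <- 1L
  while (k <= n) {
    if (k < n && pair_window_s > 0 &&
        events$onset_t[k + 1] - events$offset_t[k] <= pair_window_s &&
        events$dir_x[k] * events$dir_x[k + 1] < 0) {
      spans[[length(spans) + 1]] <- c(events$onset_t[k],
                                      events$offset_t[k + 1])
      k <- k + 2L
    } else {
      spans[[length(spans) + 1]] <- c(events$onset_t[k], events$offset_t[k])
      k <- k + 1L
    }
  }
  spans
}

#' Score one pro-saccade trial
#'
#' The first saccade is the earliest detected event after target onset
#' with amplitude at least `min_saccade_amp_deg` and displacement pointing
#' toward the target (positive dot product with the fixation-to-target
#' vector). Latency is its onset minus target onset; first gain the
#' component of its displacement along the target axis over the target
#' eccentricity; first gain error the 2-D distance from its landing point
#' to the target. Time to target is when gaze first enters the acceptance
#' window (radius `target_radius_deg`) and dwells at least `dwell_ms`;
#' saccades-to-target counts detected saccades from target onset to that
#' arrival.
#'
#' @param rec A preprocessed [gaze_recording()].
#' @param trial One row of a pro-saccade [trial_schedule()].
#' @param events Detected saccades for the recording ([detect_saccades()]).
#' @param config A [detection_config()].
#' @return One-row data frame with `trial_id`, `eccentricity_class`,
#'   `status` (`"ok"`, `"anticipatory"`, `"non_responsive"`), `latency`,
#'   `time_to_target`, `mean_velocity`, `peak_velocity`, `first_gain`,
#'   `first_gain_error`, `n_saccades`, `completed`.
#' @export
prosaccade_trial <- function(rec, trial, events, config = detection_config()) {
  tgt <- c(trial$target_x, trial$target_y)
  ecc <- sqrt(sum(tgt^2))
  u <- tgt / ecc
  on <- trial$target_onset
  end <- trial$trial_end
  na_row <- data.frame(
    trial_id = trial$trial_id, eccentricity_class = trial$eccentricity_class,
    status = "non_responsive", latency = NA_real_, time_to_target = NA_real_,
    mean_velocity = NA_real_, peak_velocity = NA_real_,
    first_gain = NA_real_, first_gain_error = NA_real_,
    n_saccades = NA_real_, completed = FALSE)

  cand <- events[events$onset_t > on & events$onset_t < end &
                   events$amplitude >= config$min_saccade_amp_deg, ,
                 drop = FALSE]
  toward <- (cand$dir_x * u[1] + cand$dir_y * u[2]) > 0
  cand <- cand[toward, , drop = FALSE]
  if (!nrow(cand)) return(na_row)
  first <- cand[1, ]
  latency <- first$onset_t - on

  # arrival: first dwell of >= dwell_ms inside the acceptance window
  s <- rec$samples
  dwell_n <- max(1L, as.integer(round(config$dwell_ms / 1000 * rec$sample_rate)))
  in_win <- s$t >= on & s$t <= end
  near <- in_win & s$valid &
    sqrt((s$x - tgt[1])^2 + (s$y - tgt[2])^2) <= config$target_radius_deg
  arrival <- NA_real_
  r <- rle(near[in_win])
  idx_map <- which(in_win)
  pos <- cumsum(c(1, r$lengths))
  for (j in seq_along(r$values)) {
    if (r$values[j] && r$lengths[j] >= dwell_n) {
      arrival <- s$t[idx_map[pos[j]]]
      break
    }
  }
  completed <- is.finite(arrival)
  n_sacc <- if (completed) {
    max(1L, sum(events$onset_t > on & events$onset_t <= arrival &
                  events$amplitude >= config$min_saccade_amp_deg))
  } else NA_real_

  land <- c(first$end_x, first$end_y)
  disp <- c(first$end_x - first$start_x, first$end_y - first$start_y)
  data.frame(
    trial_id = trial$trial_id, eccentricity_class = trial$eccentricity_class,
    status = if (latency < config$anticipatory_min_latency_s) "anticipatory"
             else "ok",
    latency = latency,
    time_to_target = if (completed) arrival - on else NA_real_,
    mean_velocity = first$mean_velocity, peak_velocity = first$peak_velocity,
    first_gain = sum(disp * u) / ecc,
    first_gain_error = sqrt(sum((land - tgt)^2)),
    n_saccades = n_sacc, completed = completed)
}

#' Aggregate pro-saccade trials into short/large eccentricity means
#'
#' Arithmetic means per eccentricity class. Latency and velocity means use
#' non-anticipatory trials only; time-to-target and saccades-to-target use
#' completed trials; non-responsive trials are excluded everywhere but
#' tallied.
#'
#' @param trials Data frame of rows from [prosaccade_trial()].
#' @return Named list: `pro_short_*` and `pro_large_*` parameter values
#'   plus `n_non_responsive`. Empty classes yield `NA` values.
#' @export
aggregate_prosaccade <- function(trials) {
  out <- list()
  for (cls in c("short", "large")) {
    tr <- trials[trials$eccentricity_class == cls &
                   trials$status != "non_responsive", , drop = FALSE]
    ok <- tr[tr$status == "ok", , drop = FALSE]
    comp <- tr[tr$completed %in% TRUE, , drop = FALSE]
    pre <- paste0("pro_", cls, "_")
    out[[paste0(pre, "latency")]] <- .mean_or_na(ok$latency)
    out[[paste0(pre, "time_to_target")]] <- .mean_or_na(comp$time_to_target)
    out[[paste0(pre, "mean_velocity")]] <- .mean_or_na(ok$mean_velocity)
    out[[paste0(pre, "peak_velocity")]] <- .mean_or_na(ok$peak_velocity)
    out[[paste0(pre, "first_gain")]] <- .mean_or_na(tr$first_gain)
    out[[paste0(pre, "first_gain_error")]] <- .mean_or_na(tr$first_gain_error)
    out[[paste0(pre, "n_saccades")]] <- .mean_or_na(comp$n_saccades)
  }
  out$n_non_responsive <- sum(trials$status == "non_responsive")
  out
}

.mean_or_na <- function(x) {
  x <- x[is.finite(x)]
  if (length(x)) mean(x) else NA_real_
}

#' Score one anti-saccade trial
#'
#' The first saccade (amplitude >= `min_saccade_amp_deg`, onset after
#' target onset, before the response screen) is correct when its
#' horizontal component points away from the target side. An error trial
#' is corrected when a later saccade lands on the correct side of the
#' screen centre before arrow offset. Arrow recognition is scored from the
#' response screen: per-direction dwell time of gaze more than 2 degrees
#' from centre (left/right when |x| >= |y|, up/down otherwise); the
#' longest dwell, if at least 0.5 s, is the subject's answer; ties,
#' shorter dwells or no off-centre gaze count as unrecognised.
#'
#' @inheritParams prosaccade_trial
#' @param trial One row of an anti-saccade [trial_schedule()].
#' @return One-row data frame with `trial_id`, `status`, `first_direction`
#'   (`"correct"`/`"error"`), `corrected`, `recognized_arrow`, `latency`.
#' @export
antisaccade_trial <- function(rec, trial, events, config = detection_config()) {
  on <- trial$target_onset
  arrow_off <- trial$arrow_onset + trial$arrow_duration
  cand <- events[events$onset_t > on & events$onset_t < trial$response_onset &
                   events$amplitude >= config$min_saccade_amp_deg, ,
                 drop = FALSE]
  if (!nrow(cand)) {
    return(data.frame(trial_id = trial$trial_id, status = "non_responsive",
                      first_direction = NA_character_, corrected = NA,
                      recognized_arrow = NA, latency = NA_real_))
  }
  first <- cand[1, ]
  side <- sign(trial$target_x)
  correct <- sign(first$dir_x) == -side
  corrected <- NA
  if (!correct) {
    later <- cand[cand$onset_t > first$offset_t & cand$onset_t < arrow_off, ,
                  drop = FALSE]
    corrected <- any(sign(later$end_x) == -side)
  }

  s <- rec$samples
  resp <- s$t >= trial$response_onset &
    s$t <= trial$response_onset + trial$response_window &
    s$valid & is.finite(s$x) & is.finite(s$y)
  rx <- s$x[resp]; ry <- s$y[resp]
  off_centre <- sqrt(rx^2 + ry^2) > 2
  answer <- NA_character_
  min_dwell <- 0.5 * rec$sample_rate  # an answer needs a deliberate dwell
  if (any(off_centre)) {
    rx <- rx[off_centre]; ry <- ry[off_centre]
    sector <- ifelse(abs(rx) >= abs(ry),
                     ifelse(rx < 0, "left", "right"),
                     ifelse(ry < 0, "down", "up"))
    dwell <- table(sector)
    best <- dwell == max(dwell)
    if (sum(best) == 1 && max(dwell) >= min_dwell) {
      answer <- names(dwell)[best]
    }
  }
  data.frame(
    trial_id = trial$trial_id,
    status = if (first$onset_t - on < config$anticipatory_min_latency_s)
      "anticipatory" else "ok",
    first_direction = if (correct) "correct" else "error",
    corrected = corrected,
    recognized_arrow = identical(answer, trial$arrow_direction),
    latency = first$onset_t - on)
}

#' Aggregate anti-saccade trials
#'
#' Error rate = error trials / valid trials; corrected rate = corrected /
#' error trials (`NA` when there are no errors); recognition rate over
#' valid trials; mean latency separately over correct and error trials
#' (anticipatory trials excluded from the latency means).
#'
#' @param trials Data frame of rows from [antisaccade_trial()].
#' @return Named list of the `anti_*` parameters plus `n_non_responsive`.
#' @export
aggregate_antisaccade <- function(trials) {
  valid <- trials[trials$status != "non_responsive", , drop = FALSE]
  err <- valid$first_direction == "error"
  ok_lat <- valid$status == "ok"
  list(
    anti_error_rate = if (nrow(valid)) mean(err) else NA_real_,
    anti_corrected_rate = if (any(err)) mean(valid$corrected[err]) else NA_real_,
    anti_recognition_rate = if (nrow(valid)) mean(valid$recognized_arrow)
                            else NA_real_,
    anti_correct_latency = .mean_or_na(valid$latency[!err & ok_lat]),
    anti_incorrect_latency = .mean_or_na(valid$latency[err & ok_lat]),
    n_non_responsive = sum(trials$status == "non_responsive"))
}
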