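#' Event-detection configuration
#'
#' Parameters of the velocity-threshold (I-VT) saccade detector and the
#' saccadic-intrusion detector. At a nominal 60 Hz sampling rate saccades
#' span only a handful of samples, so two threshold pairs are used: the
#' main pair for task saccades and a lower pair for small (0.5-3 degree)
#' intrusion saccades, whose central-difference peak velocities fall well
#' below the main onset threshold at this rate. The >= 0.5 degree
#' amplitude floor keeps tracker noise out of the intrusion count.
#'
#' @param onset_vel_deg_s Velocity a saccade must exceed to be detected
#'   (deg/s, default 30).
#' @param offset_vel_deg_s Velocity at which onset/offset are refined
#'   (deg/s, default 20).
#' @param min_dur_ms Minimum saccade duration (default 17 ms; events must
#'   always span at least 2 samples, so the effective minimum at 60 Hz is
#'   about 33 ms).
#' @param intrusion_min_amp_deg Minimum intrusion amplitude (default 0.5).
#' @param intrusion_max_amp_deg Maximum intrusion amplitude (default 5):
#'   larger events inside a fixation window are task or refixation
#'   saccades, not intrusions.
#' @param artifact_pad_ms Padding around artifact intervals (default 50).
#' @param intrusion_onset_vel_deg_s,intrusion_offset_vel_deg_s Threshold
#'   pair used by [detect_intrusions()] (defaults 15 / 10 deg/s). These
#'   are floors: the intrusion detector raises them adaptively to
#'   `intrusion_lambda` robust SDs of the velocity noise inside the
#'   window, so noisy recordings do not flood the intrusion count.
#' @param intrusion_lambda Multiplier on the robust velocity noise SD
#'   (estimated from the in-window speed distribution) for the adaptive
#'   intrusion threshold (default 5).
#' @param intrusion_skip_ms Window-start exclusion so the task-driven
#'   acquisition saccade is not counted as an intrusion (default 200 ms).
#' @param swj_pair_window_s Two opposite-direction intrusion saccades
#'   within this window are counted as one square-wave-jerk intrusion by
#'   the fixation metrics (default 0.25 s; set 0 to count per saccade).
#' @param min_saccade_amp_deg Minimum amplitude for a task-directed
#'   saccade in the pro/anti-saccade metrics (default 1).
#' @param target_radius_deg,dwell_ms Target acceptance window radius and
#'   dwell for time-to-target (defaults 2 degrees, 100 ms).
#' @param anticipatory_min_latency_s Latencies below this are treated as
#'   anticipatory and excluded from latency/velocity aggregates
#'   (default 0.08 s).
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(onset_vel_deg_s = 30,
                             offset_vel_deg_s = 20,
                             min_dur_ms = 17,
                             intrusion_min_amp_deg = 0.5,
                             intrusion_max_amp_deg = 5,
                             artifact_pad_ms = 50,
                             intrusion_onset_vel_deg_s = 15,
                             intrusion_offset_vel_deg_s = 10,
                             intrusion_lambda = 5,
                             intrusion_skip_ms = 200,
                             swj_pair_window_s = 0.25,
                             min_saccade_amp_deg = 1,
                             target_radius_deg = 2,
                             dwell_ms = 100,
                             anticipatory_min_latency_s = 0.08) {
  cfg <- list(
    onset_vel_deg_s = onset_vel_deg_s, offset_vel_deg_s = offset_vel_deg_s,
    min_dur_ms = min_dur_ms, intrusion_min_amp_deg = intrusion_min_amp_deg,
    intrusion_max_amp_deg = intrusion_max_amp_deg,
    artifact_pad_ms = artifact_pad_ms,
    intrusion_onset_vel_deg_s = intrusion_onset_vel_deg_s,
    intrusion_offset_vel_deg_s = intrusion_offset_vel_deg_s,
    intrusion_lambda = intrusion_lambda,
    intrusion_skip_ms = intrusion_skip_ms,
    swj_pair_window_s = swj_pair_window_s,
    min_saccade_amp_deg = min_saccade_amp_deg,
    target_radius_deg = target_radius_deg, dwell_ms = dwell_ms,
    anticipatory_min_latency_s = anticipatory_min_latency_s)
  num <- vapply(cfg, is.numeric, logical(1))
  if (!all(num) || any(unlist(cfg) < 0) || min_dur_ms <= 0 ||
      onset_vel_deg_s <= 0 || offset_vel_deg_s <= 0) {
    stop("detection_config: all parameters must be non-negative numbers; ",
         "thresholds and min_dur_ms strictly positive", call. = FALSE)
  }
  if (offset_vel_deg_s > onset_vel_deg_s ||
      intrusion_offset_vel_deg_s > intrusion_onset_vel_deg_s) {
    stop("detection_config: offset threshold must not exceed onset threshold",
         call. = FALSE)
  }
  structure(cfg, class = c("detection_config", "list"))
}

.empty_events <- function() {
  data.frame(onset_t = numeric(0), offset_t = numeric(0),
             amplitude = numeric(0), dir_x = numeric(0), dir_y = numeric(0),
             peak_velocity = numeric(0), mean_velocity = numeric(0),
             start_x = numeric(0), start_y = numeric(0),
             end_x = numeric(0), end_y = numeric(0))
}

#' Detect saccades with a velocity-threshold (I-VT) detector
#'
#' Finds runs where radial speed exceeds the onset threshold for the
#' minimum duration (always at least 2 samples), then refines each event's
#' onset and offset outward to the first and last sample at or above the
#' (lower) offset threshold. Amplitude is the
#' Euclidean displacement between the samples flanking the event, so the
#' full step is captured despite the coarse sample grid; mean velocity is
#' amplitude over that flanking span, peak velocity the maximum
#' central-difference speed inside the event. Events overlapping artifact
#' intervals are discarded; output is sorted by onset.
#'
#' @param rec A [gaze_recording()] (typically denoised).
#' @param config A [detection_config()].
#' @param vel Optional precomputed [velocity()] series for `rec`.
#' @param artifacts Optional artifact data frame from [remove_artifacts()].
#' @param onset_vel,offset_vel Threshold overrides (deg/s); default to the
#'   main saccade thresholds in `config`.
#' @param min_run Override for the minimum number of consecutive
#'   above-onset-threshold samples; by default derived from `min_dur_ms`
#'   (never below 2). [detect_intrusions()] passes 1: at 60 Hz a small
#'   intrusion saccade fits inside a single inter-sample interval.
#' @return A data frame of saccade events with columns `onset_t`,
#'   `offset_t`, `amplitude` (degrees), `dir_x`, `dir_y` (unit vector),
#'   `peak_velocity`, `mean_velocity` (deg/s), and the start/end gaze
#'   positions.
#' @export
detect_saccades <- function(rec, config = detection_config(), vel = NULL,
                            artifacts = NULL,
                            onset_vel = config$onset_vel_deg_s,
                            offset_vel = config$offset_vel_deg_s,
                            min_run = NULL) {
  stopifnot(inherits(rec, "gaze_recording"))
  if (is.null(vel)) vel <- velocity(rec)
  s <- rec$samples
  fs <- rec$sample_rate
  n_min <- if (is.null(min_run)) {
    max(2L, as.integer(ceiling(config$min_dur_ms / 1000 * fs - 1e-9)))
  } else as.integer(min_run)
  if (config$min_dur_ms / 1000 < 1 / fs && n_min < 2) {
    stop("detect_saccades: min duration below 2 samples at this rate",
         call. = FALSE)
  }
  v <- vel$v
  above <- !is.na(v) & v >= onset_vel
  if (!any(above)) return(.empty_events())
  runs <- .valid_runs(above)
  runs <- runs[runs$end - runs$start + 1 >= n_min, , drop = FALSE]
  if (!nrow(runs)) return(.empty_events())

  ext <- vapply(seq_len(nrow(runs)), function(k) {
    a <- runs$start[k]
    b <- runs$end[k]
    while (a > 1 && !is.na(v[a - 1]) && v[a - 1] >= offset_vel) a <- a - 1
    while (b < length(v) && !is.na(v[b + 1]) && v[b + 1] >= offset_vel) b <- b + 1
    c(a, b)
  }, numeric(2))
  a <- ext[1, ]; b <- ext[2, ]
  keep <- !duplicated(a)
  a <- a[keep]; b <- b[keep]

  events <- lapply(seq_along(a), function(k) {
    ai <- a[k]; bi <- b[k]
    # flanking samples (just below offset threshold) bound the displacement
    aa <- if (ai > 1 && !is.na(v[ai - 1])) ai - 1 else ai
    bb <- if (bi < length(v) && !is.na(v[bi + 1])) bi + 1 else bi
    onset_t <- s$t[ai]
    offset_t <- s$t[bi]
    dx <- s$x[bb] - s$x[aa]
    dy <- s$y[bb] - s$y[aa]
    amp <- sqrt(dx^2 + dy^2)
    span <- s$t[bb] - s$t[aa]
    data.frame(
      onset_t = onset_t, offset_t = offset_t, amplitude = amp,
      dir_x = if (amp > 0) dx / amp else 0,
      dir_y = if (amp > 0) dy / amp else 0,
      peak_velocity = max(v[ai:bi], na.rm = TRUE),
      mean_velocity = if (span > 0) amp / span else 0,
      start_x = s$x[aa], start_y = s$y[aa],
      end_x = s$x[bb], end_y = s$y[bb])
  })
  ev <- do.call(rbind, events)
  ev <- ev[order(ev$onset_t), , drop = FALSE]
  if (!is.null(artifacts) && nrow(artifacts)) {
    hit <- vapply(seq_len(nrow(ev)), function(k) {
      any(ev$onset_t[k] <= artifacts$end_t & ev$offset_t[k] >= artifacts$start_t)
    }, logical(1))
    ev <- ev[!hit, , drop = FALSE]
  }
  rownames(ev) <- NULL
  ev
}

#' Detect saccadic intrusions during fixation
#'
#' Runs the I-VT detector with the low intrusion threshold pair inside a
#' fixation window and keeps events of amplitude at least
#' `intrusion_min_amp_deg` (default 0.5 degrees). The first
#' `intrusion_skip_ms` of the window are skipped so the task-driven
#' acquisition saccade is not counted.
#'
#' @inheritParams detect_saccades
#' @param window Numeric length-2 vector `c(start_t, end_t)` in seconds.
#' @return A saccade-event data frame (see [detect_saccades()]); one row
#'   per intrusion saccade (a square-wave jerk contributes two rows).
#' @export
detect_intrusions <- function(rec, window, config = detection_config(),
                              vel = NULL, artifacts = NULL) {
  stopifnot(inherits(rec, "gaze_recording"))
  if (length(window) != 2 || window[2] <= window[1]) {
    stop("detect_intrusions: window must be c(start, end) with end > start",
         call. = FALSE)
  }
  if (is.null(vel)) vel <- velocity(rec)
  # adaptive threshold: lambda robust SDs of the velocity noise in the
  # window (medians are insensitive to the sparse saccade samples), with
  # the configured thresholds as floors
  inw <- vel$t >= window[1] & vel$t <= window[2] & is.finite(vel$v)
  # q75 of radial speed estimates the noise level robustly even when
  # saccade samples make up ~20% of the window; for Rayleigh noise
  # q75 = 1.665 sigma, so lambda * 0.58 * q75 ~ lambda * 0.97 sigma
  q75 <- if (sum(inw) >= 20) stats::quantile(vel$v[inw], 0.75, names = FALSE)
         else 0
  onset_vel <- max(config$intrusion_onset_vel_deg_s,
                   config$intrusion_lambda * 0.58 * q75)
  ev <- detect_saccades(rec, config, vel = vel, artifacts = artifacts,
                        onset_vel = onset_vel,
                        offset_vel = onset_vel * 2 / 3,
                        min_run = 1L)
  lo <- window[1] + config$intrusion_skip_ms / 1000
  keep <- ev$onset_t >= lo & ev$offset_t <= window[2] &
    ev$amplitude >= config$intrusion_min_amp_deg &
    ev$amplitude <= config$intrusion_max_amp_deg
  ev <- ev[keep, , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Count square-wave-jerk-aware intrusions
#'
#' Pairs consecutive intrusion saccades of roughly opposite horizontal
#' direction occurring within `pair_window_s` and counts each pair as one
#' intrusion (a square-wave jerk is a paired outward + return saccade).
#' With `pair_window_s = 0` every saccade counts individually.
#'
#' @param events Intrusion events from [detect_intrusions()].
#' @param pair_window_s Pairing window in seconds.
#' @return Integer intrusion count.
#' @export
count_intrusions <- function(events, pair_window_s = 0.25) {
  n <- nrow(events)
  if (n == 0) return(0L)
  if (pair_window_s <= 0) return(n)
  count <- 0L
  k <- 1L
  while (k <= n) {
    if (k < n &&
        events$onset_t[k + 1] - events$offset_t[k] <= pair_window_s &&
        events$dir_x[k] * events$dir_x[k + 1] < 0) {
      k <- k + 2L
    } else {
      k <- k + 1L
    }
    count <- count + 1L
  }
  count
}
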