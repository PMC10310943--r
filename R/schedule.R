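#' Trial schedules for the three oculomotor tasks
#'
#' A `trial_schedule` is a data frame with one row per trial and an attached
#' task label. Columns: `trial_id`, `target_x`, `target_y` (degrees),
#' `fixation_onset`, `target_onset`, `target_duration`, `trial_end`
#' (seconds from recording start), `eccentricity_class`
#' (`"short"`/`"large"`/`"n/a"`), and for the anti-saccade task
#' `arrow_direction`, `arrow_onset`, `arrow_duration`, `response_onset`,
#' `response_window`.
#'
#' @param trials Data frame of trials.
#' @param task Task kind.
#' @return The data frame with class `trial_schedule` and a `task` attribute.
#' @export
trial_schedule <- function(trials, task) {
  task <- match.arg(task, c("fixation", "prosaccade", "antisaccade"))
  trials <- as.data.frame(trials)
  required <- c("trial_id", "target_x", "target_y", "fixation_onset",
                "target_onset", "target_duration", "trial_end",
                "eccentricity_class")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols)) {
    stop("trial_schedule: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(trials) > 1) {
    starts <- trials$fixation_onset
    ends <- trials$trial_end
    if (any(diff(starts) <= 0) || any(starts[-1] < ends[-nrow(trials)] - 1e-9)) {
      stop("trial_schedule: trial windows must be increasing and non-overlapping",
           call. = FALSE)
    }
  }
  structure(trials, class = c("trial_schedule", "data.frame"), task = task)
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat(sprintf("<trial_schedule> task %s: %d trials over %.1f s\n",
              attr(x, "task"), nrow(x), max(x$trial_end)))
  NextMethod()
}

#' Task kind of a schedule
#' @param schedule A [trial_schedule()].
#' @return Character scalar.
#' @export
schedule_task <- function(schedule) attr(schedule, "task")

# Canonical target geometry (degrees of visual angle).
# Fixation: centre, +/-10 horizontal, +/-14 vertical.
# Pro-saccade: short 5 deg horizontal / 6 deg vertical,
#              large 10 deg horizontal / 12 deg vertical.
# Anti-saccade: +/-10 deg horizontal.
.fixation_positions <- function() {
  data.frame(target_x = c(0, -10, 10, 0, 0), target_y = c(0, 0, 0, -14, 14))
}

.prosaccade_locations <- function() {
  data.frame(
    target_x = c(-5, 5, 0, 0, -10, 10, 0, 0),
    target_y = c(0, 0, -6, 6, 0, 0, -12, 12),
    eccentricity_class = rep(c("short", "large"), each = 4))
}

#' Build a task schedule
#'
#' Emits the canonical trial sequence for one task:
#' * fixation: 5 trials of 7 s, one per canonical location (centre,
#'   10 degrees left/right, 14 degrees up/down), order shuffled;
#' * prosaccade: 8 locations (4 directions x short/large eccentricity)
#'   sampled 3 times each, 24 trials; each trial a central fixation point
#'   for a random 1.0-3.5 s followed by the eccentric target for 1.5 s;
#' * antisaccade: targets at +/-10 degrees horizontal shown 100 ms,
#'   1,200 ms blank, a 400 ms arrow (uniform over left/right/up/down) at
#'   the location opposite the target, then a 5 s response screen.
#'
#' @param task `"fixation"`, `"prosaccade"` or `"antisaccade"`.
#' @param seed Integer seed controlling trial order and random durations.
#' @param n_trials Number of anti-saccade trials (default 12; ignored for
#'   the other tasks, whose counts are fixed by the protocol).
#' @return A [trial_schedule()].
#' @export
#' @examples
#' nrow(make_schedule("prosaccade", seed = 1))  # 24
make_schedule <- function(task, seed = 1, n_trials = 12) {
  task <- match.arg(task, c("fixation", "prosaccade", "antisaccade"))
  rng <- local_rng(seed)
  if (task == "fixation") {
    pos <- .fixation_positions()[sample.int(5), ]
    onset <- 7 * (seq_len(5) - 1)
    trials <- data.frame(
      trial_id = seq_len(5), target_x = pos$target_x, target_y = pos$target_y,
      fixation_onset = onset, target_onset = onset, target_duration = 7,
      trial_end = onset + 7, eccentricity_class = "n/a")
  } else if (task == "prosaccade") {
    loc <- .prosaccade_locations()
    loc <- loc[rep(seq_len(8), 3), ]
    loc <- loc[sample.int(24), ]
    fix_dur <- stats::runif(24, 1.0, 3.5)
    t0 <- cumsum(c(0, fix_dur[-24] + 1.5))
    trials <- data.frame(
      trial_id = seq_len(24), target_x = loc$target_x, target_y = loc$target_y,
      fixation_onset = t0, target_onset = t0 + fix_dur, target_duration = 1.5,
      trial_end = t0 + fix_dur + 1.5, eccentricity_class = loc$eccentricity_class)
  } else {
    side <- sample(rep(c(-1, 1), length.out = n_trials))
    fix_dur <- stats::runif(n_trials, 1.0, 3.5)
    arrow_dir <- sample(c("left", "right", "up", "down"), n_trials,
                        replace = TRUE)
    trial_len <- fix_dur + 0.1 + 1.2 + 0.4 + 5
    t0 <- cumsum(c(0, trial_len[-n_trials]))
    target_onset <- t0 + fix_dur
    arrow_onset <- target_onset + 0.1 + 1.2
    trials <- data.frame(
      trial_id = seq_len(n_trials), target_x = 10 * side, target_y = 0,
      fixation_onset = t0, target_onset = target_onset, target_duration = 0.1,
      trial_end = t0 + trial_len, eccentricity_class = "n/a",
      arrow_direction = arrow_dir, arrow_onset = arrow_onset,
      arrow_duration = 0.4, response_onset = arrow_onset + 0.4,
      response_window = 5)
  }
  rng()  # restore RNG state
  trial_schedule(trials, task)
}

#' Write a schedule to JSON
#'
#' One JSON object per trial plus a task-level metadata block
#' (`task`, `sample_rate`).
#'
#' @param schedule A [trial_schedule()].
#' @param path Output path.
#' @param sample_rate Recording rate recorded in the metadata block.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path, sample_rate = 60) {
  stopifnot(inherits(schedule, "trial_schedule"))
  obj <- list(
    meta = list(task = schedule_task(schedule), sample_rate = sample_rate),
    trials = as.data.frame(schedule))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read a schedule from JSON
#'
#' @param path Path written by [write_schedule()].
#' @return A [trial_schedule()]; the metadata `sample_rate` is attached as
#'   an attribute of the same name.
#' @export
read_schedule <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$meta$task)) {
    stop(sprintf("schedule JSON %s: missing meta.task", path), call. = FALSE)
  }
  sched <- trial_schedule(obj$trials, obj$meta$task)
  attr(sched, "sample_rate") <- obj$meta$sample_rate
  sched
}

# Run code under a temporary RNG seed; returns a restorer to call when done.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    invisible(NULL)
  }
}
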