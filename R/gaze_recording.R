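#' Gaze recording container
#'
#' A `gaze_recording` holds one subject's gaze trace for one task: a sample
#' table with time (seconds from recording start), horizontal and vertical
#' gaze position in degrees of visual angle (screen-centre origin, right/up
#' positive), and a per-sample validity flag. Invalid samples are carried
#' with their flag; preprocessing, not I/O, decides their fate.
#'
#' @param subject_id Subject identifier (scalar character).
#' @param task One of `"fixation"`, `"prosaccade"`, `"antisaccade"`.
#' @param samples Data frame with columns `t`, `x`, `y`, `valid` (and
#'   optionally `trial_id`).
#' @param sample_rate Nominal sampling rate in Hz (default 60).
#'
#' @return An object of class `gaze_recording`.
#' @export
gaze_recording <- function(subject_id, task, samples, sample_rate = 60) {
  task <- match.arg(task, c("fixation", "prosaccade", "antisaccade"))
  required <- c("t", "x", "y", "valid")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols)) {
    stop("gaze_recording: samples missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  samples$valid <- as.logical(samples$valid)
  rec <- structure(
    list(subject_id = as.character(subject_id)[1], task = task,
         samples = as.data.frame(samples), sample_rate = sample_rate),
    class = "gaze_recording")
  validate_gaze_recording(rec)
}

#' Validate a gaze recording
#'
#' Checks the container invariants: at least two samples, non-decreasing
#' time, gaze within a +/-60 degree sanity bound (invalid samples exempt),
#' and a median inter-sample interval within 20% of the nominal one.
#'
#' @param rec A [gaze_recording()].
#' @return `rec`, invisibly unchanged, or an error.
#' @export
validate_gaze_recording <- function(rec) {
  stopifnot(inherits(rec, "gaze_recording"))
  s <- rec$samples
  if (nrow(s) < 2) {
    stop("gaze_recording: need at least 2 samples", call. = FALSE)
  }
  dt <- diff(s$t)
  if (any(dt < 0)) {
    stop(sprintf("gaze_recording: time not non-decreasing at row %d",
                 which(dt < 0)[1] + 1), call. = FALSE)
  }
  ok <- s$valid & is.finite(s$x) & is.finite(s$y)
  if (any(abs(s$x[ok]) > 60 | abs(s$y[ok]) > 60)) {
    stop("gaze_recording: valid gaze outside the +/-60 degree sanity bound",
         call. = FALSE)
  }
  med_dt <- stats::median(dt[dt > 0])
  nominal <- 1 / rec$sample_rate
  if (!is.finite(med_dt) || abs(med_dt - nominal) > 0.2 * nominal) {
    stop(sprintf(
      "gaze_recording: median inter-sample interval %.4f s is not within 20%% of nominal %.4f s",
      med_dt, nominal), call. = FALSE)
  }
  rec
}

#' @export
print.gaze_recording <- function(x, ...) {
  s <- x$samples
  cat(sprintf(
    "<gaze_recording> subject %s, task %s: %d samples @ %g Hz (%.1f s, %.1f%% valid)\n",
    x$subject_id, x$task, nrow(s), x$sample_rate,
    diff(range(s$t)), 100 * mean(s$valid)))
  invisible(x)
}

#' Read a gaze recording from CSV
#'
#' Expects the gaze CSV dialect: header
#' `subject_id,task,trial_id,t,x_deg,y_deg,valid`, UTF-8, `.` decimal.
#' Rows with `valid = 0` are retained and flagged, never dropped; files
#' with missing columns or non-monotone time are rejected.
#'
#' @param path Path to a gaze CSV file.
#' @return A [gaze_recording()] whose samples carry a `trial_id` column.
#' @export
read_recording <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "task", "trial_id", "t", "x_deg", "y_deg", "valid")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("gaze CSV %s: missing required column(s): %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0) stop(sprintf("gaze CSV %s: no data rows", path), call. = FALSE)
  if (anyNA(df$t) || !is.numeric(df$t)) {
    stop(sprintf("gaze CSV %s: non-numeric or missing t values", path),
         call. = FALSE)
  }
  inv <- which(diff(df$t) < 0)
  if (length(inv)) {
    stop(sprintf("gaze CSV %s: time decreases at data row %d", path, inv[1] + 1),
         call. = FALSE)
  }
  gaze_recording(
    subject_id = df$subject_id[1],
    task = df$task[1],
    samples = data.frame(t = df$t, x = df$x_deg, y = df$y_deg,
                         valid = df$valid != 0, trial_id = df$trial_id),
    sample_rate = attr(df, "sample_rate") %||% 60)
}

#' Write a gaze recording to CSV
#'
#' Inverse of [read_recording()]; writes the gaze CSV dialect.
#'
#' @param rec A [gaze_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "gaze_recording"))
  s <- rec$samples
  out <- data.frame(
    subject_id = rec$subject_id, task = rec$task,
    trial_id = s$trial_id %||% NA_integer_,
    t = s$t, x_deg = s$x, y_deg = s$y, valid = as.integer(s$valid))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
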