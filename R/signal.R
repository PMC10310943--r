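#' Denoise a gaze recording
#'
#' Two-stage filter applied independently to the horizontal and vertical
#' channels of each contiguous run of valid samples: a 5-sample running
#' median (removes single-sample spikes without blurring saccade steps)
#' followed by Savitzky-Golay local quadratic smoothing (window 5), which
#' attenuates tracker noise while displacing a step edge by at most one
#' sample. The time base and validity flags are untouched; runs shorter
#' than the filter window are left as-is.
#'
#' @param rec A [gaze_recording()] with at least 5 samples.
#' @return The denoised [gaze_recording()].
#' @export
denoise <- function(rec) {
  stopifnot(inherits(rec, "gaze_recording"))
  if (nrow(rec$samples) < 5) {
    stop("denoise: need at least 5 samples", call. = FALSE)
  }
  s <- rec$samples
  runs <- .valid_runs(s$valid & is.finite(s$x) & is.finite(s$y))
  for (k in seq_len(nrow(runs))) {
    idx <- runs$start[k]:runs$end[k]
    if (length(idx) < 5) next
    s$x[idx] <- .median_sg(s$x[idx])
    s$y[idx] <- .median_sg(s$y[idx])
  }
  rec$samples <- s
  rec
}

# 5-sample running median then Savitzky-Golay quadratic (window 5).
# SG kernel for degree-2, window-5 smoothing: (-3, 12, 17, 12, -3)/35.
.median_sg <- function(x) {
  m <- stats::runmed(x, k = 5, endrule = "median")
  kern <- c(-3, 12, 17, 12, -3) / 35
  sm <- stats::filter(m, kern, sides = 2)
  sm <- as.numeric(sm)
  edge <- c(1, 2, length(x) - 1, length(x))
  sm[edge] <- m[edge]
  sm
}

# Median-only filtering (step-preserving): used in front of the event
# detector, where quadratic smoothing would attenuate the 1-2 sample
# transients that saccades produce at 60 Hz.
.median_filter_rec <- function(rec) {
  s <- rec$samples
  runs <- .valid_runs(s$valid & is.finite(s$x) & is.finite(s$y))
  for (k in seq_len(nrow(runs))) {
    idx <- runs$start[k]:runs$end[k]
    if (length(idx) < 5) next
    s$x[idx] <- stats::runmed(s$x[idx], k = 5, endrule = "median")
    s$y[idx] <- stats::runmed(s$y[idx], k = 5, endrule = "median")
  }
  rec$samples <- s
  rec
}

# Runs of TRUE in a logical vector -> data.frame(start, end).
.valid_runs <- function(valid) {
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Detect and mask non-saccadic artifacts
#'
#' Marks blinks and tracker artifacts: runs of invalid samples (blink /
#' dropout) and samples implying physiologically impossible speed
#' (two-point velocity above `max_vel_deg_s`, default 1,000 deg/s; spikes).
#' Each interval is padded by `artifact_pad_ms` on both sides (default
#' 50 ms); overlapping intervals are merged. Samples inside an interval are
#' flagged invalid; no valid sample's position is altered.
#'
#' @param rec A [gaze_recording()].
#' @param config A [detection_config()].
#' @param max_vel_deg_s Spike threshold in deg/s.
#' @return A list with `recording` (flags updated) and `artifacts`, a data
#'   frame with columns `start_t`, `end_t`, `kind`
#'   (`"blink"`/`"spike"`).
#' @export
remove_artifacts <- function(rec, config = detection_config(),
                             max_vel_deg_s = 1000) {
  stopifnot(inherits(rec, "gaze_recording"))
  s <- rec$samples
  n <- nrow(s)
  pad <- config$artifact_pad_ms / 1000
  ivals <- list()

  bad <- !s$valid | !is.finite(s$x) | !is.finite(s$y)
  if (any(bad)) {
    runs <- .valid_runs(bad)
    for (k in seq_len(nrow(runs))) {
      ivals[[length(ivals) + 1]] <- data.frame(
        start_t = s$t[runs$start[k]] - pad,
        end_t = s$t[runs$end[k]] + pad, kind = "blink")
    }
  }

  # spikes: impossible sample-to-sample speed between valid samples
  if (n > 1) {
    dt <- diff(s$t)
    sp <- sqrt(diff(s$x)^2 + diff(s$y)^2) / pmax(dt, 1e-9)
    sp[bad[-n] | bad[-1]] <- 0
    hit <- which(is.finite(sp) & sp > max_vel_deg_s)
    for (i in hit) {
      ivals[[length(ivals) + 1]] <- data.frame(
        start_t = s$t[i] - pad, end_t = s$t[i + 1] + pad, kind = "spike")
    }
  }

  if (!length(ivals)) {
    return(list(recording = rec,
                artifacts = data.frame(start_t = numeric(0),
                                       end_t = numeric(0),
                                       kind = character(0))))
  }
  iv <- do.call(rbind, ivals)
  iv <- .merge_intervals(iv[order(iv$start_t), , drop = FALSE])
  iv$start_t <- pmax(iv$start_t, s$t[1])
  iv$end_t <- pmin(iv$end_t, s$t[n])
  for (k in seq_len(nrow(iv))) {
    s$valid[s$t >= iv$start_t[k] & s$t <= iv$end_t[k]] <- FALSE
  }
  rec$samples <- s
  list(recording = rec, artifacts = iv)
}

.merge_intervals <- function(iv) {
  if (nrow(iv) < 2) return(iv)
  out <- iv[1, , drop = FALSE]
  for (k in 2:nrow(iv)) {
    last <- nrow(out)
    if (iv$start_t[k] <= out$end_t[last]) {
      out$end_t[last] <- max(out$end_t[last], iv$end_t[k])
      if (out$kind[last] != iv$kind[k]) out$kind[last] <- "blink"
    } else {
      out <- rbind(out, iv[k, , drop = FALSE])
    }
  }
  out
}

#' Gaze velocity by central differences
#'
#' Radial speed and per-axis components in deg/s. Central differences on
#' the interior of each valid run, one-sided differences at run endpoints;
#' samples outside valid runs (and runs of length 1) get `NA` velocity.
#'
#' @param rec A [gaze_recording()].
#' @return A data frame of class `velocity_series` with columns `t`, `v`,
#'   `vx`, `vy`, aligned sample-for-sample with the recording.
#' @export
velocity <- function(rec) {
  stopifnot(inherits(rec, "gaze_recording"))
  s <- rec$samples
  n <- nrow(s)
  vx <- vy <- rep(NA_real_, n)
  runs <- .valid_runs(s$valid & is.finite(s$x) & is.finite(s$y))
  for (k in seq_len(nrow(runs))) {
    idx <- runs$start[k]:runs$end[k]
    m <- length(idx)
    if (m < 2) next
    t <- s$t[idx]; x <- s$x[idx]; y <- s$y[idx]
    gx <- gy <- numeric(m)
    if (m > 2) {
      i <- 2:(m - 1)
      dt2 <- t[i + 1] - t[i - 1]
      gx[i] <- (x[i + 1] - x[i - 1]) / dt2
      gy[i] <- (y[i + 1] - y[i - 1]) / dt2
    }
    gx[1] <- (x[2] - x[1]) / (t[2] - t[1])
    gy[1] <- (y[2] - y[1]) / (t[2] - t[1])
    gx[m] <- (x[m] - x[m - 1]) / (t[m] - t[m - 1])
    gy[m] <- (y[m] - y[m - 1]) / (t[m] - t[m - 1])
    vx[idx] <- gx
    vy[idx] <- gy
  }
  structure(data.frame(t = s$t, v = sqrt(vx^2 + vy^2), vx = vx, vy = vy),
            class = c("velocity_series", "data.frame"))
}
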