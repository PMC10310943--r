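# Shared fixture builders: all synthetic, constructed at test time.

# A single saccadic step with a raised-cosine profile plus white noise.
# Returns the recording and the exact injected event parameters.
make_step_trace <- function(amp, theta = 0, noise_sd = 0, onset = 1,
                            fs = 60, len = 2.5, vmax = 500, cc = 5,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, len, by = 1 / fs)
  peak <- vmax * (1 - exp(-amp / cc))
  dur <- 2 * amp / peak
  frac <- pmin(pmax((t - onset) / dur, 0), 1)
  sfrac <- frac - sin(2 * pi * frac) / (2 * pi)
  x <- amp * cos(theta) * sfrac
  y <- amp * sin(theta) * sfrac
  if (noise_sd > 0) {
    x <- x + rnorm(length(t), 0, noise_sd)
    y <- y + rnorm(length(t), 0, noise_sd)
  }
  rec <- gaze_recording("step", "prosaccade",
                        data.frame(t = t, x = x, y = y, valid = TRUE),
                        sample_rate = fs)
  list(rec = rec, onset = onset, amp = amp, duration = dur, peak = peak)
}

# A constant-position fixation trace with optional white noise.
make_fixation_trace <- function(n = 420, noise_sd = 0, x0 = 0, y0 = 0,
                                fs = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- (seq_len(n) - 1) / fs
  gaze_recording("fix", "fixation",
                 data.frame(t = t,
                            x = x0 + rnorm(n, 0, noise_sd),
                            y = y0 + rnorm(n, 0, noise_sd),
                            valid = TRUE),
                 sample_rate = fs)
}

# Parameter table with two linearly separable groups on the default
# classifier features (all other canonical parameters constant).
make_separable_table <- function(n_per_group = 20, gap = 10, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  tab <- data.frame(subject_id = sprintf("s%03d", seq_len(n)),
                    group = rep(c("HC", "PD"), each = n_per_group),
                    age = round(runif(n, 50, 75)),
                    sex = sample(c("F", "M"), n, replace = TRUE),
                    updrs3 = NA_real_)
  for (nm in canonical_parameter_names()) tab[[nm]] <- rnorm(n)
  tab$fix_intrusion_rate <- rnorm(n) + ifelse(tab$group == "PD", gap, 0)
  tab
}

# Null table: identical distributions in both groups.
make_null_table <- function(n_per_group = 50, seed = 1) {
  make_separable_table(n_per_group, gap = 0, seed = seed)
}
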