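#' Assemble a per-subject parameter row
#'
#' Validates that the parameter map carries exactly the canonical 24-name
#' set ([canonical_parameter_names()]) and binds it to the subject's
#' demographics. Missing parameter values stay explicit `NA`s.
#'
#' @param subject_id Identifier.
#' @param group `"PD"` or `"HC"`.
#' @param age Years.
#' @param sex `"F"` or `"M"`.
#' @param updrs3 MDS-UPDRS part III motor score (0-132) or `NA`.
#' @param params Named list/vector of the 24 oculomotor parameters.
#' @return One-row data frame `subject_id, group, age, sex, updrs3, <24>`.
#' @export
subject_parameters <- function(subject_id, group, age, sex, updrs3 = NA_real_,
                               params) {
  group <- match.arg(group, c("PD", "HC"))
  canon <- canonical_parameter_names()
  if (!setequal(names(params), canon)) {
    stop("subject_parameters: parameter names must be exactly the canonical ",
         "24-name set; got ", length(params), " names (missing: ",
         paste(setdiff(canon, names(params)), collapse = ", "), ")",
         call. = FALSE)
  }
  if (is.finite(updrs3) && (updrs3 < 0 || updrs3 > 132)) {
    stop("subject_parameters: updrs3 must be in [0, 132]", call. = FALSE)
  }
  cbind(data.frame(subject_id = as.character(subject_id), group = group,
                   age = age, sex = sex, updrs3 = updrs3),
        as.data.frame(as.list(unlist(params)[canon])))
}

#' Extract the 24 oculomotor parameters for one subject
#'
#' Runs the full per-subject pipeline: artifact removal, denoising,
#' saccade detection, then the fixation, pro-saccade and anti-saccade
#' metrics, aggregated to the canonical parameter set.
#'
#' @param recordings Named list with elements `fixation`, `prosaccade`,
#'   `antisaccade`, each a [gaze_recording()] (any subset allowed; missing
#'   tasks yield `NA` parameters).
#' @param schedules Named list of matching [trial_schedule()]s.
#' @param config A [detection_config()].
#' @param demographics List with `group`, `age`, `sex`, `updrs3`.
#' @return List with `parameters` (one-row data frame, see
#'   [subject_parameters()]) and `qc` (per-trial status data frame).
#' @export
extract_subject <- function(recordings, schedules,
                            config = detection_config(),
                            demographics = list(group = "HC", age = NA_real_,
                                                sex = NA_character_,
                                                updrs3 = NA_real_)) {
  params <- stats::setNames(as.list(rep(NA_real_, 24)),
                            canonical_parameter_names())
  qc <- list()

  # detection runs on step-preserving median-filtered positions; the
  # fixation dispersion metrics see the unsmoothed (artifact-masked) signal
  prep <- function(rec) {
    art <- remove_artifacts(rec, config)
    rec_m <- .median_filter_rec(art$recording)
    list(rec = rec_m, raw = art$recording, artifacts = art$artifacts,
         events = detect_saccades(rec_m, config, artifacts = art$artifacts))
  }

  if (!is.null(recordings$fixation)) {
    p <- prep(recordings$fixation)
    fm <- fixation_metrics(p$raw, schedules$fixation, config, p$artifacts)
    params[paste0("fix_", c("bcea68", "bcea95", "sd_h", "sd_v",
                            "intrusion_rate"))] <-
      fm[c("bcea68", "bcea95", "sd_h", "sd_v", "intrusion_rate")]
    qc[[length(qc) + 1]] <- data.frame(
      task = "fixation", trial_id = NA_integer_,
      status = sprintf("%d/%d trials used", fm$n_trials_used,
                       nrow(schedules$fixation)))
  }

  if (!is.null(recordings$prosaccade)) {
    p <- prep(recordings$prosaccade)
    sched <- schedules$prosaccade
    rows <- do.call(rbind, lapply(seq_len(nrow(sched)), function(k) {
      prosaccade_trial(p$rec, sched[k, ], p$events, config)
    }))
    agg <- aggregate_prosaccade(rows)
    nm <- grep("^pro_", names(agg), value = TRUE)
    params[nm] <- agg[nm]
    qc[[length(qc) + 1]] <- data.frame(task = "prosaccade",
                                       trial_id = rows$trial_id,
                                       status = rows$status)
  }

  if (!is.null(recordings$antisaccade)) {
    p <- prep(recordings$antisaccade)
    sched <- schedules$antisaccade
    rows <- do.call(rbind, lapply(seq_len(nrow(sched)), function(k) {
      antisaccade_trial(p$rec, sched[k, ], p$events, config)
    }))
    agg <- aggregate_antisaccade(rows)
    nm <- grep("^anti_", names(agg), value = TRUE)
    params[nm] <- agg[nm]
    qc[[length(qc) + 1]] <- data.frame(task = "antisaccade",
                                       trial_id = rows$trial_id,
                                       status = rows$status)
  }

  list(parameters = subject_parameters(
         recordings[[1]]$subject_id, demographics$group, demographics$age,
         demographics$sex, demographics$updrs3 %||% NA_real_, params),
       qc = do.call(rbind, qc))
}

#' Write a parameter table to CSV
#'
#' Columns `subject_id,group,age,sex,updrs3,<parameters...>`. Numeric
#' values are written with 17 significant digits so a read/write
#' round-trip is value-preserving (to 1e-12 relative tolerance) and a
#' second write is byte-identical.
#'
#' @param rows Data frame of [subject_parameters()] rows (or an empty data
#'   frame with the right columns for a header-only file).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(rows, path) {
  fixed <- c("subject_id", "group", "age", "sex", "updrs3")
  missing_cols <- setdiff(fixed, names(rows))
  if (length(missing_cols)) {
    stop("write_parameter_table: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- rows
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) {
      out[[nm]] <- ifelse(is.na(out[[nm]]), "NA",
                          sprintf("%.17g", out[[nm]]))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a parameter table written by [write_parameter_table()]
#'
#' @param path CSV path.
#' @return Data frame with demographics columns and parameter columns.
#' @export
read_parameter_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  fixed <- c("subject_id", "group", "age", "sex", "updrs3")
  missing_cols <- setdiff(fixed, names(df))
  if (length(missing_cols)) {
    stop(sprintf("parameter table %s: missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df
}
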