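.default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "oculokit_out",
    log_level = "info",
    simulate = list(n_per_group = 10L, antisaccade_trials = 12L,
                    sample_rate = 60),
    input = list(gaze_dir = NULL, schedule_dir = NULL, subjects_csv = NULL),
    detection = unclass(detection_config()),
    analysis = list(normality_alpha = 0.05, fdr_alpha = 0.05),
    classifier = list(n_subsamples = 1000L, split_fraction = 0.7,
                      ridge_strength = 1, add_age = FALSE))
}

.merge_strict <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- paste0(path, key)
    if (!key %in% names(defaults)) {
      stop(sprintf("config: unknown key '%s'", full), call. = FALSE)
    }
    if (is.list(defaults[[key]]) && !is.null(user[[key]]) &&
        !is.list(user[[key]])) {
      stop(sprintf("config: key '%s' must be a mapping", full), call. = FALSE)
    }
    if (is.list(defaults[[key]]) && length(names(defaults[[key]]))) {
      defaults[[key]] <- .merge_strict(defaults[[key]], user[[key]],
                                       paste0(full, "."))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Validate and normalise a pipeline configuration
#'
#' Reads a YAML or JSON configuration, rejects unknown keys (strict mode,
#' so a misspelled threshold cannot silently fall back to a default),
#' fills defaults (e.g. FDR alpha 0.05), and range-checks alphas, seeds
#' and paths.
#'
#' @param path Config file path (`.yaml`/`.yml`/`.json`), or a named list.
#' @return A normalised list of class `run_config`.
#' @export
validate_config <- function(path) {
  user <- if (is.list(path)) {
    path
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- .merge_strict(.default_run_config(), user)
  for (a in c(cfg$analysis$normality_alpha, cfg$analysis$fdr_alpha)) {
    if (!is.numeric(a) || a <= 0 || a >= 1) {
      stop("config: alphas must lie in (0, 1)", call. = FALSE)
    }
  }
  if (!is.numeric(cfg$seed)) stop("config: seed must be an integer",
                                  call. = FALSE)
  if (cfg$classifier$split_fraction <= 0 || cfg$classifier$split_fraction >= 1) {
    stop("config: classifier.split_fraction must lie in (0, 1)",
         call. = FALSE)
  }
  do.call(detection_config, cfg$detection)  # range-checks the block
  if (!is.null(cfg$input$gaze_dir) && !dir.exists(cfg$input$gaze_dir)) {
    stop(sprintf("config: input.gaze_dir '%s' does not exist",
                 cfg$input$gaze_dir), call. = FALSE)
  }
  structure(cfg, class = c("run_config", "list"))
}

#' Write a simulated cohort to disk
#'
#' Emits per-subject gaze CSVs (`<subject>_<task>.csv`), schedule JSONs
#' (`<subject>_<task>_schedule.json`) and `truth.csv` with the generating
#' values.
#'
#' @param cohort A [synth_cohort()] result.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (sub in cohort$subjects) {
    for (task in names(sub$recordings)) {
      gp <- file.path(out_dir, sprintf("%s_%s.csv", sub$subject_id, task))
      sp <- file.path(out_dir, sprintf("%s_%s_schedule.json",
                                       sub$subject_id, task))
      write_recording(sub$recordings[[task]], gp)
      write_schedule(sub$schedules[[task]], sp,
                     sub$recordings[[task]]$sample_rate)
      paths <- c(paths, gp, sp)
    }
  }
  tp <- file.path(out_dir, "truth.csv")
  utils::write.csv(cohort$truth, tp, row.names = FALSE, quote = FALSE)
  invisible(c(paths, tp))
}

#' Extract parameters for every subject found in a directory
#'
#' Expects the [write_cohort()] layout plus a subjects table
#' (`truth.csv` or a `subjects_csv`) carrying
#' `subject_id, group, age, sex, updrs3`.
#'
#' @param gaze_dir Directory of gaze CSVs and schedule JSONs.
#' @param subjects Data frame of subject demographics.
#' @param config A [detection_config()].
#' @return List with `parameters` (table) and `qc` (per-trial statuses).
#' @export
extract_from_dir <- function(gaze_dir, subjects,
                             config = detection_config()) {
  rows <- list()
  qcs <- list()
  for (k in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[k]
    recs <- list()
    scheds <- list()
    for (task in c("fixation", "prosaccade", "antisaccade")) {
      gp <- file.path(gaze_dir, sprintf("%s_%s.csv", sid, task))
      sp <- file.path(gaze_dir, sprintf("%s_%s_schedule.json", sid, task))
      if (file.exists(gp) && file.exists(sp)) {
        recs[[task]] <- read_recording(gp)
        scheds[[task]] <- read_schedule(sp)
      }
    }
    if (!length(recs)) next
    res <- extract_subject(recs, scheds, config,
                           demographics = list(group = subjects$group[k],
                                               age = subjects$age[k],
                                               sex = subjects$sex[k],
                                               updrs3 = subjects$updrs3[k]))
    rows[[length(rows) + 1]] <- res$parameters
    qc <- res$qc
    qc$subject_id <- sid
    qcs[[length(qcs) + 1]] <- qc
  }
  list(parameters = do.call(rbind, rows), qc = do.call(rbind, qcs))
}

#' Run the end-to-end pipeline
#'
#' Orchestrates `simulate -> extract -> stats -> classify` under one
#' configuration: simulates a cohort (unless `input.gaze_dir` points at
#' existing recordings), extracts the parameter table with a QC sidecar,
#' runs the statistical layer, evaluates the classifier, and writes a
#' manifest with an MD5 checksum per output. Re-running an identical
#' config reproduces identical checksums.
#'
#' @param config A config path or [validate_config()] result.
#' @return List with `status` (0 on success), `manifest` (data frame of
#'   outputs and checksums) and `outputs` (paths), invisibly on success.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  det <- do.call(detection_config, cfg$detection)
  log_msg <- function(...) {
    if (!identical(cfg$log_level, "quiet")) message(sprintf(...))
  }
  outputs <- character(0)
  stage <- "config"
  status <- 0L
  tryCatch({
    stage <- "config"
    cfg_echo <- file.path(out, "config_used.json")
    jsonlite::write_json(unclass(cfg), cfg_echo, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
    outputs <- c(outputs, cfg_echo)

    stage <- "simulate"
    gaze_dir <- cfg$input$gaze_dir
    if (is.null(gaze_dir)) {
      log_msg("simulate: %d subjects per group", cfg$simulate$n_per_group)
      cohort <- synth_cohort(cohort_config(
        n_per_group = cfg$simulate$n_per_group, seed = cfg$seed,
        antisaccade_trials = cfg$simulate$antisaccade_trials,
        sample_rate = cfg$simulate$sample_rate))
      gaze_dir <- file.path(out, "gaze")
      outputs <- c(outputs, write_cohort(cohort, gaze_dir))
      subjects <- cohort$truth[, c("subject_id", "group", "age", "sex",
                                   "updrs3")]
    } else {
      sc <- cfg$input$subjects_csv %||% file.path(gaze_dir, "truth.csv")
      subjects <- utils::read.csv(sc, stringsAsFactors = FALSE,
                                  colClasses = c(subject_id = "character"))
    }

    stage <- "extract"
    log_msg("extract: %d subjects", nrow(subjects))
    ext <- extract_from_dir(gaze_dir, subjects, det)
    pt <- file.path(out, "parameters.csv")
    write_parameter_table(ext$parameters, pt)
    qcp <- file.path(out, "qc.csv")
    utils::write.csv(ext$qc, qcp, row.names = FALSE, quote = FALSE)
    outputs <- c(outputs, pt, qcp)

    stage <- "stats"
    log_msg("stats")
    res <- analyze_parameter_table(ext$parameters,
                                   cfg$analysis$normality_alpha)
    for (nm in c("correlations", "comparisons", "mancova")) {
      if (is.null(res[[nm]])) next
      p <- file.path(out, paste0(nm, ".csv"))
      utils::write.csv(res[[nm]], p, row.names = FALSE, quote = FALSE)
      outputs <- c(outputs, p)
    }

    stage <- "classify"
    log_msg("classify: %d subsamples", cfg$classifier$n_subsamples)
    rep <- subsample_evaluate(
      ext$parameters, n_subsamples = cfg$classifier$n_subsamples,
      split_fraction = cfg$classifier$split_fraction, seed = cfg$seed,
      ridge_strength = cfg$classifier$ridge_strength,
      add_age = cfg$classifier$add_age)
    rp <- file.path(out, "classifier_report.json")
    jsonlite::write_json(unclass(rep), rp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    rocp <- file.path(out, "roc_curve.csv")
    utils::write.csv(data.frame(fpr = rep$fpr_grid, tpr_mean = rep$tpr_mean,
                                tpr_lo = rep$tpr_lo, tpr_hi = rep$tpr_hi),
                     rocp, row.names = FALSE, quote = FALSE)
    outputs <- c(outputs, rp, rocp)
  }, error = function(e) {
    message(sprintf("pipeline failed at stage '%s': %s", stage,
                    conditionMessage(e)))
    status <<- 1L
  })

  manifest <- data.frame(file = sub(paste0("^", out, "/?"), "", outputs),
                         md5 = unname(tools::md5sum(outputs)))
  utils::write.csv(manifest, file.path(out, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  res <- list(status = status, manifest = manifest, outputs = outputs)
  if (status == 0L) invisible(res) else res
}
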