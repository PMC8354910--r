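#' Default experiment configuration
#'
#' Nested list of every tunable in the pipeline, grouped by stage.  All
#' design constants of the emulated study surface here: 18 s blocks, TR
#' 3 s, 4 trials per class, 200 resting scans, 2 dropped scans per block,
#' 0.010–0.10 Hz fourth-order band-pass, 1000 null iterations, alpha 0.05,
#' top-10% weight maps.
#'
#' @param n_subjects subjects to simulate.
#' @param seed master seed; per-subject seeds are derived from it (see
#'   [subject_seed()]).
#' @return Nested configuration list.
#' @export
experiment_config <- function(n_subjects = 5L, seed = 1L) {
  list(
    simulation = list(
      n_subjects = as.integer(n_subjects),
      n_voxels = 200L,
      n_sessions = 8L,
      tr_seconds = 3,
      block_seconds = 18,
      trials_per_class_per_session = 4L,
      rest_scans = 200L,
      task_amplitude = 1.5,
      rc_amplitude = 3,
      noise_sd = 1,
      pattern_overlap = 0.1,
      nuisance_gain = 0.5,
      seed = as.integer(seed)
    ),
    preprocessing = list(
      drop_initial = 2L,
      low_hz = 0.010,
      high_hz = 0.10,
      filter_order = 4L
    ),
    decoder = list(
      lambda = 1,
      top_fraction = 0.10
    ),
    null = list(
      n_iterations = 1000L,
      normalize_scans = TRUE
    ),
    significance = list(
      alpha = 0.05
    ),
    output = list(
      write_weight_maps = FALSE
    )
  )
}

#' Derive a per-subject seed from the master seed
#'
#' Documented splitting rule: subject `i` under master seed `m` uses
#' `(m + i * 100003) mod (2^31 - 1)`; the surrogate null for that subject
#' uses the subject seed plus 49999 under the same modulus.
#'
#' @param master master seed.
#' @param i subject index (1-based).
#' @return Integer seed.
#' @export
subject_seed <- function(master, i) {
  as.integer((as.double(master) + as.double(i) * 100003) %% 2147483647)
}

null_seed <- function(master, i) {
  as.integer((as.double(subject_seed(master, i)) + 49999) %% 2147483647)
}

# merge user config over defaults, erroring on unknown keys
merge_config <- function(user, defaults = experiment_config()) {
  if (is.null(user)) return(defaults)
  bad <- character(0)
  for (section in names(user)) {
    if (!section %in% names(defaults)) { bad <- c(bad, section); next }
    for (key in names(user[[section]])) {
      if (!key %in% names(defaults[[section]]))
        bad <- c(bad, paste(section, key, sep = "."))
      else defaults[[section]][[key]] <- user[[section]][[key]]
    }
  }
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  defaults
}

#' Run the full simulated cross-decoding experiment
#'
#' For each simulated subject: generate the dataset, temporally preprocess
#' every task run and the resting run, extract trial patterns, evaluate the
#' decoder by leave-one-session-out cross-validation, train the final
#' decoder on all sessions, and cross-decode the resting run against an
#' IAAFT shuffled-weight null.
#'
#' @param config nested list as from [experiment_config()], a path to a
#'   YAML/JSON file with the same structure, or `NULL` for defaults.
#'   Unknown keys raise an error naming the offenders.
#' @param out_dir optional directory; when given, writes `report.json`,
#'   `summary.tsv`, a config snapshot, and (optionally) weight maps.
#' @return An `experiment_report`: list with `subjects` (data frame of
#'   per-subject records), `config`, and `models` (final decoders).
#' @export
run_experiment <- function(config = NULL, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  cfg <- merge_config(config)
  sim <- cfg$simulation
  pp <- cfg$preprocessing
  n_sub <- sim$n_subjects
  rows <- vector("list", n_sub)
  models <- vector("list", n_sub)

  for (i in seq_len(n_sub)) {
    res <- run_subject(cfg, i)
    rows[[i]] <- res$record
    models[[i]] <- res$model
  }
  subjects <- do.call(rbind, rows)

  report <- structure(list(subjects = subjects, config = cfg,
                           models = models,
                           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                      class = "experiment_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# one subject through the whole pipeline
run_subject <- function(cfg, i) {
  sim <- cfg$simulation; pp <- cfg$preprocessing
  scfg <- sim_config(n_voxels = sim$n_voxels, n_sessions = sim$n_sessions,
                     tr_seconds = sim$tr_seconds,
                     block_seconds = sim$block_seconds,
                     trials_per_class_per_session = sim$trials_per_class_per_session,
                     rest_scans = sim$rest_scans,
                     task_amplitude = sim$task_amplitude,
                     rc_amplitude = sim$rc_amplitude,
                     noise_sd = sim$noise_sd,
                     pattern_overlap = sim$pattern_overlap,
                     nuisance_gain = sim$nuisance_gain,
                     seed = subject_seed(sim$seed, i))
  ds <- generate_subject(scfg)
  trials <- lapply(seq_along(ds$task_runs), function(s) {
    clean <- preprocess_task_run(ds$task_runs[[s]], ds$task_nuisance[[s]])
    extract_trials(clean, drop_initial = pp$drop_initial)
  })
  all_trials <- combine_trials(trials)
  cv <- loo_cv_accuracy(all_trials, lambda = cfg$decoder$lambda)
  model <- train_decoder(all_trials, lambda = cfg$decoder$lambda)
  rest <- preprocess_rest_run(ds$rest_run, ds$rest_nuisance,
                              low_hz = pp$low_hz, high_hz = pp$high_hz,
                              order = pp$filter_order)
  cd <- cross_decode(model, rest,
                     n_iterations = cfg$null$n_iterations,
                     alpha = cfg$significance$alpha,
                     normalize_scans = cfg$null$normalize_scans,
                     seed = null_seed(sim$seed, i))
  record <- data.frame(subject = i,
                       seed = scfg$seed,
                       accuracy = cv$accuracy,
                       n_trials = cv$n_trials,
                       sd_rs_raw = cd$sd_rs_raw,
                       sd_rs_corrected = cd$sd_rs_corrected,
                       critical_value = cd$critical_value,
                       empirical_p = cd$empirical_p,
                       significant = cd$significant)
  list(record = record, model = model, crossdecode = cd, dataset = ds)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d subjects; mean accuracy %.1f%%; %d/%d significant\n",
              nrow(x$subjects), 100 * mean(x$subjects$accuracy),
              sum(x$subjects$significant), nrow(x$subjects)))
  invisible(x)
}

#' Write an experiment report to disk
#'
#' Writes `report.json` (per-subject records plus the config snapshot),
#' `summary.tsv` (the per-subject table), and optionally per-subject
#' weight-map TSVs.
#'
#' @param report an `experiment_report`.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$subjects, file.path(out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(subjects = report$subjects,
                            config = report$config,
                            timestamp = report$timestamp),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (isTRUE(report$config$output$write_weight_maps)) {
    for (i in seq_along(report$models)) {
      utils::write.table(data.frame(voxel = seq_along(report$models[[i]]$w),
                                    w = report$models[[i]]$w),
                         file.path(out_dir, sprintf("weights_subject%03d.tsv", i)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(out_dir)
}

#' Validate a report JSON against the packaged schema
#'
#' Light structural validation: checks that every field required by the
#' schema (`inst/extdata/report-schema.json`) is present with the declared
#' type in each subject record.
#'
#' @param path path to a `report.json` written by [write_report()].
#' @return `TRUE` invisibly; errors describe any violation.
#' @export
validate_report <- function(path) {
  schema <- jsonlite::read_json(system.file("extdata", "report-schema.json",
                                            package = "restmvpa"),
                                simplifyVector = FALSE)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in names(schema$subject_record)) {
    if (!field %in% names(rep$subjects))
      stop("report is missing subject field '", field, "'")
    want <- schema$subject_record[[field]]
    got <- class(rep$subjects[[field]])[1]
    ok <- switch(want,
                 number = got %in% c("numeric", "integer"),
                 integer = got %in% c("integer", "numeric"),
                 boolean = got == "logical",
                 TRUE)
    if (!ok)
      stop("subject field '", field, "' has type ", got, ", expected ", want)
  }
  if (!"config" %in% names(rep)) stop("report is missing the config snapshot")
  invisible(TRUE)
}

#' Serialize a synthetic subject dataset to a directory
#'
#' Writes each run's data matrix and schedule as TSV plus a JSON snapshot
#' of the configuration and ground truth.
#'
#' @param ds a `subject_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_subject_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "subject_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_along(ds$task_runs)) {
    utils::write.table(ds$task_runs[[s]]$data,
                       file.path(dir, sprintf("task_run%02d.tsv", s)),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    write_schedule_tsv(ds$task_runs[[s]],
                       file.path(dir, sprintf("task_run%02d_schedule.tsv", s)))
  }
  utils::write.table(ds$rest_run$data, file.path(dir, "rest_run.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(config = unclass(ds$config),
                            truth = list(
                              wrist_pattern = ds$truth$wrist_pattern,
                              finger_pattern = ds$truth$finger_pattern,
                              realized_overlap = ds$truth$realized_overlap)),
                       file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a real 4-D BOLD run through an ROI mask
#'
#' Adapter for measured data: reads a 4-D NIfTI volume and a 3-D binary
#' mask on the same grid and returns the scans x in-mask-voxels matrix.
#' Voxel order is the flattened (column-major) mask index order, recorded
#' on the result.  Requires the `RNifti` package.
#'
#' @param bold_path path to a 4-D NIfTI BOLD image.
#' @param mask_path path to a 3-D binary NIfTI ROI mask on the same grid.
#' @param schedule_path optional TSV with per-scan `scan_index`, `onset_s`,
#'   `label` columns.
#' @param tr repetition time; taken from the NIfTI header when `NULL`.
#' @return A [bold_run()] with attribute `voxel_index` (flat mask indices).
#' @export
load_real_run <- function(bold_path, mask_path, schedule_path = NULL, tr = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("load_real_run requires the RNifti package")
  bold <- RNifti::readNifti(bold_path)
  mask <- RNifti::readNifti(mask_path)
  db <- dim(bold); dm <- dim(mask)
  if (length(db) != 4L) stop("BOLD image must be 4-D, got ", length(db), "-D")
  if (length(dm) != 3L || !all(db[1:3] == dm))
    stop("mask grid ", paste(dm, collapse = "x"),
         " does not match BOLD grid ", paste(db[1:3], collapse = "x"))
  idx <- which(as.array(mask) != 0)
  if (length(idx) == 0L) stop("ROI mask is empty")
  n_t <- db[4]
  flat <- matrix(as.numeric(bold), prod(db[1:3]), n_t)
  data <- t(flat[idx, , drop = FALSE])
  if (is.null(tr)) {
    pd <- attr(bold, "pixdim")
    tr <- if (!is.null(pd) && length(pd) >= 4 && pd[4] > 0) pd[4] else 1
  }
  sched <- if (!is.null(schedule_path))
    utils::read.table(schedule_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  else NULL
  run <- bold_run(data, tr = tr, schedule = sched)
  attr(run, "voxel_index") <- idx
  run
}
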