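# End-to-end orchestration: a single human-readable YAML run configuration
# drives simulate (phantom study to disk), measure (segmentation +
# morphometry to a study table) and compare (time-course report). Every
# output directory receives a resolved-config snapshot for provenance;
# log messages go to stderr, machine output only to files.

log_msg <- function(config, level, ...) {
  levels <- c(debug = 1L, info = 2L, warn = 3L)
  want <- levels[[config$log_level %||% "info"]]
  if (levels[[level]] >= want) {
    message("[", level, "] ", ...)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default run configuration
#'
#' Nested list mirroring [phantom_params()], [study_design()] and the
#' segmentation defaults; serializable to/from YAML with
#' [write_run_config()] / [read_run_config()].
#'
#' @param seed master seed.
#' @param out_dir output directory for [simulate_study()].
#' @return run-config list.
#' @export
default_run_config <- function(seed = 1L, out_dir = "study") {
  p <- phantom_params(seed = seed)
  d <- study_design()
  list(seed = as.integer(seed),
       phantom = p[setdiff(names(p), "seed")],
       design = unclass(d),
       segmentation = list(bone_threshold = 160, cortical_threshold = 500,
                           max_shell_depth = NULL),
       vertebrae = c("L2", "L3", "L4"),
       out_dir = out_dir,
       log_level = "info")
}

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop("unknown ", where, " key(s): ", paste(unknown, collapse = ", "))
  }
}

validate_run_config <- function(config) {
  ref <- default_run_config()
  check_keys(config, names(ref), "config")
  check_keys(config$phantom, names(ref$phantom), "phantom")
  check_keys(config$design, names(ref$design), "design")
  check_keys(config$segmentation, names(ref$segmentation), "segmentation")
  invisible(config)
}

config_params <- function(config) {
  do.call(phantom_params, c(config$phantom, list(seed = config$seed)))
}

config_design <- function(config) {
  do.call(study_design, config$design)
}

config_segmentation <- function(config) {
  seg <- config$segmentation
  list(bone_threshold = seg$bone_threshold %||% 160,
       cortical_threshold = seg$cortical_threshold %||% 500,
       max_shell_depth = seg$max_shell_depth %||% Inf)
}

#' Write / read a run configuration (YAML)
#'
#' Unknown keys at any level are rejected at read time, so a typo in a
#' config file cannot silently fall back to a default.
#'
#' @param config run-config list.
#' @param path YAML file path.
#' @return `read_run_config` returns the validated config;
#'   `write_run_config` returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  validate_run_config(config)
  # yaml drops the names of atomic vectors; store named factors as maps
  config$phantom$vertebra_factors <-
    as.list(config$phantom$vertebra_factors)
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  config <- yaml::read_yaml(path)
  validate_run_config(config)
  # YAML collapses named vectors to lists; restore the few we rely on
  config$phantom$outer_semiaxes <- as.numeric(config$phantom$outer_semiaxes)
  config$phantom$vertebra_factors <-
    unlist(config$phantom$vertebra_factors)
  config$vertebrae <- as.character(unlist(config$vertebrae))
  config
}

#' Simulate a phantom study to disk
#'
#' Renders every subject at every imaging day and writes, under `out_dir`:
#' one stack directory per subject x day (16-bit TIFFs + JSON sidecar), a
#' `manifest.json`, the analytic `ground_truth.csv` and a resolved
#' `config.yaml` snapshot.
#'
#' @param config run-config list (see [default_run_config()]).
#' @param out_dir output directory (defaults to `config$out_dir`).
#' @return `out_dir`, invisibly.
#' @export
simulate_study <- function(config, out_dir = NULL) {
  validate_run_config(config)
  out_dir <- out_dir %||% config$out_dir
  params <- config_params(config)
  design <- config_design(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2L) != 0L) {
    stop("output directory is not writable: ", out_dir)
  }
  log_msg(config, "info", "simulating study into ", out_dir)
  study <- generate_study(params, design, render = TRUE)
  for (sid in names(study$stacks)) {
    for (dy in names(study$stacks[[sid]])) {
      write_stack(study$stacks[[sid]][[dy]],
                  file.path(out_dir, sid, sprintf("day_%02d",
                                                  as.integer(dy))),
                  slope = params$calibration$slope,
                  intercept = params$calibration$intercept)
    }
  }
  manifest <- list(subjects = lapply(seq_len(nrow(study$subjects)),
    function(i) list(subject_id = study$subjects$subject_id[i],
                     group = study$subjects$group[i],
                     days = design$imaging_days)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  gt <- study$ground_truth
  write_results_table(gt, file.path(out_dir, "ground_truth.csv"))
  config$out_dir <- out_dir
  write_run_config(config, file.path(out_dir, "config.yaml"))
  log_msg(config, "info", "wrote ", nrow(gt), " ground-truth rows for ",
          length(study$stacks), " subjects")
  invisible(out_dir)
}

#' Measure every stack of a study
#'
#' Accepts either a study directory written by [simulate_study()] or the
#' in-memory study list from [generate_study()]. Subjects whose stacks fail
#' to read or measure are skipped with a log message and summarized at the
#' end.
#'
#' @param study study directory path or [generate_study()] result.
#' @param config run-config list (segmentation thresholds, vertebra set).
#' @return study table: one row per subject x imaging day.
#' @export
measure_study <- function(study, config = default_run_config()) {
  validate_run_config(config)
  seg <- config_segmentation(config)
  measure_one <- function(stack) {
    measure_stack(stack, bone_threshold = seg$bone_threshold,
                  cortical_threshold = seg$cortical_threshold,
                  max_shell_depth = seg$max_shell_depth,
                  vertebrae = config$vertebrae)
  }
  rows <- list()
  failed <- character(0)
  if (is.character(study)) {
    manifest <- jsonlite::read_json(file.path(study, "manifest.json"),
                                    simplifyVector = FALSE)
    for (s in manifest$subjects) {
      res <- tryCatch({
        sub_rows <- lapply(s$days, function(dy) {
          stack <- read_stack(file.path(study, s$subject_id,
                                        sprintf("day_%02d", as.integer(dy))))
          cbind(data.frame(subject_id = s$subject_id, group = s$group,
                           day = as.integer(dy), stringsAsFactors = FALSE),
                measure_one(stack))
        })
        do.call(rbind, sub_rows)
      }, error = function(e) {
        log_msg(config, "warn", "subject ", s$subject_id, " skipped: ",
                conditionMessage(e))
        NULL
      })
      if (is.null(res)) failed <- c(failed, s$subject_id)
      else rows[[length(rows) + 1L]] <- res
    }
  } else {
    for (sid in names(study$stacks)) {
      grp <- study$subjects$group[study$subjects$subject_id == sid]
      res <- tryCatch({
        do.call(rbind, lapply(names(study$stacks[[sid]]), function(dy) {
          cbind(data.frame(subject_id = sid, group = grp,
                           day = as.integer(dy), stringsAsFactors = FALSE),
                measure_one(study$stacks[[sid]][[dy]]))
        }))
      }, error = function(e) {
        log_msg(config, "warn", "subject ", sid, " skipped: ",
                conditionMessage(e))
        NULL
      })
      if (is.null(res)) failed <- c(failed, sid)
      else rows[[length(rows) + 1L]] <- res
    }
  }
  if (length(failed)) {
    log_msg(config, "warn", length(failed), " subject(s) skipped: ",
            paste(failed, collapse = ", "))
  }
  if (length(rows) == 0L) stop("no subject could be measured")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare the two arms across the whole time course
#'
#' @param table study table (data frame or CSV path).
#' @return time-course report data frame, see [timecourse_report()].
#' @export
compare_study <- function(table) {
  if (is.character(table)) table <- read_results_table(table)
  timecourse_report(table)
}

#' Run simulate, measure and compare end to end
#'
#' Writes `ground_truth.csv`, `morphometry.csv` and `timecourse.csv` (plus
#' stacks and config snapshot) under the configured output directory.
#'
#' @param config run-config list.
#' @param out_dir output directory (defaults to `config$out_dir`).
#' @return the time-course report, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  out_dir <- out_dir %||% config$out_dir
  simulate_study(config, out_dir)
  table <- measure_study(out_dir, config)
  write_results_table(table, file.path(out_dir, "morphometry.csv"))
  report <- compare_study(table)
  write_timecourse_report(report, file.path(out_dir, "timecourse.csv"))
  log_msg(config, "info", "pipeline complete: ", nrow(report),
          " comparisons")
  invisible(report)
}
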