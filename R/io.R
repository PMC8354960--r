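CHOICE_LOG_SCHEMA <- "# choicerep choice-log v1"
CHOICE_LOG_COLUMNS <- c("participant_id", "session", "block", "trial_index",
                        "triplet_id", "role", "stim", "sham_order",
                        "sn_value", "lf_value", "sn_distance",
                        "extra_distance", "iti_before_ms", "choice", "dt_ms",
                        "timeout")

#' Write a choice log CSV
#'
#' Comma-separated, UTF-8, header row, no index column; the first line is a
#' schema-version comment (`# choicerep choice-log v1`). Writing the same
#' records twice produces byte-identical files.
#'
#' @param records choice-record data frame.
#' @param path output file path.
#' @export
write_choice_log <- function(records, path) {
  missing_cols <- setdiff(CHOICE_LOG_COLUMNS, names(records))
  check_arg(length(missing_cols) == 0,
            paste("records are missing columns:",
                  paste(missing_cols, collapse = ", ")))
  con <- file(path, open = "wb")  # binary: stable line endings
  on.exit(close(con))
  writeLines(CHOICE_LOG_SCHEMA, con)
  write.csv(records[, CHOICE_LOG_COLUMNS], con, row.names = FALSE,
            quote = FALSE, na = "")
  invisible(path)
}

#' Read and validate a choice log CSV
#'
#' Parses a file written by [write_choice_log], validating the schema line,
#' the column set, the enums (`role`, `stim`, `sham_order`, `choice`) and
#' the inter-trial intervals (500 or 1500 ms, or empty for block-initial
#' trials). Errors name the first offending data row.
#'
#' @param path file path.
#' @return choice-record data frame (possibly empty).
#' @export
read_choice_log <- function(path) {
  check_arg(file.exists(path), paste("no such file:", path))
  first <- readLines(path, n = 1)
  if (!identical(first, CHOICE_LOG_SCHEMA)) {
    stop_choicerep("schema_error",
                   sprintf("unrecognised schema line %s (expected %s)",
                           deparse(first), deparse(CHOICE_LOG_SCHEMA)))
  }
  df <- read.csv(path, skip = 1, stringsAsFactors = FALSE,
                 colClasses = "character")
  if (!identical(names(df), CHOICE_LOG_COLUMNS)) {
    stop_choicerep("schema_error", "column header does not match the choice-log schema")
  }
  if (nrow(df) == 0) {
    out <- df
    for (cn in c("participant_id", "session", "block", "trial_index",
                 "sn_value", "lf_value", "sn_distance", "extra_distance")) {
      out[[cn]] <- integer()
    }
    for (cn in c("iti_before_ms", "dt_ms")) out[[cn]] <- numeric()
    out$timeout <- logical()
    return(out)
  }

  bad_row <- function(rows, what) {
    stop_choicerep("parse_error",
                   sprintf("%s in data row(s) %s", what,
                           paste(utils::head(rows, 5), collapse = ", ")))
  }
  num <- function(cn, allow_na = FALSE) {
    x <- suppressWarnings(as.numeric(df[[cn]]))
    blank <- df[[cn]] == ""
    bad <- which(is.na(x) & !blank)
    if (length(bad)) bad_row(bad, paste("malformed", cn))
    if (!allow_na && any(blank)) bad_row(which(blank), paste("missing", cn))
    x
  }
  enum <- function(cn, levels) {
    bad <- which(!df[[cn]] %in% levels)
    if (length(bad)) {
      stop_choicerep("schema_error",
                     sprintf("unknown %s label %s in data row(s) %s", cn,
                             deparse(df[[cn]][bad[1]]),
                             paste(utils::head(bad, 5), collapse = ", ")))
    }
    df[[cn]]
  }

  out <- df
  out$triplet_id[out$triplet_id == ""] <- NA_character_
  for (cn in c("participant_id", "session", "block", "trial_index",
               "sn_value", "lf_value", "sn_distance", "extra_distance")) {
    out[[cn]] <- as.integer(num(cn))
  }
  out$role <- enum("role", c("measurement", "bias_SN", "bias_LF", "target"))
  out$stim <- enum("stim", c("sham", "anodal", "cathodal"))
  out$sham_order <- enum("sham_order", c("sham_first", "sham_second"))
  out$choice <- enum("choice", c("SN", "LF"))
  out$iti_before_ms <- num("iti_before_ms", allow_na = TRUE)
  bad_iti <- which(!(is.na(out$iti_before_ms) |
                       out$iti_before_ms %in% c(500, 1500)))
  if (length(bad_iti)) bad_row(bad_iti, "iti_before_ms not in {500, 1500}")
  out$dt_ms <- num("dt_ms")
  out$timeout <- enum("timeout", c("TRUE", "FALSE")) == "TRUE"
  out
}

# ---- run configuration ----

#' Default end-to-end run configuration
#'
#' A run configuration is a plain named list mirroring the plain-text
#' key/value (YAML) file accepted by [read_run_config]: a master seed, the
#' cohort size, the design, agent and population parameters, the analysis
#' options and the output directory.
#'
#' @param master_seed integer master seed; every source of randomness in a
#'   run flows from it.
#' @param n_participants recruited cohort size.
#' @param out_dir directory for run artifacts.
#' @export
default_run_config <- function(master_seed = 1L, n_participants = 52L,
                               out_dir = "results") {
  list(
    master_seed = as.integer(master_seed),
    n_participants = as.integer(n_participants),
    design = design_config(),
    agent = unclass(agent_params()),
    population = population_spec(),
    analysis = list(filter_mode = "preceding", alpha = 0.05),
    out_dir = out_dir
  )
}

validate_run_config <- function(config) {
  ref <- default_run_config()
  unknown <- setdiff(names(config), names(ref))
  if (length(unknown)) {
    stop_choicerep("schema_error",
                   paste("unknown configuration key(s):",
                         paste(unknown, collapse = ", ")))
  }
  for (section in c("design", "agent", "population", "analysis")) {
    if (!is.null(config[[section]])) {
      unknown <- setdiff(names(config[[section]]), names(ref[[section]]))
      if (length(unknown)) {
        stop_choicerep("schema_error",
                       sprintf("unknown key(s) in %s: %s", section,
                               paste(unknown, collapse = ", ")))
      }
    }
  }
  out <- utils::modifyList(ref, config)
  out$agent <- do.call(agent_params, out$agent)
  out
}

#' Write a run configuration file
#' @param config run-configuration list.
#' @param path output path (YAML).
#' @export
write_run_config <- function(config, path) {
  cfg <- validate_run_config(config)
  cfg$agent <- unclass(cfg$agent)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read and validate a run configuration file
#'
#' Unknown keys are rejected; missing keys take their defaults. The
#' write/read round trip reproduces an identical configuration.
#'
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  check_arg(file.exists(path), paste("no such file:", path))
  cfg <- validate_run_config(yaml::read_yaml(path))
  cfg$agent <- unclass(cfg$agent)
  cfg
}

#' Run the full pipeline end to end
#'
#' Simulates a cohort under the configuration, writes the trial schedule and
#' choice-log CSVs, re-reads the log (so the analysis consumes exactly what
#' is on disk), runs the preregistered report, and writes the report as JSON
#' with stable key ordering plus a run log (package version, configuration
#' hash, per-stage seeds). Deterministic given `master_seed`. A failure in
#' any stage aborts with the stage name; artifacts of earlier stages are
#' kept.
#'
#' @param config run-configuration list (see [default_run_config]).
#' @return (invisibly) list with the `report`, the `cohort` and the artifact
#'   `paths`.
#' @export
run_end_to_end <- function(config = default_run_config()) {
  cfg <- validate_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    config = file.path(cfg$out_dir, "run_config.yaml"),
    schedule = file.path(cfg$out_dir, "trial_schedule.csv"),
    choice_log = file.path(cfg$out_dir, "choice_log.csv"),
    report = file.path(cfg$out_dir, "report.json"),
    log = file.path(cfg$out_dir, "run_log.txt")
  )
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      stop_choicerep("stage_error",
                     sprintf("[stage %s] %s", label, conditionMessage(e)))
    })
  }

  cfg_plain <- cfg
  cfg_plain$agent <- unclass(cfg_plain$agent)
  yaml::write_yaml(cfg_plain, paths$config)
  cfg_hash <- unname(tools::md5sum(paths$config))

  cohort <- stage("simulate", {
    simulate_cohort(cfg$n_participants, design = cfg$design,
                    params = cfg$agent, population = cfg$population,
                    rng_seed = cfg$master_seed)
  })
  stage("write", {
    sched_cols <- setdiff(CHOICE_LOG_COLUMNS, c("choice", "dt_ms", "timeout"))
    write.csv(cohort$records[, sched_cols], paths$schedule, row.names = FALSE,
              quote = FALSE, na = "")
    write_choice_log(cohort$records, paths$choice_log)
  })
  report <- stage("analyze", {
    records <- read_choice_log(paths$choice_log)
    preregistered_report(records, filter_mode = cfg$analysis$filter_mode,
                         alpha = cfg$analysis$alpha)
  })
  stage("report", {
    jsonlite::write_json(as_report_list(report), paths$report,
                         auto_unbox = TRUE, digits = NA, na = "null")
    writeLines(c(
      sprintf("choicerep %s", as.character(packageVersion("choicerep"))),
      sprintf("config_md5 %s", cfg_hash),
      sprintf("master_seed %d", cfg$master_seed),
      sprintf("participant_seeds %s",
              paste(cohort$participants$seed, collapse = " ")),
      sprintf("eligible %d of %d", sum(cohort$participants$eligible),
              nrow(cohort$participants))
    ), paths$log)
  })
  invisible(list(report = report, cohort = cohort, paths = paths))
}
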