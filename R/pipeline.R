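# End-to-end orchestration: configuration, validation and the full
# simulate-or-read -> counts -> METs -> reliability chain with CSV outputs.

#' Read or write a participants table
#'
#' CSV with columns `participant_id`, `age`, `body_mass_kg`, `height_m`,
#' `gender_code` (1 = female, 2 = male).
#'
#' @param path File path.
#' @return `read_participants()` returns a tibble.
#' @export
read_participants <- function(path) {
  p <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("participant_id", "age", "body_mass_kg", "height_m", "gender_code")
  missing_cols <- setdiff(need, names(p))
  if (length(missing_cols)) {
    abort(sprintf("participants file is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "actimets_format_error")
  }
  p
}

#' @rdname read_participants
#' @param participants Participants tibble.
#' @export
write_participants <- function(participants, path) {
  readr::write_csv(participants, path, progress = FALSE)
  invisible(path)
}

.config_keys <- c("mode", "seed", "design", "input", "vertical_axis",
                  "bout_minutes", "equations", "icc_form", "exclusions",
                  "out_dir")

#' Build a pipeline configuration
#'
#' @param mode `"simulate"` (generate the study from `design`) or `"csv"`
#'   (read manifest, participants and per-record signal CSVs from `input`).
#' @param seed Seed used in simulate mode.
#' @param design Named list of [sim_design()] arguments (simulate mode).
#' @param input Named list for csv mode: `manifest`, `participants`,
#'   `signals_dir` and optionally `dialect` (arguments to [csv_dialect()]).
#' @param vertical_axis Named list/vector mapping each placement to the axis
#'   treated as vertical, e.g. `list(wrist = "y", thigh = "y")`.  Required:
#'   which physical axis is vertical depends on how the device is worn and
#'   cannot be inferred from data.
#' @param bout_minutes Bout length used for epoch averaging.
#' @param equations `"all"` or a subset of the equation ids.
#' @param icc_form `"single"` or `"average"`.
#' @param exclusions Record ids removed before analysis.
#' @param out_dir Output directory.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(mode = c("simulate", "csv"), seed = 20220326,
                            design = list(), input = list(),
                            vertical_axis = list(wrist = "y", thigh = "y"),
                            bout_minutes = 2, equations = "all",
                            icc_form = c("single", "average"),
                            exclusions = default_exclusions(),
                            out_dir = tempfile("actimets_out_")) {
  mode <- match.arg(mode)
  icc_form <- match.arg(icc_form)
  cfg <- structure(
    list(mode = mode, seed = seed, design = design, input = input,
         vertical_axis = as.list(vertical_axis), bout_minutes = bout_minutes,
         equations = equations, icc_form = icc_form,
         exclusions = as.character(exclusions), out_dir = out_dir),
    class = "pipeline_config"
  )
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' Accepts a `pipeline_config`, a plain list, or a path to a YAML file.
#' All violations are collected and reported together, not just the first.
#'
#' @param config Configuration object, list or YAML path.
#' @param strict If `TRUE` (default) unknown keys are an error; otherwise a
#'   warning.
#' @return The validated `pipeline_config`.
#' @export
validate_config <- function(config, strict = TRUE) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      abort(sprintf("config file not found: %s", config),
            class = "actimets_format_error")
    }
    config <- yaml::read_yaml(config)
  }
  config <- unclass(config)
  problems <- character()
  unknown <- setdiff(names(config), .config_keys)
  if (length(unknown)) {
    msg <- sprintf("unknown key(s): %s", paste(unknown, collapse = ", "))
    if (strict) problems <- c(problems, msg) else warn(msg)
    config <- config[intersect(names(config), .config_keys)]
  }
  defaults <- list(mode = "simulate", seed = 20220326, design = list(),
                   input = list(),
                   vertical_axis = NULL, bout_minutes = 2, equations = "all",
                   icc_form = "single", exclusions = default_exclusions(),
                   out_dir = tempfile("actimets_out_"))
  config <- modifyList(defaults, config)
  # YAML reads empty/scalar sequences as lists; normalize the vector fields
  config$exclusions <- as.character(unlist(config$exclusions))
  if (!identical(config$equations, "all")) {
    config$equations <- as.character(unlist(config$equations))
  }
  if (!config$mode %in% c("simulate", "csv")) {
    problems <- c(problems, sprintf("mode must be 'simulate' or 'csv', got '%s'",
                                    config$mode))
  }
  # YAML 1.1 reads a bare `y` as boolean TRUE; map it back to the axis name
  config$vertical_axis <- lapply(config$vertical_axis,
                                 function(v) if (isTRUE(v)) "y" else v)
  if (is.null(config$vertical_axis) ||
      !all(c("wrist", "thigh") %in% names(config$vertical_axis))) {
    problems <- c(problems,
                  "vertical_axis must map both 'wrist' and 'thigh' to an axis")
  } else if (!all(unlist(config$vertical_axis) %in% c("x", "y", "z"))) {
    problems <- c(problems, "vertical_axis values must be 'x', 'y' or 'z'")
  }
  if (!config$icc_form %in% c("single", "average")) {
    problems <- c(problems, sprintf("icc_form must be 'single' or 'average', got '%s'",
                                    config$icc_form))
  }
  if (!is.numeric(config$bout_minutes) || config$bout_minutes <= 0) {
    problems <- c(problems, "bout_minutes must be a positive number")
  }
  if (!identical(config$equations, "all")) {
    bad <- setdiff(config$equations, .equation_ids)
    if (length(bad)) {
      problems <- c(problems, sprintf("unknown equation id(s): %s",
                                      paste(bad, collapse = ", ")))
    }
  }
  if (config$mode == "csv") {
    for (key in c("manifest", "participants", "signals_dir")) {
      pth <- config$input[[key]]
      if (is.null(pth)) {
        problems <- c(problems, sprintf("input$%s is required in csv mode", key))
      } else if (!file.exists(pth)) {
        problems <- c(problems, sprintf("input$%s does not exist: %s", key, pth))
      }
    }
  }
  if (length(problems)) {
    abort(paste(c("invalid pipeline config:",
                  paste0("  - ", problems)), collapse = "\n"),
          class = "actimets_config_error")
  }
  structure(config, class = "pipeline_config")
}

#' Write a configuration to YAML
#'
#' Configurations round-trip losslessly through their YAML form.
#'
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.config_checksum <- function(config) {
  txt <- yaml::as.yaml(unclass(config))
  codes <- utf8ToInt(txt)
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% 2147483647
  sprintf("%08x", h)
}

.log_line <- function(con, msg, echo = TRUE) {
  if (echo) message(msg)
  writeLines(msg, con)
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) the study, applies the exclusion list, converts every
#' record to activity counts and epoch summaries, evaluates the ten MET
#' estimates, and writes the three reliability tables (wrist devices, thigh
#' devices, wrist-vs-thigh placement) plus a skipped-records report and a run
#' log to `config$out_dir`.
#'
#' @param config A [pipeline_config()] (or anything [validate_config()]
#'   accepts).
#' @param quiet Suppress progress messages (log file is always written).
#' @return Invisibly, a list with the output `paths` and the in-memory
#'   `manifest`, `epochs`, `ee` and `tables`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config <- validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con))
  t0 <- Sys.time()
  stage <- function(msg) .log_line(log_con, msg, echo = !quiet)
  stage(sprintf("actimets %s | config checksum %s",
                as.character(utils::packageVersion("actimets")),
                .config_checksum(config)))

  if (config$mode == "simulate") {
    design <- do.call(sim_design, modifyList(list(seed = config$seed),
                                             config$design))
    stage("stage: simulate study")
    study <- simulate_study(design)
    manifest <- study$manifest
    participants <- study$participants
    get_signal <- function(id) study$signals[[id]]
  } else {
    stage("stage: read inputs")
    manifest <- read_manifest(config$input$manifest)
    participants <- read_participants(config$input$participants)
    dialect <- do.call(csv_dialect, as.list(config$input$dialect %||% list()))
    get_signal <- function(id) {
      row <- manifest[manifest$record_id == id, ]
      read_raw_csv(file.path(config$input$signals_dir, paste0(id, ".csv")),
                   dialect = dialect, record_id = id,
                   device = row$device)
    }
  }

  stage(sprintf("stage: exclusions (%d listed)", length(config$exclusions)))
  manifest <- apply_exclusions(manifest, config$exclusions)
  stage(sprintf("  %d records, %g min retained",
                nrow(manifest), total_minutes(manifest)))

  stage("stage: activity counts and epoch summaries")
  epochs <- purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    vt <- config$vertical_axis[[row$placement]]
    epoch_summary(get_signal(row$record_id), vertical_axis = vt,
                  bout_minutes = min(config$bout_minutes, row$duration_min))
  })

  stage("stage: energy expenditure")
  ee <- estimate_energy(epochs, manifest, participants)
  if (!identical(config$equations, "all")) {
    ee <- ee[ee$equation %in% config$equations, , drop = FALSE]
  }

  stage("stage: reliability tables")
  tables <- list(
    wrist_devices = agreement_table(ee, manifest, "device_at_placement",
                                    "wrist", icc_form = config$icc_form),
    thigh_devices = agreement_table(ee, manifest, "device_at_placement",
                                    "thigh", icc_form = config$icc_form),
    placement = agreement_table(ee, manifest, "placement_within_device",
                                "actigraph", icc_form = config$icc_form)
  )

  paths <- list(
    manifest = file.path(config$out_dir, "manifest_clean.csv"),
    epochs = file.path(config$out_dir, "epoch_summary.csv"),
    ee = file.path(config$out_dir, "ee_results.csv"),
    wrist_devices = file.path(config$out_dir, "agreement_wrist_devices.csv"),
    thigh_devices = file.path(config$out_dir, "agreement_thigh_devices.csv"),
    placement = file.path(config$out_dir, "agreement_placement.csv"),
    skipped = file.path(config$out_dir, "skipped_records.csv"),
    log = log_path
  )
  write_manifest(manifest, paths$manifest)
  write_counts_csv(epochs, paths$epochs)
  write_ee_csv(ee, paths$ee)
  for (nm in names(tables)) write_agreement_csv(tables[[nm]], paths[[nm]])
  skipped <- dplyr::bind_rows(
    lapply(names(tables), function(nm) {
      sk <- attr(tables[[nm]], "skipped")
      if (nrow(sk)) dplyr::mutate(sk, table = nm) else NULL
    })
  )
  if (is.null(skipped) || !nrow(skipped)) {
    skipped <- tibble::tibble(speed_kmh = double(), equation_full = character(),
                              unit = character(), table = character())
  }
  readr::write_csv(skipped, paths$skipped, progress = FALSE)
  stage(sprintf("done in %.1f s; outputs in %s",
                as.numeric(difftime(Sys.time(), t0, units = "secs")),
                config$out_dir))
  invisible(list(paths = paths, manifest = manifest, epochs = epochs,
                 ee = ee, tables = tables))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
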