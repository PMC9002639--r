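#' Treadmill speeds of the recording protocol
#'
#' The ten walking/running speeds, in km/h, at which bouts are recorded.
#'
#' @return Numeric vector of length 10.
#' @export
#' @examples
#' study_speeds()
study_speeds <- function() {
  c(1.4, 2.9, 4.3, 5, 6, 6.5, 7, 8, 9, 10)
}

# Device dynamic ranges (g): ActiGraph GT9X Link +/-8 g, SensorID (Lis2DH12)
# configured at +/-16 g.
.device_range <- c(actigraph = 8, sensorid = 16)

#' Describe the layout of a raw accelerometer CSV
#'
#' A dialect names the time and axis columns, the field delimiter and how the
#' time column is encoded.  The default matches a comma-separated export with
#' a header line `time,x,y,z`, time in elapsed seconds and acceleration in g.
#'
#' @param time_col,x_col,y_col,z_col Column names in the file.
#' @param delim Field delimiter.
#' @param time_format `"elapsed"` for seconds from record start, `"iso8601"`
#'   for absolute timestamps (converted to elapsed seconds on read; the start
#'   time is kept as metadata).
#' @return An object of class `csv_dialect`.
#' @export
csv_dialect <- function(time_col = "time", x_col = "x", y_col = "y",
                        z_col = "z", delim = ",",
                        time_format = c("elapsed", "iso8601")) {
  time_format <- match.arg(time_format)
  structure(
    list(time_col = time_col, x_col = x_col, y_col = y_col, z_col = z_col,
         delim = delim, time_format = time_format),
    class = "csv_dialect"
  )
}

#' Construct a raw tri-axial acceleration signal
#'
#' A `raw_accel` is a tibble with columns `time` (elapsed seconds, strictly
#' increasing) and `x`, `y`, `z` (acceleration in g), carrying the record id,
#' nominal sample rate, device and dynamic range as attributes.
#'
#' @param time Elapsed seconds from record start, strictly increasing.
#' @param x,y,z Acceleration in g, same length as `time`.
#' @param record_id Opaque record identifier, e.g. `"t1110"`.
#' @param sample_rate_hz Nominal sampling rate in Hz.
#' @param device `"actigraph"` or `"sensorid"`.
#' @param dynamic_range_g Sensor range in g; defaults to the device's range
#'   (8 g ActiGraph, 16 g SensorID).
#' @param start_time Optional absolute start time kept as metadata.
#' @return A `raw_accel` tibble.
#' @export
#' @examples
#' sig <- raw_accel(time = (0:89) / 30, x = 0, y = 1, z = 0,
#'                  record_id = "demo", sample_rate_hz = 30)
#' signal_duration(sig)
raw_accel <- function(time, x, y, z, record_id, sample_rate_hz,
                      device = c("actigraph", "sensorid"),
                      dynamic_range_g = NULL, start_time = NULL) {
  device <- match.arg(device)
  if (is.null(dynamic_range_g)) dynamic_range_g <- unname(.device_range[device])
  n <- length(time)
  x <- rep_len(as.double(x), n)
  y <- rep_len(as.double(y), n)
  z <- rep_len(as.double(z), n)
  out <- tibble::tibble(time = as.double(time), x = x, y = y, z = z)
  out <- structure(out, class = c("raw_accel", class(out)),
                   record_id = as.character(record_id),
                   sample_rate_hz = as.double(sample_rate_hz),
                   device = device,
                   dynamic_range_g = as.double(dynamic_range_g),
                   start_time = start_time)
  validate_raw_accel(out)
}

#' @rdname raw_accel
#' @param signal A `raw_accel` object to validate.
#' @export
validate_raw_accel <- function(signal) {
  need <- c("time", "x", "y", "z")
  missing_cols <- setdiff(need, names(signal))
  if (length(missing_cols)) {
    abort(sprintf("raw signal is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "actimets_format_error")
  }
  fs <- attr(signal, "sample_rate_hz")
  if (is.null(fs) || !is.finite(fs) || fs <= 0) {
    abort("sample_rate_hz must be a positive number",
          class = "actimets_data_error")
  }
  vals <- c(signal$x, signal$y, signal$z, signal$time)
  if (!all(is.finite(vals))) {
    abort("acceleration and time values must all be finite",
          class = "actimets_data_error")
  }
  bad <- which(diff(signal$time) <= 0)
  if (length(bad)) {
    abort(sprintf("timestamps must be strictly increasing; first violation at row %d",
                  bad[1] + 1L),
          class = "actimets_data_error")
  }
  signal
}

#' @rdname raw_accel
#' @export
signal_duration <- function(signal) {
  fs <- attr(signal, "sample_rate_hz")
  nrow(signal) / fs
}

#' Read a raw accelerometer CSV
#'
#' Reads a delimited file holding one record's time and x/y/z acceleration
#' columns (in g) and returns a validated [raw_accel()].  Rows with values
#' that cannot be parsed are an error, never silently dropped.
#'
#' @param path Path to the file.
#' @param dialect A [csv_dialect()] describing the layout.
#' @param record_id Record identifier; defaults to the file name without
#'   extension.
#' @param sample_rate_hz Nominal rate; if `NULL`, inferred from the median
#'   timestamp spacing.
#' @inheritParams raw_accel
#' @return A `raw_accel` tibble.
#' @export
read_raw_csv <- function(path, dialect = csv_dialect(), record_id = NULL,
                         sample_rate_hz = NULL,
                         device = c("actigraph", "sensorid"),
                         dynamic_range_g = NULL) {
  device <- match.arg(device)
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "actimets_format_error")
  }
  if (is.null(record_id)) {
    record_id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- readr::read_delim(path, delim = dialect$delim, col_types = readr::cols(),
                           show_col_types = FALSE, progress = FALSE)
  need <- c(dialect$time_col, dialect$x_col, dialect$y_col, dialect$z_col)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
          class = "actimets_format_error")
  }
  start_time <- NULL
  if (dialect$time_format == "iso8601") {
    tt <- as.POSIXct(raw[[dialect$time_col]], tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
    if (anyNA(tt)) {
      abort(sprintf("unparseable timestamp at row %d", which(is.na(tt))[1]),
            class = "actimets_data_error")
    }
    start_time <- tt[1]
    time <- as.double(difftime(tt, tt[1], units = "secs"))
  } else {
    time <- suppressWarnings(as.double(raw[[dialect$time_col]]))
  }
  axes <- lapply(c(dialect$x_col, dialect$y_col, dialect$z_col), function(col) {
    v <- suppressWarnings(as.double(raw[[col]]))
    if (anyNA(v)) {
      abort(sprintf("unparseable value in column '%s' at row %d",
                    col, which(is.na(v))[1]),
            class = "actimets_data_error")
    }
    v
  })
  if (anyNA(time)) {
    abort(sprintf("unparseable value in column '%s' at row %d",
                  dialect$time_col, which(is.na(time))[1]),
          class = "actimets_data_error")
  }
  if (is.null(sample_rate_hz)) {
    dt <- stats::median(diff(time))
    if (!is.finite(dt) || dt <= 0) {
      abort("cannot infer sample rate from timestamps",
            class = "actimets_data_error")
    }
    sample_rate_hz <- 1 / dt
  }
  raw_accel(time = time, x = axes[[1]], y = axes[[2]], z = axes[[3]],
            record_id = record_id, sample_rate_hz = sample_rate_hz,
            device = device, dynamic_range_g = dynamic_range_g,
            start_time = start_time)
}

#' Write a raw signal back to CSV
#'
#' Emits an RFC-4180 comma-separated file with the dialect's column names and
#' elapsed-second timestamps; the inverse of [read_raw_csv()] for the default
#' dialect.
#'
#' @inheritParams read_raw_csv
#' @param signal A `raw_accel`.
#' @return `path`, invisibly.
#' @export
write_raw_csv <- function(signal, path, dialect = csv_dialect()) {
  validate_raw_accel(signal)
  out <- setNames(
    signal[, c("time", "x", "y", "z")],
    c(dialect$time_col, dialect$x_col, dialect$y_col, dialect$z_col)
  )
  readr::write_csv(tibble::as_tibble(out), path, progress = FALSE)
  invisible(path)
}

#' Drop the unstable lead-in of a raw recording
#'
#' Recordings that still contain the warm-up phase can be trimmed to the
#' analysed bout; timestamps are re-zeroed to the new start.
#'
#' @param signal A `raw_accel`.
#' @param seconds Lead time to discard.
#' @return The trimmed `raw_accel`.
#' @export
trim_leading <- function(signal, seconds) {
  validate_raw_accel(signal)
  stopifnot(seconds >= 0)
  keep <- signal$time >= signal$time[1] + seconds
  out <- signal[keep, , drop = FALSE]
  if (!nrow(out)) {
    abort("trim_leading removed the whole signal", class = "actimets_data_error")
  }
  out$time <- out$time - out$time[1]
  attributes(out)[c("record_id", "sample_rate_hz", "device",
                    "dynamic_range_g", "start_time")] <-
    attributes(signal)[c("record_id", "sample_rate_hz", "device",
                         "dynamic_range_g", "start_time")]
  validate_raw_accel(out)
}

# ---- study manifest ---------------------------------------------------------

.manifest_cols <- c("record_id", "participant_id", "device", "placement",
                    "configuration", "speed_kmh", "duration_min")

#' Validate a study manifest
#'
#' A manifest is a tibble with one row per recorded bout and columns
#' `record_id`, `participant_id`, `device`, `placement`, `configuration`,
#' `speed_kmh`, `duration_min`.  Record ids must be unique and speeds must be
#' among [study_speeds()].
#'
#' @param manifest A data frame.
#' @return The manifest as a tibble, invisibly checked.
#' @export
validate_manifest <- function(manifest) {
  missing_cols <- setdiff(.manifest_cols, names(manifest))
  if (length(missing_cols)) {
    abort(sprintf("manifest is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "actimets_format_error")
  }
  if (anyDuplicated(manifest$record_id)) {
    abort("manifest record_id values must be unique",
          class = "actimets_data_error")
  }
  bad_speed <- setdiff(unique(manifest$speed_kmh), study_speeds())
  if (length(bad_speed)) {
    abort(sprintf("speed_kmh outside the protocol speeds: %s",
                  paste(bad_speed, collapse = ", ")),
          class = "actimets_data_error")
  }
  tibble::as_tibble(manifest)
}

#' Read or write a study manifest
#'
#' Manifests round-trip through CSV (RFC-4180) or YAML, chosen by file
#' extension.
#'
#' @param path File path ending in `.csv`, `.yml` or `.yaml`.
#' @return `read_manifest()` returns a validated manifest tibble;
#'   `write_manifest()` returns `path` invisibly.
#' @export
read_manifest <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    rows <- yaml::read_yaml(path)
    manifest <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  } else {
    manifest <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  validate_manifest(manifest)
}

#' @rdname read_manifest
#' @param manifest A manifest tibble.
#' @export
write_manifest <- function(manifest, path) {
  manifest <- validate_manifest(manifest)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(lapply(seq_len(nrow(manifest)),
                            function(i) as.list(manifest[i, ])), path)
  } else {
    readr::write_csv(manifest, path, progress = FALSE)
  }
  invisible(path)
}

#' Remove excluded records from a manifest
#'
#' Bookkeeping for data cleaning: drops the listed record ids, preserving
#' order.  Ids absent from the manifest produce a warning, not an error, so a
#' published exclusion list can be applied verbatim.
#'
#' @param manifest A manifest tibble.
#' @param excluded_ids Character vector of record ids to drop.
#' @return The filtered manifest.
#' @export
#' @examples
#' m <- tibble::tibble(record_id = c("a", "b", "c"), participant_id = "p1",
#'                     device = "actigraph", placement = "wrist",
#'                     configuration = 1, speed_kmh = 5, duration_min = 2)
#' apply_exclusions(m, "b")
apply_exclusions <- function(manifest, excluded_ids) {
  manifest <- validate_manifest(manifest)
  excluded_ids <- unique(as.character(excluded_ids))
  absent <- setdiff(excluded_ids, manifest$record_id)
  if (length(absent)) {
    warn(sprintf("exclusion id(s) not in manifest: %s",
                 paste(absent, collapse = ", ")))
  }
  manifest[!manifest$record_id %in% excluded_ids, , drop = FALSE]
}

#' Total recorded minutes in a manifest
#'
#' @param manifest A manifest tibble.
#' @return Sum of `duration_min` over all records (0 for an empty manifest).
#' @export
total_minutes <- function(manifest) {
  manifest <- validate_manifest(manifest)
  if (anyNA(manifest$duration_min)) {
    abort("duration_min missing for some records", class = "actimets_data_error")
  }
  sum(manifest$duration_min)
}
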