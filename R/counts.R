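# ActiGraph count-replication constants.
#
# Band-pass IIR coefficients and post-filter constants from the open-source
# count replication published by Brond, Andersen & Arvidsson (2017,
# Med Sci Sports Exerc 49:2351-2360), the algorithm distributed as the
# "activityCounts" R package.  Taken verbatim from that implementation.
.brond <- list(
  a = c(1, -4.1637, 7.5712, -7.9805, 5.385, -2.4636, 0.89238, 0.06361,
        -1.3481, 2.4734, -2.9257, 2.9298, -2.7816, 2.4777, -1.6847,
        0.46483, 0.46565, -0.67312, 0.4162, -0.13832, 0.019852),
  b = c(0.049109, -0.12284, 0.14356, -0.11269, 0.053804, -0.02023,
        0.0063778, 0.018513, -0.038154, 0.048727, -0.052577, 0.047847,
        -0.046015, 0.036283, -0.012977, -0.0046262, 0.012835, -0.0093762,
        0.0034485, -0.00080972, -0.00019623),
  gain = 0.965,          # pre-filter input gain applied to b
  target_fs = 30,        # Hz the filter is designed for
  decimate_to = 10,      # Hz after filtering (every 3rd sample)
  peak_g = 2.13,         # clip ceiling, g
  deadband_g = 0.068,    # values below this contribute nothing
  adc_g = 0.0064,        # quantization step, g per count unit
  per_second = 10        # 10 Hz samples summed into one 1-s count
)

#' Constants of the count-replication chain
#'
#' Returns the filter coefficients, dead-band, clip ceiling and quantization
#' step used by [counts_per_second()], for inspection and documentation.
#'
#' @return A named list.
#' @export
count_constants <- function() .brond

# Resample one axis to the filter's design rate by linear interpolation on
# the timestamps; a signal already at exactly 30 Hz passes through untouched.
.resample_30hz <- function(time, v, fs) {
  fs0 <- .brond$target_fs
  if (isTRUE(all.equal(fs, fs0))) {
    return(v)
  }
  dur <- length(v) / fs
  grid <- seq(0, by = 1 / fs0, length.out = floor(dur * fs0))
  t0 <- time - time[1]
  approx(t0, v, xout = pmin(grid, max(t0)), rule = 2)$y
}

# One axis, already at 30 Hz, to quantized 10 Hz count units.  The IIR is
# started at the steady state implied by the first sample, so a constant
# (DC / gravity-only) input produces an identically zero filter output
# rather than a startup transient.
.count_units_10hz <- function(v30) {
  b <- .brond$b * .brond$gain
  a <- .brond$a
  x0 <- v30[1]
  y0 <- x0 * sum(b) / sum(a)
  f <- signal::filter(b, a, v30,
                      init.x = rep(x0, length(b) - 1),
                      init.y = rep(y0, length(a) - 1))
  f <- as.numeric(f)
  f <- f[seq(3, length(f), by = 3)]          # 30 Hz -> 10 Hz
  f <- pmax(pmin(f, .brond$peak_g), -.brond$peak_g)
  f <- abs(f)
  f[f < .brond$deadband_g] <- 0
  floor(f / .brond$adc_g)
}

#' ActiGraph-style activity counts per second for one axis
#'
#' Implements the published count-replication chain: resample to 30 Hz
#' (linear interpolation; exact-30 Hz input passes through), apply the
#' band-pass IIR filter, decimate to 10 Hz, clip at the published ceiling,
#' rectify, zero values below the dead-band, quantize to integer count units
#' and sum each 1-s window.  Partial trailing seconds are discarded.
#'
#' @param signal A [raw_accel()].
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return A tibble with columns `record_id`, `second` (1-based window
#'   index), `axis` and integer `counts`.
#' @export
#' @examples
#' sig <- raw_accel(time = (0:299) / 30, x = 0, y = sin(2 * pi * 2 * (0:299) / 30),
#'                  z = 0, record_id = "demo", sample_rate_hz = 30)
#' counts_per_second(sig, "y")
counts_per_second <- function(signal, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  validate_raw_accel(signal)
  fs <- attr(signal, "sample_rate_hz")
  if (signal_duration(signal) < 1) {
    abort("signal must be at least 1 s long", class = "actimets_data_error")
  }
  v30 <- .resample_30hz(signal$time, signal[[axis]], fs)
  u <- .count_units_10hz(v30)
  per <- .brond$per_second
  n_sec <- length(u) %/% per
  counts <- as.integer(colSums(matrix(u[seq_len(n_sec * per)], nrow = per)))
  tibble::tibble(record_id = attr(signal, "record_id"),
                 second = seq_len(n_sec), axis = axis, counts = counts)
}

#' Per-second counts on all axes plus vector magnitude
#'
#' Convenience wrapper running [counts_per_second()] on x, y and z and
#' attaching the per-second vector magnitude.
#'
#' @param signal A [raw_accel()].
#' @return A wide tibble: `record_id`, `second`, `x`, `y`, `z`, `vm`.
#' @export
activity_counts <- function(signal) {
  per_axis <- lapply(c("x", "y", "z"), function(ax) {
    counts_per_second(signal, ax)$counts
  })
  names(per_axis) <- c("x", "y", "z")
  vm <- vector_magnitude_counts(per_axis$x, per_axis$y, per_axis$z)
  tibble::tibble(record_id = attr(signal, "record_id"),
                 second = seq_along(vm),
                 x = per_axis$x, y = per_axis$y, z = per_axis$z, vm = vm)
}

#' Vector-magnitude counts
#'
#' Per-second Euclidean norm of the three axes' counts:
#' `sqrt(x^2 + y^2 + z^2)`.
#'
#' @param cx,cy,cz Equal-length numeric vectors of per-second counts.
#' @return Numeric vector of the same length (not integer-quantized).
#' @export
#' @examples
#' vector_magnitude_counts(3, 4, 0)
vector_magnitude_counts <- function(cx, cy, cz) {
  if (length(cx) != length(cy) || length(cy) != length(cz)) {
    abort("axis count series must have equal length",
          class = "actimets_data_error")
  }
  sqrt(cx^2 + cy^2 + cz^2)
}

#' Average counts over a recorded bout
#'
#' Converts a per-second count series covering a whole bout into the epoch
#' averages the MET equations consume: `per_min` divides the total by the
#' bout length in minutes (counts/min); `per_10s` divides by six times that
#' (counts/10 s).
#'
#' @param counts Numeric vector of per-second counts, or a tibble with a
#'   `counts` column as returned by [counts_per_second()].
#' @param epoch `"per_min"` or `"per_10s"`.
#' @param bout_minutes Length of the bout the series must cover (default 2).
#' @return A single number, counts per chosen epoch.
#' @export
#' @examples
#' epoch_average(rep(10, 120), "per_min")   # 600
#' epoch_average(rep(10, 120), "per_10s")   # 100
epoch_average <- function(counts, epoch = c("per_min", "per_10s"),
                          bout_minutes = 2) {
  epoch <- match.arg(epoch)
  if (is.data.frame(counts)) counts <- counts$counts
  if (length(counts) < bout_minutes * 60) {
    abort("bout is longer than the available count series",
          class = "actimets_data_error")
  }
  total <- sum(counts)
  switch(epoch,
         per_min = total / bout_minutes,
         per_10s = total / (bout_minutes * 6))
}

#' Per-record epoch summary feeding the MET equations
#'
#' Computes, for one raw signal, the three count aggregates used by the
#' prediction equations: counts/min on the designated vertical axis
#' (`ac_vt_cpm`), counts/min on the vector magnitude (`ac_vm_cpm`) and
#' counts/10 s on the vertical axis (`ac_vt_c10s`).  Which physical axis is
#' "vertical" depends on wear location and must be supplied explicitly.
#'
#' @param signal A [raw_accel()].
#' @param vertical_axis `"x"`, `"y"` or `"z"`: the axis treated as vertical
#'   for this placement.
#' @param bout_minutes Bout length in minutes (default 2).
#' @return A one-row tibble: `record_id`, `ac_vt_cpm`, `ac_vm_cpm`,
#'   `ac_vt_c10s`.
#' @export
epoch_summary <- function(signal, vertical_axis = c("y", "x", "z"),
                          bout_minutes = 2) {
  vertical_axis <- match.arg(vertical_axis)
  ac <- activity_counts(signal)
  vt <- ac[[vertical_axis]]
  tibble::tibble(
    record_id = attr(signal, "record_id"),
    ac_vt_cpm = epoch_average(vt, "per_min", bout_minutes),
    ac_vm_cpm = epoch_average(ac$vm, "per_min", bout_minutes),
    ac_vt_c10s = epoch_average(vt, "per_10s", bout_minutes)
  )
}

#' Write per-second counts or epoch summaries to CSV
#'
#' @param counts A tibble from [activity_counts()] (per-second) or a row-bound
#'   set of [epoch_summary()] results.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(counts, path) {
  readr::write_csv(counts, path, progress = FALSE)
  invisible(path)
}
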