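# Between-device / between-placement reliability: two-way mixed consistency
# ICC from the ANOVA mean squares of a subjects x raters decomposition, and
# Cronbach's standardized-items alpha from mean pairwise correlation.

.as_rater_matrix <- function(values) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    drop <- stats::complete.cases(m)
    warn(sprintf("%d row(s) with missing cells dropped listwise",
                 sum(!drop)))
    m <- m[drop, , drop = FALSE]
  }
  if (!all(is.finite(m))) {
    abort("values must be finite", class = "actimets_data_error")
  }
  if (ncol(m) < 2) {
    abort("at least k = 2 raters required", class = "actimets_data_error")
  }
  if (nrow(m) < 3) {
    abort("at least n = 3 subjects required", class = "actimets_data_error")
  }
  m
}

#' Two-way mixed, consistency-type intraclass correlation
#'
#' Computes the ICC from the mean squares of a subjects x raters two-way
#' ANOVA decomposition.  The single-measure form is
#' `ICC(3,1) = (MS_subjects - MS_error) / (MS_subjects + (k - 1) MS_error)`
#' and the average-measure form is `(MS_subjects - MS_error) / MS_subjects`,
#' where `MS_error` is the residual (subject x rater interaction) mean
#' square.  Consistency ICC ignores systematic rater offsets and may be
#' negative; negative estimates are returned as computed.
#'
#' @param values An `n x k` matrix or data frame, one row per subject-bout
#'   and one column per rater (device or placement).  Rows with missing
#'   cells are dropped listwise with a warning.
#' @param conf_level Optional confidence level (e.g. `0.95`); if supplied,
#'   an F-distribution interval for the single-measure ICC is attached.
#' @return An object of class `icc_mixed`: a list with `icc_single`,
#'   `icc_average`, `alpha_standardized`, the mean squares, `n_subjects`
#'   and `k_raters`.  Has [tidy()] and [glance()] methods.
#' @export
#' @examples
#' m <- cbind(a = c(1, 2, 3, 4, 5), b = c(1.1, 2.2, 2.9, 4.1, 4.8))
#' icc_two_way_mixed(m)
icc_two_way_mixed <- function(values, conf_level = NULL) {
  m <- .as_rater_matrix(values)
  n <- nrow(m)
  k <- ncol(m)
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_total <- sum((m - grand)^2)
  if (ss_total == 0) {
    abort("zero total variance: all values identical",
          class = "actimets_degenerate_error")
  }
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_cols <- ss_cols / (k - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  icc_single <- (ms_rows - ms_err) / (ms_rows + (k - 1) * ms_err)
  icc_average <- (ms_rows - ms_err) / ms_rows
  alpha <- tryCatch(cronbach_alpha_standardized(m), error = function(e) NA_real_)
  out <- list(icc_single = icc_single, icc_average = icc_average,
              alpha_standardized = alpha,
              ms_subjects = ms_rows, ms_raters = ms_cols, ms_error = ms_err,
              n_subjects = n, k_raters = k)
  if (!is.null(conf_level)) {
    alpha2 <- (1 - conf_level) / 2
    fobs <- ms_rows / ms_err
    df1 <- n - 1
    df2 <- (n - 1) * (k - 1)
    fl <- fobs / qf(1 - alpha2, df1, df2)
    fu <- fobs * qf(1 - alpha2, df2, df1)
    out$conf_level <- conf_level
    out$icc_single_ci <- c(lower = (fl - 1) / (fl + k - 1),
                           upper = (fu - 1) / (fu + k - 1))
  }
  structure(out, class = "icc_mixed")
}

#' @export
print.icc_mixed <- function(x, ...) {
  cat(sprintf(
    "Two-way mixed consistency ICC (n = %d subjects, k = %d raters)\n",
    x$n_subjects, x$k_raters))
  cat(sprintf("  single measure:  %.4f\n", x$icc_single))
  cat(sprintf("  average measure: %.4f\n", x$icc_average))
  cat(sprintf("  standardized alpha: %.4f\n", x$alpha_standardized))
  if (!is.null(x$icc_single_ci)) {
    cat(sprintf("  %d%% CI (single): [%.4f, %.4f]\n",
                round(100 * x$conf_level),
                x$icc_single_ci["lower"], x$icc_single_ci["upper"]))
  }
  invisible(x)
}

#' Cronbach's standardized-items alpha
#'
#' `alpha_std = k * rbar / (1 + (k - 1) * rbar)` where `rbar` is the mean
#' pairwise Pearson correlation among the k rater columns.  May be negative.
#'
#' @inheritParams icc_two_way_mixed
#' @return A single number.
#' @export
#' @examples
#' set.seed(1)
#' s <- rnorm(20)
#' cronbach_alpha_standardized(cbind(s + rnorm(20, sd = .3),
#'                                   s + rnorm(20, sd = .3)))
cronbach_alpha_standardized <- function(values) {
  m <- .as_rater_matrix(values)
  if (any(apply(m, 2, var) == 0)) {
    abort("a rater column has zero variance",
          class = "actimets_degenerate_error")
  }
  r <- cor(m)
  rbar <- mean(r[upper.tri(r)])
  k <- ncol(m)
  k * rbar / (1 + (k - 1) * rbar)
}

# ---- building paired matrices from EE results -------------------------------

#' Pair EE estimates for a reliability contrast
#'
#' Joins record-level MET estimates to the manifest and spreads them into
#' paired rater columns per (speed, equation):
#'
#' * `contrast = "device_at_placement"`: ActiGraph vs SensorID worn at the
#'   same placement (`placement_or_device` selects `"wrist"` or `"thigh"`);
#'   the pairing unit is participant x configuration.
#' * `contrast = "placement_within_device"`: wrist vs thigh recordings of
#'   the same device (`placement_or_device` selects the device, default
#'   `"actigraph"`).
#'
#' Units missing one of the two raters are dropped and reported in the
#' `skipped` attribute.
#'
#' @param ee Tibble from [estimate_energy()].
#' @param manifest Study manifest.
#' @param contrast See above.
#' @param placement_or_device Placement (for the device contrast) or device
#'   (for the placement contrast).
#' @param configurations Configurations to include (default both).
#' @return A tibble with columns `speed_kmh`, `equation`, `corrected`,
#'   `unit`, `rater_1`, `rater_2`.
#' @export
pair_measurements <- function(ee, manifest,
                              contrast = c("device_at_placement",
                                           "placement_within_device"),
                              placement_or_device = NULL,
                              configurations = c(1, 2)) {
  contrast <- match.arg(contrast)
  manifest <- validate_manifest(manifest)
  if (is.null(placement_or_device)) {
    placement_or_device <-
      if (contrast == "device_at_placement") "wrist" else "actigraph"
  }
  dat <- ee |>
    dplyr::inner_join(manifest, by = "record_id") |>
    dplyr::filter(.data$configuration %in% configurations)
  if (contrast == "device_at_placement") {
    dat <- dat |>
      dplyr::filter(.data$placement == placement_or_device) |>
      dplyr::mutate(rater = .data$device)
  } else {
    dat <- dat |>
      dplyr::filter(.data$device == placement_or_device) |>
      dplyr::mutate(rater = .data$placement)
  }
  dat <- dat |>
    dplyr::mutate(
      unit = paste(.data$participant_id, .data$configuration, sep = "/"),
      equation_full = paste0(ifelse(.data$corrected, "corrected_", ""),
                             .data$equation)
    )
  wide <- dat |>
    dplyr::select("speed_kmh", "equation", "corrected", "equation_full",
                  "unit", "rater", "mets") |>
    tidyr::pivot_wider(names_from = "rater", values_from = "mets",
                       names_prefix = "rater_")
  rater_cols <- grep("^rater_", names(wide), value = TRUE)
  if (length(rater_cols) < 2) {
    abort("fewer than two raters present for this contrast",
          class = "actimets_data_error")
  }
  complete <- stats::complete.cases(wide[rater_cols])
  skipped <- wide[!complete, c("speed_kmh", "equation_full", "unit")]
  out <- wide[complete, , drop = FALSE]
  names(out)[match(rater_cols, names(out))] <-
    paste0("rater_", seq_along(rater_cols))
  attr(out, "skipped") <- skipped
  attr(out, "raters") <- sub("^rater_", "", rater_cols)
  out
}

#' Speed x equation agreement table
#'
#' The headline reliability summary: one row per protocol speed, one column
#' of standardized Cronbach's alpha plus one ICC column per equation
#' (five plain, five corrected), and a final `MEAN` row of arithmetic column
#' means.  The per-speed alpha uses the mean over equations of the
#' between-rater Pearson correlation at that speed.
#'
#' @inheritParams pair_measurements
#' @param icc_form `"single"` or `"average"` measure consistency ICC.
#' @return A tibble of class `ee_agreement` with columns `speed`,
#'   `alpha_std` and the ten equation columns; attributes `contrast`,
#'   `icc_form`, `raters` and `skipped`.
#' @export
agreement_table <- function(ee, manifest,
                            contrast = c("device_at_placement",
                                         "placement_within_device"),
                            placement_or_device = NULL,
                            configurations = c(1, 2),
                            icc_form = c("single", "average")) {
  contrast <- match.arg(contrast)
  icc_form <- match.arg(icc_form)
  paired <- pair_measurements(ee, manifest, contrast, placement_or_device,
                              configurations)
  canonical <- c(.equation_ids, paste0("corrected_", .equation_ids))
  eq_levels <- intersect(canonical, unique(paired$equation_full))
  speeds <- sort(unique(paired$speed_kmh))
  one_cell <- function(df) {
    m <- as.matrix(df[, c("rater_1", "rater_2")])
    res <- tryCatch(icc_two_way_mixed(m), error = function(e) NULL)
    if (is.null(res)) return(NA_real_)
    if (icc_form == "single") res$icc_single else res$icc_average
  }
  rows <- purrr::map_dfr(speeds, function(sp) {
    at_speed <- paired[paired$speed_kmh == sp, , drop = FALSE]
    iccs <- vapply(eq_levels, function(eq) {
      one_cell(at_speed[at_speed$equation_full == eq, , drop = FALSE])
    }, numeric(1))
    rs <- vapply(eq_levels, function(eq) {
      d <- at_speed[at_speed$equation_full == eq, , drop = FALSE]
      if (nrow(d) < 3) return(NA_real_)
      suppressWarnings(cor(d$rater_1, d$rater_2))
    }, numeric(1))
    rbar <- mean(rs, na.rm = TRUE)
    alpha <- 2 * rbar / (1 + rbar)
    dplyr::bind_cols(tibble::tibble(speed = as.character(sp),
                                    alpha_std = alpha),
                     tibble::as_tibble(as.list(iccs)))
  })
  mean_row <- dplyr::bind_cols(
    tibble::tibble(speed = "MEAN",
                   alpha_std = mean(rows$alpha_std, na.rm = TRUE)),
    tibble::as_tibble(as.list(colMeans(rows[, eq_levels], na.rm = TRUE)))
  )
  out <- dplyr::bind_rows(rows, mean_row)
  structure(out, class = c("ee_agreement", class(out)),
            contrast = contrast, icc_form = icc_form,
            raters = attr(paired, "raters"),
            skipped = attr(paired, "skipped"))
}

#' Reshape an agreement table to long (tidy) format
#'
#' @param x An `ee_agreement` tibble.
#' @param ... Unused.
#' @return A tibble with columns `speed`, `equation`, `corrected`, `icc`.
#' @export
tidy.ee_agreement <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(cols = -c("speed", "alpha_std"),
                        names_to = "equation_full", values_to = "icc") |>
    dplyr::mutate(
      corrected = startsWith(.data$equation_full, "corrected_"),
      equation = sub("^corrected_", "", .data$equation_full)
    ) |>
    dplyr::select("speed", "equation", "corrected", "icc")
}

#' @rdname icc_two_way_mixed
#' @param x An `icc_mixed` object.
#' @param ... Unused.
#' @export
tidy.icc_mixed <- function(x, ...) {
  tibble::tibble(
    form = c("single", "average"),
    estimate = c(x$icc_single, x$icc_average)
  )
}

#' @rdname icc_two_way_mixed
#' @export
glance.icc_mixed <- function(x, ...) {
  tibble::tibble(
    icc_single = x$icc_single, icc_average = x$icc_average,
    alpha_standardized = x$alpha_standardized,
    ms_subjects = x$ms_subjects, ms_raters = x$ms_raters,
    ms_error = x$ms_error,
    n_subjects = x$n_subjects, k_raters = x$k_raters
  )
}

#' Write an agreement table to CSV
#'
#' Wide speed x equation layout by default; `format = "long"` writes the
#' [tidy()] version.
#'
#' @param x An `ee_agreement`.
#' @param path Output file.
#' @param format `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_agreement_csv <- function(x, path, format = c("wide", "long")) {
  format <- match.arg(format)
  out <- if (format == "wide") tibble::as_tibble(x) else tidy(x)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
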