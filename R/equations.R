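# MET prediction equations operating on activity-count epochs, plus the
# Harris-Benedict resting-metabolic-rate individual correction and intensity
# classification.  Gender coding throughout: 1 = female, 2 = male, entered
# into the Santos-Lozano equations as that raw integer code.

.check_counts <- function(ac, what) {
  if (any(!is.finite(ac)) || any(ac < 0)) {
    abort(sprintf("%s must be finite and non-negative", what),
          class = "actimets_domain_error")
  }
}

.check_gender <- function(gender_code) {
  if (!all(gender_code %in% c(1, 2))) {
    abort("gender_code must be 1 (female) or 2 (male)",
          class = "actimets_domain_error")
  }
}

#' MET prediction equations
#'
#' The five published equations evaluated by the pipeline, in their
#' all-age-group adult forms.  All are vectorized.  `validate = FALSE`
#' disables input checks; it exists so the printed intercepts can be
#' recovered by evaluating at degenerate zero inputs.
#'
#' * Freedson et al. 1998 (vertical axis, counts/min):
#'   `1.439008 + 7.95e-4 * ac_vt_cpm`
#' * Crouter et al. 2010 walking/running branch (vertical axis, counts/10 s),
#'   exponential form: `2.294275 * exp(8.4679e-5 * ac_vt_c10s)`
#' * Santos-Lozano et al. 2013 VT (counts/min, body mass kg, gender code):
#'   `3.4002 + 5.3e-4 * ac - 5.564e-2 * bm + 1.2789 * gender`
#' * Santos-Lozano et al. 2013 VM:
#'   `2.8323 + 5.4e-4 * ac - 5.912e-2 * bm + 1.4410 * gender`
#' * Sasaki et al. 2011 (vector magnitude, counts/min):
#'   `8.63e-4 * ac_vm_cpm + 0.668876`
#'
#' @param ac_vt_cpm Vertical-axis counts per minute.
#' @param ac_vt_c10s Vertical-axis counts per 10 s.
#' @param ac_vm_cpm Vector-magnitude counts per minute.
#' @param body_mass Body mass in kg.
#' @param gender_code 1 = female, 2 = male.
#' @param validate Check argument domains (default `TRUE`).
#' @return METs (numeric).
#' @name met_equations
#' @examples
#' met_freedson1998(1000)
#' met_sasaki2011(10000)
NULL

#' @rdname met_equations
#' @export
met_freedson1998 <- function(ac_vt_cpm, validate = TRUE) {
  if (validate) .check_counts(ac_vt_cpm, "ac_vt_cpm")
  1.439008 + 7.95e-4 * ac_vt_cpm
}

#' @rdname met_equations
#' @export
met_crouter2010 <- function(ac_vt_c10s, validate = TRUE) {
  if (validate) .check_counts(ac_vt_c10s, "ac_vt_c10s")
  2.294275 * exp(8.4679e-5 * ac_vt_c10s)
}

#' @rdname met_equations
#' @export
met_santoslozano_vt <- function(ac_vt_cpm, body_mass, gender_code,
                                validate = TRUE) {
  if (validate) {
    .check_counts(ac_vt_cpm, "ac_vt_cpm")
    stopifnot(all(body_mass > 0))
    .check_gender(gender_code)
  }
  3.4002 + 5.3e-4 * ac_vt_cpm - 5.564e-2 * body_mass + 1.2789 * gender_code
}

#' @rdname met_equations
#' @export
met_santoslozano_vm <- function(ac_vm_cpm, body_mass, gender_code,
                                validate = TRUE) {
  if (validate) {
    .check_counts(ac_vm_cpm, "ac_vm_cpm")
    stopifnot(all(body_mass > 0))
    .check_gender(gender_code)
  }
  2.8323 + 5.4e-4 * ac_vm_cpm - 5.912e-2 * body_mass + 1.4410 * gender_code
}

#' @rdname met_equations
#' @export
met_sasaki2011 <- function(ac_vm_cpm, validate = TRUE) {
  if (validate) .check_counts(ac_vm_cpm, "ac_vm_cpm")
  8.63e-4 * ac_vm_cpm + 0.668876
}

#' Harris-Benedict basal energy expenditure
#'
#' Sex-specific linear predictor of basal energy expenditure in kcal/day:
#' females `655.0955 + 1.8496 * height_cm + 9.5634 * bm - 4.6756 * age`,
#' males `66.4730 + 5.0033 * height_cm + 13.7516 * bm - 6.7550 * age`.
#' Height is stored in metres and converted to cm internally; set
#' `height_unit = "cm"` if your data is already in centimetres.
#'
#' @param age Age in years.
#' @param body_mass Body mass in kg.
#' @param height Height (metres by default).
#' @param gender_code 1 = female, 2 = male.
#' @param height_unit `"m"` or `"cm"`.
#' @param validate Check argument domains.
#' @return kcal/day (numeric, vectorized).
#' @export
#' @examples
#' harris_benedict(age = 30, body_mass = 60, height = 1.65, gender_code = 1)
harris_benedict <- function(age, body_mass, height, gender_code,
                            height_unit = c("m", "cm"), validate = TRUE) {
  height_unit <- match.arg(height_unit)
  if (validate) {
    stopifnot(all(age > 0), all(body_mass > 0), all(height > 0))
    .check_gender(gender_code)
  }
  height_cm <- if (height_unit == "m") height * 100 else height
  female <- 655.0955 + 1.8496 * height_cm + 9.5634 * body_mass - 4.6756 * age
  male <- 66.4730 + 5.0033 * height_cm + 13.7516 * body_mass - 6.7550 * age
  ifelse(gender_code == 1, female, male)
}

#' Individual resting metabolic rate in mL O2 / kg / min
#'
#' Converts the Harris-Benedict kcal/day prediction to an oxygen-uptake rate:
#' divide by 1440 min/day and by 5 kcal per litre O2, multiply by 1000 mL/L,
#' divide by body mass.
#'
#' @inheritParams harris_benedict
#' @return mL O2 per kg per minute.
#' @export
rmr_mlkgmin <- function(age, body_mass, height, gender_code,
                        height_unit = c("m", "cm"), validate = TRUE) {
  hb <- harris_benedict(age, body_mass, height, gender_code,
                        height_unit = height_unit, validate = validate)
  hb * 1000 / (1440 * 5 * body_mass)
}

#' Correct METs for an individual's resting metabolic rate
#'
#' Published MET values assume a resting oxygen uptake of 3.5 mL/kg/min
#' (the Compendium convention).  This rescales a MET value to an
#' individualized resting rate predicted by Harris-Benedict:
#' `corrected = mets * 3.5 / rmr_mlkgmin(...)`.  A person whose predicted
#' resting rate is exactly 3.5 is the fixed point: their METs are unchanged.
#'
#' @param mets Uncorrected MET value(s).
#' @inheritParams harris_benedict
#' @return Corrected METs.
#' @export
corrected_mets <- function(mets, age, body_mass, height, gender_code,
                           height_unit = c("m", "cm"), validate = TRUE) {
  if (validate) stopifnot(all(mets >= 0))
  rmr <- rmr_mlkgmin(age, body_mass, height, gender_code,
                     height_unit = height_unit, validate = validate)
  if (any(rmr <= 0)) {
    abort("predicted resting metabolic rate must be positive",
          class = "actimets_computation_error")
  }
  mets * 3.5 / rmr
}

#' Classify activity intensity from METs
#'
#' Half-open bins: `[0, 1.5)` light, `[1.5, 3)` moderate, `[3, 6)` vigorous,
#' `>= 6` very vigorous (the boundary 6.0 is assigned upward).
#'
#' @param mets Non-negative MET value(s).
#' @return A factor with levels `light`, `moderate`, `vigorous`,
#'   `very_vigorous`.
#' @export
#' @examples
#' classify_intensity(c(1, 2, 3, 6))
classify_intensity <- function(mets) {
  if (any(!is.finite(mets)) || any(mets < 0)) {
    abort("mets must be finite and non-negative",
          class = "actimets_domain_error")
  }
  cut(mets, breaks = c(0, 1.5, 3, 6, Inf), right = FALSE,
      labels = c("light", "moderate", "vigorous", "very_vigorous"))
}

.equation_ids <- c("freedson1998", "crouter2010", "santoslozano_vt",
                   "santoslozano_vm", "sasaki2011")

#' All ten MET estimates for one epoch summary
#'
#' Evaluates the five plain equations on the appropriate count channels of
#' one [epoch_summary()] row, then the five corrected versions via
#' [corrected_mets()], and classifies intensity for each.
#'
#' @param epoch A one-row tibble with `record_id`, `ac_vt_cpm`, `ac_vm_cpm`,
#'   `ac_vt_c10s`.
#' @param participant A one-row tibble with `age`, `body_mass_kg`,
#'   `height_m`, `gender_code` (and optionally `participant_id`).
#' @return A 10-row tibble: `record_id`, `equation`, `corrected` (logical),
#'   `mets`, `intensity`.  The linear equations can predict values below
#'   zero for heavy participants at very low counts; such rows keep their
#'   (linearly corrected) MET value and get an `NA` intensity, since the
#'   intensity bins are only defined for non-negative METs.
#' @export
compute_all <- function(epoch, participant) {
  stopifnot(nrow(epoch) == 1, nrow(participant) == 1)
  p <- participant
  plain <- c(
    freedson1998 = met_freedson1998(epoch$ac_vt_cpm),
    crouter2010 = met_crouter2010(epoch$ac_vt_c10s),
    santoslozano_vt = met_santoslozano_vt(epoch$ac_vt_cpm, p$body_mass_kg,
                                          p$gender_code),
    santoslozano_vm = met_santoslozano_vm(epoch$ac_vm_cpm, p$body_mass_kg,
                                          p$gender_code),
    sasaki2011 = met_sasaki2011(epoch$ac_vm_cpm)
  )
  adj <- corrected_mets(plain, p$age, p$body_mass_kg, p$height_m,
                        p$gender_code, validate = FALSE)
  out <- tibble::tibble(
    record_id = epoch$record_id,
    equation = rep(.equation_ids, 2),
    corrected = rep(c(FALSE, TRUE), each = 5),
    mets = c(unname(plain), unname(adj))
  )
  # negative predictions fall outside the intensity bins -> NA
  out$intensity <- cut(out$mets, breaks = c(0, 1.5, 3, 6, Inf), right = FALSE,
                       labels = c("light", "moderate", "vigorous",
                                  "very_vigorous"))
  out
}

#' Energy-expenditure estimates for a whole study
#'
#' Data-frame-first pipeline step: joins epoch summaries to participants via
#' the manifest and evaluates all ten MET estimates per record.
#'
#' @param epochs Row-bound [epoch_summary()] tibble (one row per record).
#' @param manifest A study manifest linking `record_id` to `participant_id`.
#' @param participants Tibble with `participant_id`, `age`, `body_mass_kg`,
#'   `height_m`, `gender_code`.
#' @return A tibble with 10 rows per record: `record_id`, `equation`,
#'   `corrected`, `mets`, `intensity`.
#' @export
estimate_energy <- function(epochs, manifest, participants) {
  manifest <- validate_manifest(manifest)
  joined <- epochs |>
    dplyr::inner_join(manifest[, c("record_id", "participant_id")],
                      by = "record_id") |>
    dplyr::inner_join(participants, by = "participant_id")
  missing_p <- setdiff(epochs$record_id, joined$record_id)
  if (length(missing_p)) {
    warn(sprintf("%d record(s) without manifest/participant match dropped: %s",
                 length(missing_p),
                 paste(head(missing_p, 5), collapse = ", ")))
  }
  purrr::map_dfr(seq_len(nrow(joined)), function(i) {
    row <- joined[i, ]
    compute_all(row[, c("record_id", "ac_vt_cpm", "ac_vm_cpm", "ac_vt_c10s")],
                row[, c("age", "body_mass_kg", "height_m", "gender_code")])
  })
}

#' Write EE results to CSV
#'
#' One row per record and equation, with the corrected flag, MET value and
#' intensity class.
#'
#' @param ee Tibble from [estimate_energy()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ee_csv <- function(ee, path) {
  readr::write_csv(ee, path, progress = FALSE)
  invisible(path)
}
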