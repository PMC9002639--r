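# Synthetic wearable-signal generator.  Emulates seeded treadmill bouts with
# the protocol's paired-device, multi-speed design so the complete pipeline
# (counts -> METs -> reliability) is exercisable without recorded data.

#' Parametric gait model for one treadmill speed
#'
#' A bout is modelled as a gravity offset on one axis plus a harmonic series
#' at the step frequency plus white sensor noise.  By default the step
#' frequency rises linearly from 1.0 Hz at 1.4 km/h to 2.0 Hz at 10 km/h
#' (keeping the fundamental inside the count filter's passband, whose gain
#' falls off and ripples above roughly 2 Hz) and the
#' dynamic amplitude from 0.05 g to 1.2 g over the same range.  These maps
#' are configuration, not biomechanical claims.
#'
#' @param speed_kmh Treadmill speed in km/h.
#' @param step_frequency_hz Fundamental frequency; default derived from
#'   speed.
#' @param amplitude_g Peak dynamic amplitude of the fundamental on the
#'   dominant axis; default derived from speed.
#' @param gravity_axis Axis carrying the 1 g static component.
#' @param noise_sd_g White-noise standard deviation in g.
#' @param harmonics Number of sinusoidal harmonics (amplitude halves per
#'   harmonic).
#' @param axis_gains Relative dynamic amplitude per axis.
#' @return An object of class `gait_model`.
#' @export
#' @examples
#' gait_model(6)
gait_model <- function(speed_kmh, step_frequency_hz = NULL,
                       amplitude_g = NULL, gravity_axis = c("y", "x", "z"),
                       noise_sd_g = 0.01, harmonics = 3,
                       axis_gains = c(x = 0.6, y = 1, z = 0.3)) {
  gravity_axis <- match.arg(gravity_axis)
  stopifnot(speed_kmh > 0, noise_sd_g >= 0, harmonics >= 1)
  frac <- (speed_kmh - 1.4) / (10 - 1.4)
  if (is.null(step_frequency_hz)) step_frequency_hz <- 1.0 + 1.0 * frac
  if (is.null(amplitude_g)) amplitude_g <- 0.05 + 1.15 * frac
  structure(
    list(speed_kmh = speed_kmh, step_frequency_hz = step_frequency_hz,
         amplitude_g = amplitude_g, gravity_axis = gravity_axis,
         noise_sd_g = noise_sd_g, harmonics = harmonics,
         axis_gains = axis_gains),
    class = "gait_model"
  )
}

# Random phases, one per axis and harmonic.
.gait_phases <- function(harmonics, seed) {
  .with_seed(seed, matrix(runif(3 * harmonics, 0, 2 * pi), nrow = 3,
                          dimnames = list(c("x", "y", "z"), NULL)))
}

# Deterministic motion given phases; evaluable on any time grid, which is
# what lets two co-located devices share one realization.
.gait_motion <- function(model, t, phases) {
  f <- model$step_frequency_hz
  out <- matrix(0, nrow = length(t), ncol = 3,
                dimnames = list(NULL, c("x", "y", "z")))
  for (ax in c("x", "y", "z")) {
    amp <- model$amplitude_g * model$axis_gains[[ax]]
    for (h in seq_len(model$harmonics)) {
      out[, ax] <- out[, ax] +
        amp * 0.5^(h - 1) * sin(2 * pi * f * h * t + phases[ax, h])
    }
  }
  out
}

.build_signal <- function(model, duration_min, fs_hz, phase_seed, noise_seed,
                          record_id, device, dynamic_range_g = NULL) {
  n <- round(duration_min * 60 * fs_hz)
  t <- (seq_len(n) - 1) / fs_hz
  phases <- .gait_phases(model$harmonics, phase_seed)
  motion <- .gait_motion(model, t, phases)
  noise <- .with_seed(noise_seed,
                      matrix(rnorm(3 * n, sd = model$noise_sd_g), ncol = 3))
  acc <- motion + noise
  acc[, model$gravity_axis] <- acc[, model$gravity_axis] + 1
  rng <- if (is.null(dynamic_range_g)) .device_range[[device]] else dynamic_range_g
  if (any(abs(acc) > rng)) {
    warn(sprintf("record %s: amplitude exceeds +/-%g g; clipped (sensor saturation)",
                 record_id, rng))
    acc <- pmax(pmin(acc, rng), -rng)
  }
  raw_accel(time = t, x = acc[, "x"], y = acc[, "y"], z = acc[, "z"],
            record_id = record_id, sample_rate_hz = fs_hz, device = device,
            dynamic_range_g = rng)
}

#' Simulate one treadmill bout
#'
#' @param model A [gait_model()].
#' @param duration_min Bout length in minutes (default 2).
#' @param fs_hz Sampling rate (default 30).
#' @param seed Integer seed; the trace is fully determined by it.
#' @param record_id Identifier for the emitted signal.
#' @param device `"actigraph"` or `"sensorid"`.
#' @return A [raw_accel()].
#' @export
#' @examples
#' sig <- simulate_bout(gait_model(6), duration_min = 1, seed = 1)
simulate_bout <- function(model, duration_min = 2, fs_hz = 30, seed,
                          record_id = "sim",
                          device = c("actigraph", "sensorid")) {
  device <- match.arg(device)
  .build_signal(model, duration_min, fs_hz,
                phase_seed = .mix_seed(seed, "phases"),
                noise_seed = .mix_seed(seed, "noise"),
                record_id = record_id, device = device)
}

#' Simulate two co-located devices recording one bout
#'
#' Both devices observe the same underlying motion realization (identical
#' harmonic phases); device-specific white noise and sampling rates are
#' applied afterwards.  With zero noise and equal rates the two traces are
#' identical.
#'
#' @inheritParams simulate_bout
#' @param noise_a,noise_b Noise SD (g) of device A and B.
#' @param fs_a,fs_b Sampling rates of the two devices.
#' @return A list of two [raw_accel()] objects, named `a` and `b`.
#' @export
simulate_paired_devices <- function(model, noise_a = 0.01, noise_b = 0.02,
                                    duration_min = 2, fs_a = 30, fs_b = 30,
                                    seed, record_id = "sim") {
  phase_seed <- .mix_seed(seed, "phases")
  ma <- modifyList(model, list(noise_sd_g = noise_a))
  mb <- modifyList(model, list(noise_sd_g = noise_b))
  class(ma) <- class(mb) <- "gait_model"
  list(
    a = .build_signal(ma, duration_min, fs_a, phase_seed,
                      .mix_seed(seed, "noise_a"),
                      paste0(record_id, "_a"), "actigraph"),
    b = .build_signal(mb, duration_min, fs_b, phase_seed,
                      .mix_seed(seed, "noise_b"),
                      paste0(record_id, "_b"), "sensorid")
  )
}

#' Design of a simulated paired-device study
#'
#' Defaults reproduce the recording protocol: 5 participants x 3 sensors
#' (ActiGraph wrist, ActiGraph thigh, SensorID) x 2 configurations x 10
#' speeds, 2-min bouts at 30 Hz, i.e. 300 records and 600 min.  The SensorID
#' is worn on the wrist in configuration 1 and on the thigh in configuration
#' 2.  Between-subject variability enters as a shared log-normal amplitude
#' multiplier (`subject_amplitude_sd`) plus an independent per-placement
#' multiplier (`placement_amplitude_sd`); wrist amplitudes are scaled by
#' `wrist_amplitude_factor` relative to the thigh.
#'
#' @param n_participants Number of participants.
#' @param sensors Character vector among `"actigraph_wrist"`,
#'   `"actigraph_thigh"`, `"sensorid"`.
#' @param n_configurations 1 or 2.
#' @param speeds Treadmill speeds (km/h).
#' @param bout_minutes Recorded bout length.
#' @param sample_rate_hz Sampling rate of all sensors.
#' @param device_noise_sd_g Named noise SDs per device.
#' @param subject_amplitude_sd SD of the shared log-amplitude multiplier.
#' @param placement_amplitude_sd SD of the per-placement log-amplitude
#'   multiplier.
#' @param wrist_amplitude_factor Wrist-to-thigh amplitude ratio.
#' @param seed Mandatory integer seed.
#' @return An object of class `sim_design`.
#' @export
sim_design <- function(n_participants = 5,
                       sensors = c("actigraph_wrist", "actigraph_thigh",
                                   "sensorid"),
                       n_configurations = 2,
                       speeds = study_speeds(),
                       bout_minutes = 2,
                       sample_rate_hz = 30,
                       device_noise_sd_g = c(actigraph = 0.01,
                                             sensorid = 0.02),
                       subject_amplitude_sd = 0.15,
                       placement_amplitude_sd = 0.10,
                       wrist_amplitude_factor = 0.8,
                       seed = 20220326) {
  sensors <- match.arg(as.character(unlist(sensors)),
                       c("actigraph_wrist", "actigraph_thigh", "sensorid"),
                       several.ok = TRUE)
  speeds <- as.numeric(unlist(speeds))
  device_noise_sd_g <- unlist(device_noise_sd_g)
  stopifnot(n_participants >= 1, n_configurations %in% c(1, 2),
            length(speeds) >= 1, bout_minutes > 0, sample_rate_hz > 0,
            is.numeric(seed), length(seed) == 1)
  structure(
    list(n_participants = n_participants, sensors = sensors,
         n_configurations = n_configurations, speeds = speeds,
         bout_minutes = bout_minutes, sample_rate_hz = sample_rate_hz,
         device_noise_sd_g = device_noise_sd_g,
         subject_amplitude_sd = subject_amplitude_sd,
         placement_amplitude_sd = placement_amplitude_sd,
         wrist_amplitude_factor = wrist_amplitude_factor,
         seed = as.integer(seed)),
    class = "sim_design"
  )
}

#' Default record-exclusion list for the simulated design
#'
#' Four record ids of the default [sim_design()] manifest that the
#' data-cleaning step removes, leaving 296 of the 300 records.  Record ids
#' follow the scheme `t{participant}{configuration}{sensor}{speed_index}`
#' with speed index 0-9.
#'
#' @return Character vector of length 4.
#' @export
default_exclusions <- function() {
  c("t2221", "t2210", "t2130", "t3127")
}

#' Simulate a complete paired-device study
#'
#' Enumerates participants x configurations x sensors x speeds, draws
#' participant anthropometrics and per-subject gait amplitudes from the
#' design seed, and emits one raw signal per record.  Co-located sensors
#' (same participant, configuration, placement, speed) share one motion
#' realization and differ only in device noise, which is what makes the
#' device-contrast reliability analysis meaningful.  Fully deterministic
#' given the design seed.
#'
#' @param design A [sim_design()].
#' @return A list of class `ee_study`: `manifest` (tibble), `signals`
#'   (named list of [raw_accel()]), `participants` (tibble) and `design`.
#' @export
#' @examples
#' tiny <- sim_design(n_participants = 1, sensors = "actigraph_wrist",
#'                    n_configurations = 1, speeds = 5, seed = 1)
#' study <- simulate_study(tiny)
#' study$manifest
simulate_study <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  seed <- design$seed
  np <- design$n_participants

  participants <- .with_seed(.mix_seed(seed, "participants"), {
    tibble::tibble(
      participant_id = paste0("p", seq_len(np)),
      age = round(runif(np, 22, 45)),
      body_mass_kg = round(pmin(pmax(rnorm(np, 72, 10), 50), 95), 1),
      height_m = round(pmin(pmax(rnorm(np, 1.70, 0.09), 1.50), 1.95), 2),
      gender_code = sample(c(1, 2), np, replace = TRUE)
    )
  })

  # per-subject amplitude multipliers: shared component + placement-specific
  amp <- .with_seed(.mix_seed(seed, "amplitudes"), {
    shared <- exp(rnorm(np, 0, design$subject_amplitude_sd))
    tibble::tibble(
      participant_id = participants$participant_id,
      wrist = shared * exp(rnorm(np, 0, design$placement_amplitude_sd)) *
        design$wrist_amplitude_factor,
      thigh = shared * exp(rnorm(np, 0, design$placement_amplitude_sd))
    )
  })

  sensor_info <- function(sensor, configuration) {
    switch(sensor,
           actigraph_wrist = list(device = "actigraph", placement = "wrist"),
           actigraph_thigh = list(device = "actigraph", placement = "thigh"),
           sensorid = list(device = "sensorid",
                           placement = if (configuration == 1) "wrist" else "thigh"))
  }

  grid <- expand.grid(
    speed_i = seq_along(design$speeds) - 1L,
    sensor_i = seq_along(design$sensors),
    configuration = seq_len(design$n_configurations),
    participant_i = seq_len(np),
    KEEP.OUT.ATTRS = FALSE
  )

  rows <- vector("list", nrow(grid))
  signals <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    sensor <- design$sensors[g$sensor_i]
    info <- sensor_info(sensor, g$configuration)
    speed <- design$speeds[g$speed_i + 1L]
    record_id <- sprintf("t%d%d%d%d", g$participant_i, g$configuration,
                         g$sensor_i, g$speed_i)
    mult <- amp[[info$placement]][g$participant_i]
    model <- gait_model(
      speed,
      noise_sd_g = unname(design$device_noise_sd_g[[info$device]])
    )
    model$amplitude_g <- model$amplitude_g * mult
    # one motion realization per (participant, configuration, placement,
    # speed): co-located devices share it
    phase_seed <- .mix_seed(seed, paste("phase", g$participant_i,
                                        g$configuration, info$placement,
                                        speed))
    noise_seed <- .mix_seed(seed, paste("noise", record_id))
    signals[[i]] <- .build_signal(model, design$bout_minutes,
                                  design$sample_rate_hz, phase_seed,
                                  noise_seed, record_id, info$device)
    rows[[i]] <- tibble::tibble(
      record_id = record_id,
      participant_id = participants$participant_id[g$participant_i],
      device = info$device, placement = info$placement,
      configuration = g$configuration, speed_kmh = speed,
      duration_min = design$bout_minutes
    )
  }
  manifest <- dplyr::bind_rows(rows)
  names(signals) <- manifest$record_id
  structure(list(manifest = validate_manifest(manifest), signals = signals,
                 participants = participants, design = design),
            class = "ee_study")
}

#' @export
print.ee_study <- function(x, ...) {
  cat(sprintf(
    "Simulated study: %d records (%g min total), %d participants, seed %d\n",
    nrow(x$manifest), total_minutes(x$manifest), nrow(x$participants),
    x$design$seed))
  invisible(x)
}
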