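test_that("perfect agreement with real between-subject variance gives ICC 1", {
  m <- cbind(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5))
  res <- icc_two_way_mixed(m)
  expect_equal(res$icc_single, 1)
  expect_equal(res$icc_average, 1)
})

test_that("ICC matches the hand ANOVA decomposition on a fixed matrix", {
  m <- rbind(c(1, 2), c(2, 1), c(3, 3), c(4, 4), c(5, 5))
  oracle <- icc_oracle_aov(m)
  res <- icc_two_way_mixed(m)
  expect_equal(res$icc_single, oracle$single, tolerance = 1e-12)
  expect_equal(res$icc_average, oracle$average, tolerance = 1e-12)
})

test_that("ICC equals the aov oracle on random matrices to 1e-10", {
  set.seed(31)
  for (i in 1:20) {
    m <- matrix(rnorm(20, sd = runif(1, 0.5, 3)), nrow = 10)
    m[, 2] <- m[, 2] + rnorm(10, sd = 0.5)
    oracle <- icc_oracle_aov(m)
    res <- icc_two_way_mixed(m)
    expect_equal(res$icc_single, oracle$single, tolerance = 1e-10)
    expect_equal(res$icc_average, oracle$average, tolerance = 1e-10)
  }
})

test_that("independent raters give ICC near zero", {
  set.seed(12)
  m <- matrix(rnorm(20000), ncol = 2)
  expect_lt(abs(icc_two_way_mixed(m)$icc_single), 0.05)
})

test_that("degenerate inputs raise typed errors", {
  expect_error(icc_two_way_mixed(matrix(3, nrow = 5, ncol = 2)),
               class = "actimets_degenerate_error")
  expect_error(icc_two_way_mixed(matrix(rnorm(4), nrow = 2)),
               class = "actimets_data_error")
  expect_error(icc_two_way_mixed(cbind(rnorm(10))),
               class = "actimets_data_error")
  expect_error(cronbach_alpha_standardized(cbind(rnorm(10), rep(1, 10))),
               class = "actimets_degenerate_error")
})

test_that("standardized alpha matches its closed form from independent r", {
  s <- sin(1:12)                      # deterministic, perfectly correlated
  expect_equal(cronbach_alpha_standardized(cbind(s, s * 2 + 1)), 1)
  set.seed(44)
  for (i in 1:10) {
    m <- matrix(rnorm(40), ncol = 2)
    r <- pearson_manual(m[, 1], m[, 2])
    expect_equal(cronbach_alpha_standardized(m), 2 * r / (1 + r),
                 tolerance = 1e-12)
  }
  # k = 3 uses the mean pairwise correlation
  m3 <- matrix(rnorm(60), ncol = 3)
  rbar <- mean(c(pearson_manual(m3[, 1], m3[, 2]),
                 pearson_manual(m3[, 1], m3[, 3]),
                 pearson_manual(m3[, 2], m3[, 3])))
  expect_equal(cronbach_alpha_standardized(m3),
               3 * rbar / (1 + 2 * rbar), tolerance = 1e-12)
})

test_that("for k = 2 standardized alpha equals average-measure ICC on
           variance-matched columns", {
  set.seed(77)
  s <- rnorm(300)
  m <- cbind(s + rnorm(300, sd = 0.5), s + rnorm(300, sd = 0.5))
  m <- scale(m)  # equal variances: the two indices coincide exactly
  expect_equal(cronbach_alpha_standardized(m),
               icc_two_way_mixed(m)$icc_average, tolerance = 1e-10)
})

test_that("consistency ICC is invariant to global and per-rater shifts", {
  set.seed(9)
  s <- rnorm(50)
  m <- cbind(s + rnorm(50, sd = 0.3), s + rnorm(50, sd = 0.3))
  base <- icc_two_way_mixed(m)$icc_single
  expect_equal(icc_two_way_mixed(m + 100)$icc_single, base, tolerance = 1e-10)
  shifted <- cbind(m[, 1] + 5, m[, 2] - 2)
  expect_equal(icc_two_way_mixed(shifted)$icc_single, base, tolerance = 1e-10)
})

test_that("single-measure ICC recovers the variance-component ratio", {
  set.seed(101)
  n <- 200
  for (ratio in c(0.5, 0.8)) {
    sigma_b <- 1
    sigma_e <- sqrt(sigma_b^2 * (1 - ratio) / ratio)
    subj <- rnorm(n, sd = sigma_b)
    m <- cbind(subj + rnorm(n, sd = sigma_e), subj + rnorm(n, sd = sigma_e))
    expect_equal(icc_two_way_mixed(m)$icc_single, ratio, tolerance = 0.05)
  }
})

test_that("negative ICC arises when within-pair disagreement dominates", {
  m <- rbind(c(1, 5), c(5, 1), c(2, 4), c(4, 2), c(3, 3))
  expect_lt(icc_two_way_mixed(m)$icc_single, 0)
})

test_that("tidy and glance expose the fitted quantities", {
  m <- cbind(rnorm(10), rnorm(10))
  res <- icc_two_way_mixed(m)
  td <- tidy(res)
  expect_equal(td$estimate[td$form == "single"], res$icc_single)
  gl <- glance(res)
  expect_equal(gl$n_subjects, 10)
  expect_equal(gl$k_raters, 2)
  expect_equal(gl$alpha_standardized, cronbach_alpha_standardized(m))
})

test_that("confidence interval brackets the estimate and respects level", {
  set.seed(55)
  s <- rnorm(30)
  m <- cbind(s + rnorm(30, sd = 0.4), s + rnorm(30, sd = 0.4))
  res <- icc_two_way_mixed(m, conf_level = 0.95)
  expect_lt(res$icc_single_ci[["lower"]], res$icc_single)
  expect_gt(res$icc_single_ci[["upper"]], res$icc_single)
})

# ---- agreement tables -------------------------------------------------------

make_paired_study_ee <- function(noise_sd, seed = 123) {
  # MET-level paired "study": 5 participants x 2 configurations per speed,
  # rater B = rater A + noise
  set.seed(seed)
  manifest <- tidyr::expand_grid(
    participant = sprintf("p%d", 1:5),
    configuration = 1:2,
    speed_kmh = study_speeds(),
    device = c("actigraph", "sensorid")
  ) |>
    dplyr::mutate(
      record_id = sprintf("r%04d", dplyr::row_number()),
      participant_id = participant,
      placement = "wrist",
      duration_min = 2
    ) |>
    dplyr::select(record_id, participant_id, device, placement,
                  configuration, speed_kmh, duration_min)
  truth <- manifest |>
    dplyr::distinct(participant_id, configuration, speed_kmh) |>
    dplyr::mutate(true_met = 2 + 0.5 * speed_kmh + rnorm(dplyr::n()))
  base <- manifest |>
    dplyr::left_join(truth, by = c("participant_id", "configuration",
                                   "speed_kmh")) |>
    dplyr::mutate(met_obs = true_met +
                    ifelse(device == "sensorid",
                           rnorm(dplyr::n(), sd = noise_sd), 0))
  ee <- tidyr::expand_grid(
    base[, c("record_id", "met_obs")],
    equation = c("freedson1998", "crouter2010", "santoslozano_vt",
                 "santoslozano_vm", "sasaki2011"),
    corrected = c(FALSE, TRUE)
  ) |>
    dplyr::mutate(mets = met_obs * ifelse(corrected, 1.1, 1),
                  intensity = classify_intensity(pmax(mets, 0))) |>
    dplyr::select(record_id, equation, corrected, mets, intensity)
  list(manifest = manifest, ee = ee)
}

test_that("duplicated rater data yields an all-ones agreement table", {
  made <- make_paired_study_ee(noise_sd = 0)
  tab <- agreement_table(made$ee, made$manifest, "device_at_placement",
                         "wrist")
  expect_equal(nrow(tab), 11)
  expect_equal(tab$speed[11], "MEAN")
  vals <- as.matrix(tab[, -(1:2)])
  expect_true(all(abs(vals - 1) < 1e-10))
  expect_true(all(abs(tab$alpha_std - 1) < 1e-10))
})

test_that("low-noise paired study keeps all per-speed ICC above 0.9", {
  made <- make_paired_study_ee(noise_sd = 0.1)   # sigma_e/sigma_b = 0.1
  tab <- agreement_table(made$ee, made$manifest, "device_at_placement",
                         "wrist")
  body <- tab[tab$speed != "MEAN", ]
  expect_true(all(as.matrix(body[, -(1:2)]) > 0.9))
  expect_equal(nrow(body), 10)
  expect_equal(ncol(tab), 12)  # speed + alpha + 10 equations
})

test_that("units missing a rater are skipped and reported", {
  made <- make_paired_study_ee(noise_sd = 0.1)
  drop_id <- made$manifest$record_id[made$manifest$device == "sensorid"][1]
  ee <- made$ee[made$ee$record_id != drop_id, ]
  tab <- agreement_table(ee, made$manifest, "device_at_placement", "wrist")
  expect_gt(nrow(attr(tab, "skipped")), 0)
})

test_that("tidy() reshapes the agreement table to one row per cell", {
  made <- make_paired_study_ee(noise_sd = 0.1)
  tab <- agreement_table(made$ee, made$manifest, "device_at_placement",
                         "wrist")
  long <- tidy(tab)
  expect_equal(nrow(long), 11 * 10)
  expect_setequal(unique(long$corrected), c(TRUE, FALSE))
})
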