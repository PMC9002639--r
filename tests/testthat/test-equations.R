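test_that("each equation reproduces hand-computed values", {
  expect_equal(met_freedson1998(1000), 2.234008)
  expect_equal(met_freedson1998(2000) - met_freedson1998(1000), 0.795)
  expect_equal(met_crouter2010(1000), 2.294275 * exp(0.084679))
  expect_equal(met_santoslozano_vt(0, 70, 2), 3.4002 - 3.8948 + 2.5578)
  expect_equal(met_santoslozano_vm(1000, 70, 1),
               2.8323 + 0.54 - 4.1384 + 1.4410)
  expect_equal(met_sasaki2011(10000), 9.298876)
  expect_equal(harris_benedict(30, 60, 1.65, 1),
               655.0955 + 1.8496 * 165 + 9.5634 * 60 - 4.6756 * 30)
  expect_equal(harris_benedict(30, 60, 165, 1, height_unit = "cm"),
               harris_benedict(30, 60, 1.65, 1))
})

test_that("all five equations are monotone non-decreasing in counts", {
  ac <- seq(0, 20000, by = 500)
  expect_true(all(diff(met_freedson1998(ac)) >= 0))
  expect_true(all(diff(met_crouter2010(ac / 6)) >= 0))
  expect_true(all(diff(met_santoslozano_vt(ac, 70, 1)) >= 0))
  expect_true(all(diff(met_santoslozano_vm(ac, 70, 1)) >= 0))
  expect_true(all(diff(met_sasaki2011(ac)) >= 0))
})

test_that("gender swap moves the outputs by exactly the gender coefficient", {
  expect_equal(met_santoslozano_vt(1500, 80, 2) - met_santoslozano_vt(1500, 80, 1),
               1.2789)
  expect_equal(met_santoslozano_vm(1500, 80, 2) - met_santoslozano_vm(1500, 80, 1),
               1.4410)
  # and switches the Harris-Benedict branch
  expect_equal(harris_benedict(30, 70, 1.75, 2),
               66.4730 + 5.0033 * 175 + 13.7516 * 70 - 6.7550 * 30)
})

test_that("negative counts and invalid gender codes are domain errors", {
  expect_error(met_freedson1998(-1), class = "actimets_domain_error")
  expect_error(met_sasaki2011(-5), class = "actimets_domain_error")
  expect_error(met_santoslozano_vt(100, 70, 3), class = "actimets_domain_error")
})

test_that("the RMR correction is the Compendium rescaling with HB as RMR", {
  hb <- harris_benedict(30, 60, 1.65, 1)
  rmr <- hb * 1000 / (1440 * 5 * 60)
  expect_equal(rmr_mlkgmin(30, 60, 1.65, 1), rmr)
  expect_equal(corrected_mets(5, 30, 60, 1.65, 1), 5 * 3.5 / rmr)
  # linear in the input METs
  expect_equal(corrected_mets(8, 30, 60, 1.65, 1),
               2 * corrected_mets(4, 30, 60, 1.65, 1))
})

test_that("a person whose predicted RMR is 3.5 mL/kg/min is the fixed point", {
  # solve the female HB equation for height so HB*1000/(1440*5*BM) == 3.5
  bm <- 60; age <- 30
  target_hb <- 3.5 * 1440 * 5 * bm / 1000
  height_m <- (target_hb - 655.0955 - 9.5634 * bm + 4.6756 * age) /
    (1.8496 * 100)
  expect_equal(rmr_mlkgmin(age, bm, height_m, 1), 3.5)
  for (m in c(1, 2.5, 7)) {
    expect_equal(corrected_mets(m, age, bm, height_m, 1), m)
  }
})

test_that("corrected/plain ratio is constant in counts for a fixed person", {
  ac <- c(0, 500, 2000, 10000)
  plain <- met_freedson1998(ac)
  corr <- corrected_mets(plain, 28, 75, 1.80, 2)
  expect_equal(length(unique(round(corr / plain, 12))), 1)
})

test_that("intensity bins are half-open with 6.0 assigned upward", {
  expect_equal(as.character(classify_intensity(c(0, 1.0, 1.49))),
               rep("light", 3))
  expect_equal(as.character(classify_intensity(c(1.5, 2.9))),
               rep("moderate", 2))
  expect_equal(as.character(classify_intensity(c(3.0, 5.99))),
               rep("vigorous", 2))
  expect_equal(as.character(classify_intensity(c(6.0, 12))),
               rep("very_vigorous", 2))
  expect_error(classify_intensity(-0.1), class = "actimets_domain_error")
})

test_that("compute_all composes the standalone operations", {
  p <- tibble::tibble(participant_id = "p1", age = 33, body_mass_kg = 68,
                      height_m = 1.72, gender_code = 2)
  ep <- tibble::tibble(record_id = "r1", ac_vt_cpm = 2500, ac_vm_cpm = 4100,
                       ac_vt_c10s = 2500 / 6)
  res <- compute_all(ep, p)
  expect_equal(nrow(res), 10)
  expect_setequal(unique(res$equation),
                  c("freedson1998", "crouter2010", "santoslozano_vt",
                    "santoslozano_vm", "sasaki2011"))
  pick <- function(eq, corr) res$mets[res$equation == eq & res$corrected == corr]
  expect_equal(pick("freedson1998", FALSE), met_freedson1998(2500))
  expect_equal(pick("crouter2010", FALSE), met_crouter2010(2500 / 6))
  expect_equal(pick("santoslozano_vt", FALSE),
               met_santoslozano_vt(2500, 68, 2))
  expect_equal(pick("santoslozano_vm", FALSE),
               met_santoslozano_vm(4100, 68, 2))
  expect_equal(pick("sasaki2011", FALSE), met_sasaki2011(4100))
  expect_equal(pick("sasaki2011", TRUE),
               corrected_mets(met_sasaki2011(4100), 33, 68, 1.72, 2))
  # zero-count epoch returns the printed intercepts on the plain rows
  ep0 <- tibble::tibble(record_id = "r0", ac_vt_cpm = 0, ac_vm_cpm = 0,
                        ac_vt_c10s = 0)
  res0 <- compute_all(ep0, p)
  expect_equal(res0$mets[!res0$corrected],
               c(1.439008, 2.294275,
                 met_santoslozano_vt(0, 68, 2),
                 met_santoslozano_vm(0, 68, 2), 0.668876))
})

test_that("estimate_energy joins records to participants and warns on gaps", {
  study <- simulate_study(sim_design(n_participants = 2,
                                     sensors = "actigraph_wrist",
                                     n_configurations = 1, speeds = c(5, 8),
                                     seed = 4))
  epochs <- purrr::map_dfr(study$signals, epoch_summary, vertical_axis = "y")
  ee <- estimate_energy(epochs, study$manifest, study$participants)
  expect_equal(nrow(ee), nrow(epochs) * 10)
  orphan <- dplyr::bind_rows(epochs,
                             tibble::tibble(record_id = "zzz", ac_vt_cpm = 0,
                                            ac_vm_cpm = 0, ac_vt_c10s = 0))
  expect_warning(estimate_energy(orphan, study$manifest, study$participants),
                 "zzz")
})
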