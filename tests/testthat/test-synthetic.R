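test_that("zero-noise velocity data is the exact curve, with ground truth attached", {
  d <- generate_velocity_data(1, 5, assay_design(noise_cv = 0))
  expect_equal(d$velocity[d$substrate_conc_mM == 5], rep(0.5, 3))
  expect_equal(d$velocity,
               mm_velocity(d$substrate_conc_mM, 1, 5))
  gt <- attr(d, "ground_truth")
  expect_equal(gt$vmax, 1)
  expect_equal(gt$km, 5)
  expect_identical(gt$n_truncated, 0L)
})

test_that("generation is seed-deterministic and truncation is recorded", {
  des <- assay_design(noise_cv = 0.1, seed = 99)
  expect_identical(generate_velocity_data(1, 5, des),
                   generate_velocity_data(1, 5, des))
  # huge noise forces negative draws, which are truncated and counted
  noisy <- generate_velocity_data(1, 5, assay_design(noise_cv = 3, seed = 1))
  expect_true(all(noisy$velocity >= 0))
  expect_gt(attr(noisy, "ground_truth")$n_truncated, 0)
})

test_that("assay designs outside the measured range need an override", {
  expect_error(assay_design(substrate_grid = c(0.5, 2, 5)),
               class = "phosflux_config_error")
  d <- assay_design(substrate_grid = c(0.5, 2, 5),
                    allow_outside_range = TRUE)
  expect_equal(d$substrate_grid, c(0.5, 2, 5))
  expect_error(assay_design(replicates = 0), class = "phosflux_config_error")
  expect_error(assay_design(enzyme_conc = 2), class = "phosflux_config_error")
})

test_that("plate generation inverts through the fluorescence correction", {
  plate <- generate_plate_data(5000, wells = 4, fp_bg = 100, od_bg = 0.1)
  expect_equal(
    corrected_fluorescence(plate$fp, plate$od, plate$fp_bg, plate$od_bg),
    rep(5000, 4))
  # the worked single-well case
  w <- generate_plate_data(5000, wells = 1, fp_bg = 100, od_bg = 0.1,
                           od_range = c(1, 1))
  expect_equal(w$fp, 4600)
  zero <- generate_plate_data(0, wells = 3)
  expect_equal(correct_plate(zero)$fp_per_od, rep(0, 3))
})

test_that("noisy plate estimates the true intensity within Monte-Carlo error", {
  plate <- generate_plate_data(5000, wells = 96, noise_sd = 200, seed = 12)
  corr <- correct_plate(plate)$fp_per_od
  se <- stats::sd(corr) / sqrt(96)
  expect_lt(abs(mean(corr) - 5000), 3 * se)
})

test_that("the packaged panel matches the published values digit for digit", {
  panel <- bt4131_panel()
  expect_identical(dim(panel), c(20L, 5L))
  expect_equal(
    panel$kcat_km[panel$variant == "WT"],
    c(30.98, 10.08, 2.08, 13.28))
  expect_equal(
    panel$sd[panel$variant == "WT"],
    c(1.75, 1.67, 0.48, 1.83))
  expect_equal(
    panel$kcat_km[panel$substrate == "GlcNAc6P"],
    c(13.28, 31.88, 67.48, 74.72, 126.27))
  m4 <- panel[panel$variant == "M4", ]
  expect_equal(m4$kcat_km[m4$substrate == "Glc6P"], 12.58)
  expect_equal(m4$kcat_km[m4$substrate == "GlcNAc6P"], 126.27)
  expect_equal(m4$sd[m4$substrate == "GlcNAc6P"], 7.84)
  expect_identical(m4$measured[m4$substrate %in% c("Fru6P", "GlcN6P")],
                   c(FALSE, FALSE))
  # digit-for-digit checksum over all measured values
  expect_equal(sum(panel$kcat_km, na.rm = TRUE), 498.16)
  expect_equal(sum(panel$sd, na.rm = TRUE), 50.19)
})

test_that("the default ratio table anchors on wild-type Glc6P", {
  r <- default_ratio_table()
  expect_equal(
    r$vmax_ratio[r$variant == "WT" & r$substrate == "Glc6P"], 1)
  expect_equal(
    r$vmax_ratio[r$variant == "M4" & r$substrate == "GlcNAc6P"],
    126.27 / 30.98)
  expect_true(all(r$km_ratio == 1))
  expect_identical(nrow(r[r$variant == "M4", ]), 2L)  # unmeasured absent
})
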