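test_that("noise-free phantom slices match the analytic ellipse cross-section", {
  spec <- clean_spec()
  ph <- generate_lv_stack(spec)
  px <- spec$pixel_spacing_mm
  sp <- spec$slice_thickness_mm + spec$slice_gap_mm
  axes <- spec$cavity_semi_axes_mm
  for (i in c(1, 3, 6, spec$n_slices)) {
    z <- (i - 0.5) * sp
    s <- sqrt(1 - (z / axes[3])^2)
    a <- axes[1] * s / px; b <- axes[2] * s / px
    analytic_px <- pi * a * b
    perim_px <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
    observed <- sum(ph$contours$ED$endo[, , i])
    # rasterization bound: boundary-cell count, plus one
    expect_lt(abs(observed - analytic_px), perim_px + 1)
  }
  expect_equal(ph$truth$true_cavity_volume_ml, ph$truth$analytic_cavity_volume_ml,
               tolerance = 0.01)
})

test_that("TPM ground truth equals the generator's own rasterized area and mass", {
  spec <- spoke_spec()
  ph <- generate_lv_stack(spec)
  px2 <- spec$pixel_spacing_mm^2
  for (i in seq_len(spec$n_slices)) {
    expect_equal(ph$truth$true_tpm_area_mm2_per_slice[i],
                 sum(ph$tpm_mask[, , i]) * px2)
  }
  sp <- spec$slice_thickness_mm + spec$slice_gap_mm
  expect_equal(ph$truth$true_tpm_mass_g,
               sum(ph$truth$true_tpm_area_mm2_per_slice) * sp * 1.05 / 1000)
  # trabeculae strictly inside the endocardial boundary
  for (i in seq_len(spec$n_slices)) {
    expect_true(all(ph$tpm_mask[, , i] <= ph$contours$ED$endo[, , i]))
    border <- mask_boundary(ph$contours$ED$endo[, , i])
    expect_false(any(ph$tpm_mask[, , i] & border))
  }
})

test_that("identical seeds reproduce bit-identical phantoms", {
  spec <- spoke_spec(noise_sigma = 60, seed = 42L)
  a <- generate_lv_stack(spec)
  b <- generate_lv_stack(spec)
  expect_identical(a$stack$phases, b$stack$phases)
  expect_identical(a$truth, b$truth)
  spec2 <- spoke_spec(noise_sigma = 60, seed = 43L)
  expect_false(identical(generate_lv_stack(spec2)$stack$phases, a$stack$phases))
})

test_that("phantom geometry that does not fit is rejected with the offending dimension", {
  expect_error(lv_phantom_spec(grid_size = 48, cavity_semi_axes_mm = c(30, 28, 90)),
               "grid_size")
  expect_error(lv_phantom_spec(n_slices = 12, cavity_semi_axes_mm = c(24, 22, 85)),
               "cavity_semi_axes_mm\\[3\\]")
  expect_error(lv_phantom_spec(intensity_levels = c(background = 50, myocardium = 400,
                                                    tpm = 400, blood = 1000)),
               "distinct")
})

test_that("fractal border fixtures are closed, 1-px curves of the stated class", {
  for (cls in c("smooth", "koch", "midpoint_displacement")) {
    b <- rasterize_fractal_border(cls, border_param = if (cls == "koch") 4 else 0.5,
                                  grid_size = 512, seed = 3L)
    expect_true(sum(b) > 100)
    inside <- fill_closed_border(b)
    expect_gt(sum(inside), 5 * sum(b))  # a closed curve encloses an interior
  }
  expect_equal(attr(rasterize_fractal_border("koch", 4, 512), "theoretical_fd"),
               log(4) / log(3))
  expect_error(rasterize_fractal_border("koch", 3, 128), "grid_size >= 256")
  expect_error(rasterize_fractal_border("koch", 7, 512), "larger grid_size")
})

test_that("T1 phantom pair inverts the ECV relation exactly", {
  # hand-arithmetic anchor: 1/t1_post = 1/1200 + 0.294/0.58 * (1/350 - 1/1800)
  dr1b <- delta_r1(1800, 350)
  expect_equal(trabeculr:::solve_t1_post_myo(1200, 0.294, 0.42, dr1b), 500,
               tolerance = 1e-3)
  pair <- generate_t1_pair(t1_phantom_spec(target_ecv = 0.30, hematocrit = 0.42))
  expect_equal(attr(ecv_subject(pair), "subject_ecv_pct"), 30, tolerance = 1e-12)
  # non-HF median used as a realistic set-point
  pair2 <- generate_t1_pair(t1_phantom_spec(target_ecv = 0.278))
  expect_equal(attr(ecv_subject(pair2), "subject_ecv_pct"), 27.8, tolerance = 1e-9)
  expect_error(t1_phantom_spec(t1_post_blood_ms = 2000), "shorter")
})

test_that("cohort generation is deterministic and validates planted effects", {
  a <- generate_cohort_table(12, seed = 5L)
  b <- generate_cohort_table(12, seed = 5L)
  expect_identical(a, b)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(a, f1, seed = 5L)
  write_cohort_csv(b, f2, seed = 5L)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(generate_cohort_table(5), "n_per_group")
  expect_error(generate_cohort_table(12, effect_spec = list(outcome = "tpmi",
                                                            effects = c(nope = 1))),
               "unknown planted effect")
})
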