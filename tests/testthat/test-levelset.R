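test_that("contour detection recovers noise-free phantom contours", {
  spec <- spoke_spec()
  ph <- generate_lv_stack(spec)
  for (i in c(2, 5)) {
    ct <- detect_epi_endo_contours(ph$stack$phases$ED[, , i], spec$pixel_spacing_mm)
    expect_gte(dice(ct$endo_mask, ph$contours$ED$endo[, , i]), 0.98)
    expect_gte(dice(ct$epi_mask, ph$contours$ED$epi[, , i]), 0.98)
    expect_true(all(ct$endo_mask <= ct$epi_mask))
  }
})

test_that("a blank slice raises an LV-not-found error", {
  expect_error(detect_epi_endo_contours(matrix(100, 64, 64)), "LV not found")
  expect_error(detect_epi_endo_contours(matrix(rnorm(64^2, 100, 1), 64, 64)),
               "LV not found")
})

test_that("TPM segmentation finds the piecewise-constant optimum on a step edge", {
  fx <- step_edge_fixture()
  seg <- segment_tpm(fx$img, fx$roi)
  # recovered boundary within 1 px of the true step everywhere
  dark_truth <- fx$roi & !fx$truth_high
  expect_lte(hausdorff_px(seg$mask, dark_truth), 1)
  expect_true(seg$converged)
})

test_that("a cavity without trabeculae yields an essentially empty TPM mask", {
  spec <- lv_phantom_spec(trabecula_count = 0, noise_sigma = 66, seed = 9L)
  ph <- generate_lv_stack(spec)
  roi <- ph$contours$ED$endo[, , 3]
  seg <- suppressWarnings(segment_tpm(ph$stack$phases$ED[, , 3], roi))
  expect_lte(sum(seg$mask), 0.01 * sum(roi))
})

test_that("segmentation respects the ROI mask and is deterministic", {
  spec <- spoke_spec(noise_sigma = 66, seed = 2L)
  ph <- generate_lv_stack(spec)
  img <- ph$stack$phases$ED[, , 3]
  roi <- ph$contours$ED$endo[, , 3]
  a <- suppressWarnings(segment_tpm(img, roi))
  b <- suppressWarnings(segment_tpm(img, roi))
  expect_identical(a$mask, b$mask)
  expect_true(all(a$mask <= roi))          # no pixel outside the ROI changes phase
  be <- suppressWarnings(extract_endocardial_border(img, ph$contours$ED$epi[, , 3]))
  expect_true(all(be$mask <= ph$contours$ED$epi[, , 3]))
})

test_that("the discrete level-set energy never increases", {
  spec <- spoke_spec(noise_sigma = 80, seed = 6L)
  ph <- generate_lv_stack(spec)
  seg <- suppressWarnings(segment_tpm(ph$stack$phases$ED[, , 4],
                                      ph$contours$ED$endo[, , 4]))
  expect_true(all(diff(seg$energy_trace) <= 1e-6))
  be <- suppressWarnings(extract_endocardial_border(
    ph$stack$phases$ED[, , 4], ph$contours$ED$epi[, , 4]))
  expect_true(all(diff(be$energy_trace) <= 1e-6))
})

test_that("bias-corrected and plain variants agree when no bias is present", {
  spec <- spoke_spec()
  ph <- generate_lv_stack(spec)
  img <- ph$stack$phases$ED[, , 3]
  roi <- ph$contours$ED$epi[, , 3]
  with_bias <- suppressWarnings(
    extract_endocardial_border(img, roi, level_set_params(bias_basis_order = 2)))
  plain <- suppressWarnings(
    extract_endocardial_border(img, roi, level_set_params(bias_basis_order = 0)))
  expect_gte(dice(with_bias$mask, plain$mask), 0.999)
})

test_that("border extraction under planted bias recovers border and field", {
  spec <- lv_phantom_spec(trabecula_count = 0, noise_sigma = 20,
                          bias_amplitude = 0.3, seed = 8L)
  ph <- generate_lv_stack(spec)
  roi <- ph$contours$ED$epi[, , 3]
  be <- suppressWarnings(extract_endocardial_border(ph$stack$phases$ED[, , 3], roi))
  truth_border <- mask_boundary(ph$contours$ED$endo[, , 3])
  expect_lte(hausdorff_px(be$border, truth_border), 2)
  expect_gte(stats::cor(be$bias_field[roi], ph$truth$bias_field[roi]), 0.95)
})

test_that("an extracted fractal border preserves the downstream FD", {
  koch <- rasterize_fractal_border("koch", 4, 512)
  fx <- border_phantom_image(koch, noise_sigma = 25, seed = 4L)
  roi <- matrix(TRUE, nrow(fx$img), ncol(fx$img))
  be <- suppressWarnings(extract_endocardial_border(fx$img, roi))
  truth_fit <- slice_fd(koch)
  extr_fit <- slice_fd(be$border, scales = truth_fit$scales)
  expect_lte(abs(extr_fit$fd - truth_fit$fd), 0.03)
})
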