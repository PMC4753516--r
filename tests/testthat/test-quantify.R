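geom10 <- slice_geometry(1, slice_thickness_mm = 8, slice_gap_mm = 2)

test_that("contour areas follow pixel count times spacing", {
  m <- matrix(FALSE, 20, 20); m[1:10, 1:10] <- TRUE
  expect_equal(contour_area(m, 1.21), 100 * 1.21^2)
  expect_equal(contour_area(matrix(FALSE, 5, 5), 2), 0)
  # rasterized disk close to pi r^2
  n <- 64; r <- 20
  disk <- (row(matrix(0, n, n)) - 32.5)^2 + (col(matrix(0, n, n)) - 32.5)^2 <= r^2
  expect_equal(contour_area(disk, 1), pi * r^2, tolerance = 0.02)
})

test_that("disc summation is exact for cylinders and accurate for ellipsoids", {
  expect_equal(simpson_volume(rep(500, 10), geom10), 50)
  # full ellipsoid a = b = 25, c = 80 sampled at 10 mm slice centres
  z <- seq(-75, 75, by = 10)
  areas <- pi * 25^2 * (1 - (z / 80)^2)
  expect_equal(simpson_volume(areas, geom10), 4 / 3 * pi * 25 * 25 * 80 / 1000,
               tolerance = 0.03)
  expect_error(simpson_volume(500, geom10), "at least 2")
  expect_error(simpson_volume(c(100, -5), geom10), "non-negative")
})

test_that("LV mass follows the epicardial-minus-cavity convention at 1.05 g/cc", {
  expect_equal(lv_mass(250, 150), 105)
  expect_equal(lv_mass(100, 100), 0)
  expect_error(lv_mass(100, 150), "inversion")
})

test_that("TPM mass accumulates slice areas at myocardial density", {
  expect_equal(tpm_mass(rep(300, 5), geom10), 300 * 5 * 10 * 1.05 / 1000)
  masks <- replicate(3, matrix(FALSE, 10, 10), simplify = FALSE)
  masks[[2]][3:4, 3:4] <- TRUE
  expect_equal(tpm_mass(masks, geom10), 4 * 10 * 1.05 / 1000)
  endo <- replicate(3, matrix(FALSE, 10, 10), simplify = FALSE)  # nothing inside
  expect_error(tpm_mass(masks, geom10, endo_masks = endo), "slice 2")
})

test_that("BSA indexing and ratios are assembled correctly", {
  expect_equal(body_surface_area(170, 70), sqrt(170 * 70 / 3600))
  q <- index_and_ratios(150, 60, 100, 25, 170, 70)
  expect_equal(q$lvef_pct, 60)
  expect_equal(q$tpm_lvm_ratio_pct, 25)
  expect_equal(q$lvedvi_ml_m2, 150 / q$bsa_m2)
  expect_equal(index_and_ratios(100, 100, 100, 10, 170, 70)$lvef_pct, 0)
  expect_error(index_and_ratios(0, 0, 100, 10, 170, 70), "undefined")
  # LVEF is invariant under BSA indexing
  q2 <- index_and_ratios(150, 60, 100, 25, 150, 45)
  expect_equal(q$lvef_pct, q2$lvef_pct)
})

test_that("recovered phantom volumes and masses match generator truth", {
  spec <- spoke_spec()
  ph <- generate_lv_stack(spec)
  geom <- ph$stack$geometry
  q <- quantify_subject(
    endo_masks = list(ED = ph$contours$ED$endo, ES = ph$contours$ES$endo),
    epi_masks = list(ED = ph$contours$ED$epi, ES = ph$contours$ES$epi),
    tpm_masks = ph$tpm_mask, geometry = geom)
  expect_equal(q$lvedv_ml, ph$truth$true_cavity_volume_ml, tolerance = 1e-9)
  expect_equal(q$lvm_g, ph$truth$true_wall_volume_ml * 1.05, tolerance = 1e-9)
  expect_equal(q$tpm_mass_g, ph$truth$true_tpm_mass_g, tolerance = 1e-9)
  expect_true(q$lvesv_ml <= q$lvedv_ml)
  expect_true(q$lvef_pct >= 0 && q$lvef_pct <= 100)
})

test_that("volumes are stable under a resolution change", {
  coarse <- clean_spec(grid_size = 96, pixel_spacing_mm = 5 / 3)
  fine <- clean_spec(grid_size = 192, pixel_spacing_mm = 5 / 6)
  v <- function(s) generate_lv_stack(s)$truth$true_cavity_volume_ml
  expect_equal(v(coarse), v(fine), tolerance = 0.02)
})
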