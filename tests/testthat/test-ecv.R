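test_that("ROI means and relaxation-rate changes follow the stated arithmetic", {
  m <- matrix(1200, 8, 8)
  roi <- matrix(FALSE, 8, 8); roi[3, 3] <- TRUE; roi[4, 4] <- TRUE
  expect_equal(roi_mean_t1(m, roi), 1200)
  m[3, 3] <- 1000; m[4, 4] <- 1400
  expect_equal(roi_mean_t1(m, roi), 1200)
  expect_error(roi_mean_t1(m, matrix(FALSE, 8, 8)), "empty")
  expect_equal(delta_r1(1200, 500), 1 / 500 - 1 / 1200)
  expect_equal(delta_r1(1200, 500), 0.0011667, tolerance = 1e-4)
  expect_equal(delta_r1(1800, 350), 0.0023016, tolerance = 1e-4)
  expect_equal(delta_r1(1000, 1000), 0)
  expect_error(delta_r1(-1, 500), "positive")
})

test_that("the slice ECV formula honors its limits and the hand-worked chain", {
  expect_equal(ecv_slice(0.002, 0.002, 0), 100)
  expect_equal(ecv_slice(0.002, 0.002, 1), 0)
  expect_equal(ecv_slice(delta_r1(1200, 500), delta_r1(1800, 350), 0.42), 29.4,
               tolerance = 0.05 / 29.4)
  expect_error(ecv_slice(0.001, 0, 0.4), "positive")
  # unit invariance: ms and seconds give the same ECV
  expect_equal(ecv_slice(delta_r1(1.2, 0.5), delta_r1(1.8, 0.35), 0.42),
               ecv_slice(delta_r1(1200, 500), delta_r1(1800, 350), 0.42))
  # strictly decreasing in hematocrit
  h <- seq(0.1, 0.9, by = 0.1)
  vals <- vapply(h, function(x) ecv_slice(0.0012, 0.0023, x), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("the generator-analysis round trip is the identity at zero noise", {
  for (target in c(0.25, 0.30, 0.40)) {
    pair <- generate_t1_pair(t1_phantom_spec(target_ecv = target))
    expect_equal(attr(ecv_subject(pair), "subject_ecv_pct"), 100 * target,
                 tolerance = 1e-11)
  }
})

test_that("LGE myocardium is excluded before averaging", {
  pair <- generate_t1_pair(t1_phantom_spec(target_ecv = 0.28, lge_fraction = 0.3,
                                           lge_ecv = 0.55))
  res <- ecv_subject(pair)
  expect_equal(attr(res, "subject_ecv_pct"), 28, tolerance = 0.5)
  # without the mask the hyperenhanced region contaminates the estimate
  no_mask <- t1_pair(pair$t1_pre_ms, pair$t1_post_ms, pair$blood_roi,
                     pair$myo_roi, pair$hematocrit)
  expect_gt(attr(ecv_subject(no_mask), "subject_ecv_pct"), 30)
})

test_that("slices that lose their myocardial ROI are excluded with a reason", {
  pair <- generate_t1_pair(t1_phantom_spec(target_ecv = 0.30))
  lge <- pair$myo_roi
  lge[, , -3] <- FALSE            # slice 3 fully enhanced
  p2 <- t1_pair(pair$t1_pre_ms, pair$t1_post_ms, pair$blood_roi, pair$myo_roi,
                pair$hematocrit, lge_mask = lge)
  res <- ecv_subject(p2)
  expect_false(res$included[res$slice == 3])
  expect_match(res$reason[res$slice == 3], "LGE")
  expect_equal(sum(res$included), 4)
  expect_equal(attr(res, "subject_ecv_pct"), 30, tolerance = 1e-9)
  all_lge <- pair$myo_roi
  p3 <- t1_pair(pair$t1_pre_ms, pair$t1_post_ms, pair$blood_roi, pair$myo_roi,
                pair$hematocrit, lge_mask = all_lge)
  expect_error(ecv_subject(p3), "all slices excluded")
})

test_that("noisy maps stay within the sampling error of the planted mean", {
  pair <- generate_t1_pair(t1_phantom_spec(target_ecv = 0.30,
                                           noise_sigma_ms = 30, seed = 2))
  m <- pair$t1_pre_ms[, , 1][pair$myo_roi[, , 1]]
  sem <- 30 / sqrt(length(m))
  expect_lt(abs(mean(m) - 1200), 3 * sem)
})
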