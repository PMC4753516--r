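test_that("box counts are exact on degenerate and axis-aligned inputs", {
  single <- matrix(FALSE, 32, 32); single[7, 19] <- TRUE
  bc <- box_count(single, c(1, 2, 4, 8, 16))
  expect_equal(bc$count, rep(1, 5))
  line <- matrix(FALSE, 64, 64); line[, 1] <- TRUE  # 64-px vertical line
  expect_equal(box_count(line, c(1, 2, 4, 8))$count, c(64, 32, 16, 8))
  expect_error(box_count(matrix(FALSE, 8, 8), c(1, 2)), "no border pixels")
  expect_error(box_count(single, c(4, 2)), "strictly increasing")
})

test_that("box counts agree with an exhaustive cell-scan oracle", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      border <- matrix(stats::runif(32 * 32) < 0.12, 32, 32)
      if (!any(border)) border[5, 5] <- TRUE
      scales <- c(1, 2, 3, 4, 5, 7, 8, 11, 16)
      bc <- box_count(border, scales)
      oracle <- vapply(scales, function(s) box_count_oracle(border, s), integer(1))
      expect_identical(as.integer(bc$count), oracle)
      expect_true(all(diff(bc$count) <= 0))
    }
  })
})

test_that("the log-log fit recovers exact power laws", {
  s <- c(1, 2, 4, 8, 16)
  exact <- tibble::tibble(scale = s, count = 100 * s^-1.3)
  fit <- fit_fd(exact)
  expect_equal(fit$fd, 1.3, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  line <- fit_fd(tibble::tibble(scale = c(1, 2, 4, 8), count = c(64, 32, 16, 8)))
  expect_equal(line$fd, 1, tolerance = 1e-12)
  expect_error(fit_fd(tibble::tibble(scale = c(1, 2), count = c(4, 2))),
               "at least 3")
})

test_that("known border classes yield their theoretical dimensions", {
  circ <- rasterize_fractal_border("smooth", grid_size = 512)
  expect_equal(slice_fd(circ)$fd, 1, tolerance = 0.02)
  koch <- rasterize_fractal_border("koch", 4, 1024)
  expect_equal(slice_fd(koch)$fd, log(4) / log(3), tolerance = 0.03)
  rough <- slice_fd(rasterize_fractal_border("midpoint_displacement", 0.7, 1024,
                                             seed = 7))$fd
  smooth <- slice_fd(rasterize_fractal_border("midpoint_displacement", 0.2, 1024,
                                              seed = 7))$fd
  expect_gt(rough, 1.02)
  expect_gt(rough, smooth)
})

test_that("FD is robust to rotation and resolution", {
  koch <- rasterize_fractal_border("koch", 4, 1024)
  f <- slice_fd(koch)
  rotated <- t(koch)[, rev(seq_len(nrow(koch)))]
  expect_lte(abs(slice_fd(rotated, scales = f$scales)$fd - f$fd), 0.01)
  f2 <- slice_fd(rasterize_fractal_border("koch", 4, 2048))
  expect_lte(abs(f$fd - f2$fd), 0.02)
})

test_that("maximal apical FD summarizes the apical half", {
  expect_equal(max_apical_fd(c(1.20, 1.22, 1.30, 1.25)), 1.30)
  expect_equal(max_apical_fd(rep(1.25, 4)), 1.25)
  # odd count: apical half is the ceiling(n/2) most apical slices
  expect_equal(max_apical_fd(c(1.1, 1.1, 1.4, 1.2, 1.3)), 1.4)
  expect_error(max_apical_fd(numeric(0)), "no per-slice")
})

test_that("fd_stack composes per-slice fits and annotates the summary", {
  borders <- list(rasterize_fractal_border("smooth", grid_size = 256),
                  rasterize_fractal_border("midpoint_displacement", 0.6, 256,
                                           seed = 2))
  res <- fd_stack(borders)
  expect_s3_class(res, "fd_result")
  expect_equal(nrow(res), 2)
  expect_true(all(res$fd >= 0.95 & res$fd <= 2.05))
  expect_equal(attr(res, "max_apical_fd"), res$fd[2])
})
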