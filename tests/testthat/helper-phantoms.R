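# Shared fixture builders: small, fast phantom configurations.

clean_spec <- function(...) {
  lv_phantom_spec(noise_sigma = 0, bias_amplitude = 0, trabecula_count = 0, ...)
}

spoke_spec <- function(noise_sigma = 0, seed = 1L, ...) {
  lv_phantom_spec(trabecula_count = 6, trabecula_width_mm = 3,
                  noise_sigma = noise_sigma, seed = seed, ...)
}

# two-level image with a known straight step edge inside a disk ROI
step_edge_fixture <- function(n = 64, low = 200, high = 800) {
  img <- matrix(low, n, n)
  img[(n / 2 + 1):n, ] <- high
  cx <- (n + 1) / 2
  roi <- (row(img) - cx)^2 + (col(img) - cx)^2 <= (0.44 * n)^2
  list(img = img, roi = roi, truth_high = roi & row(img) > n / 2)
}

# image whose blood pool is bounded by a supplied closed border curve
border_phantom_image <- function(border, blood = 1000, myo = 400,
                                 bias = NULL, noise_sigma = 0, seed = 1L) {
  interior <- fill_closed_border(border)
  img <- matrix(myo, nrow(border), ncol(border))
  img[interior] <- blood
  if (!is.null(bias)) img <- img * bias
  if (noise_sigma > 0) {
    img <- img + matrix(withr::with_seed(seed, stats::rnorm(length(img), 0, noise_sigma)),
                        nrow(img), ncol(img))
  }
  list(img = img, interior = interior)
}

# exhaustive cell-by-cell box-count oracle (independent of box_count())
box_count_oracle <- function(border, s) {
  n_r <- ceiling(nrow(border) / s)
  n_c <- ceiling(ncol(border) / s)
  count <- 0L
  for (i in seq_len(n_r)) {
    for (j in seq_len(n_c)) {
      rows <- ((i - 1) * s + 1):min(i * s, nrow(border))
      cols <- ((j - 1) * s + 1):min(j * s, ncol(border))
      if (any(border[rows, cols])) count <- count + 1L
    }
  }
  count
}
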