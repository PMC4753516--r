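# Region-based level-set segmentation.
#
# Two variants share one engine:
#   * plain two-phase piecewise-constant (Chan--Vese) energy, evaluated only
#     on pixels inside a region of interest -- used for TPM segmentation;
#   * the same energy under a multiplicative smooth bias field I ~ b(x) * c_k,
#     with level-set evolution and bias re-estimation interleaved -- used for
#     endocardial border extraction ahead of fractal analysis.
#
# The engine performs gradient descent on a smoothed level-set function but
# accepts a step only if the *discrete* two-phase energy (data terms with
# re-optimized class means + length_weight * boundary-edge count) does not
# increase, halving the step otherwise. Mean and bias updates are exact
# minimizers given the current partition, so the recorded energy trace is
# non-increasing by construction. Initialization is deterministic; identical
# inputs give identical masks.

#' Level-set segmentation parameters
#'
#' @param lambda_inside,lambda_outside Data-term weights for the two phases.
#' @param length_weight Weight of the boundary-length penalty (per boundary
#'   edge, normalized-intensity units).
#' @param time_step Gradient-descent step; large values act as an
#'   alternating-minimization sweep and are safe because the step is halved
#'   automatically whenever it would raise the discrete energy.
#' @param max_iterations Iteration cap.
#' @param convergence_tol Mean absolute level-set change per ROI pixel below
#'   which (sustained over 10 iterations) the evolution is declared converged.
#' @param reinit_interval Signed-distance reinitialization period (iterations).
#' @param bias_basis_order Polynomial order of the multiplicative bias model
#'   (0 = constant, i.e. no spatial bias; used by the bias-corrected variant).
#' @param bias_kernel_sigma_px Optional Gaussian smoothing (pixels) applied to
#'   the re-estimated bias field; 0 disables.
#' @param bias_update_interval Iterations between bias re-estimations.
#' @return A `level_set_params` list.
#' @export
level_set_params <- function(lambda_inside = 1, lambda_outside = 1,
                             length_weight = 0.05, time_step = 10,
                             max_iterations = 300L, convergence_tol = 1e-4,
                             reinit_interval = 20L, bias_basis_order = 2L,
                             bias_kernel_sigma_px = 0,
                             bias_update_interval = 5L) {
  assert_scalar_num(lambda_inside, "lambda_inside", lower = 1e-9)
  assert_scalar_num(lambda_outside, "lambda_outside", lower = 1e-9)
  assert_scalar_num(length_weight, "length_weight", lower = 0)
  assert_scalar_num(time_step, "time_step", lower = 1e-9)
  assert_scalar_num(max_iterations, "max_iterations", lower = 1)
  assert_scalar_num(convergence_tol, "convergence_tol", lower = 1e-12)
  assert_scalar_num(reinit_interval, "reinit_interval", lower = 1)
  assert_scalar_num(bias_basis_order, "bias_basis_order", lower = 0)
  assert_scalar_num(bias_kernel_sigma_px, "bias_kernel_sigma_px", lower = 0)
  structure(list(lambda_inside = lambda_inside, lambda_outside = lambda_outside,
                 length_weight = length_weight, time_step = time_step,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 reinit_interval = as.integer(reinit_interval),
                 bias_basis_order = as.integer(bias_basis_order),
                 bias_kernel_sigma_px = bias_kernel_sigma_px,
                 bias_update_interval = as.integer(bias_update_interval)),
            class = "level_set_params")
}

delta_eps <- function(phi, eps = 1.5) eps / (pi * (eps^2 + phi^2))

# Two-threshold Otsu on a binned histogram: returns (t1, t2) in the image's
# normalized units maximizing the three-class between-class variance.
otsu_two_thresholds <- function(img_n, n_bins = 128L) {
  h <- tabulate(pmin(pmax(floor(img_n * n_bins) + 1L, 1L), n_bins), n_bins)
  p <- h / sum(h)
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  W <- cumsum(p)
  M <- cumsum(p * mids)
  mu_total <- M[n_bins]
  best <- c(-1, 1L, 2L)
  for (t1 in 1:(n_bins - 2L)) {
    w1 <- W[t1]; m1s <- M[t1]
    t2 <- (t1 + 1L):(n_bins - 1L)
    w2 <- W[t2] - w1;        m2s <- M[t2] - m1s
    w3 <- 1 - W[t2];         m3s <- mu_total - M[t2]
    term <- function(w, ms) ifelse(w > 0, w * (ms / pmax(w, 1e-300) - mu_total)^2, 0)
    v <- term(w1, m1s) + term(w2, m2s) + term(w3, m3s)
    i <- which.max(v)
    if (v[i] > best[1]) best <- c(v[i], t1, t2[i])
  }
  c(best[2] / n_bins, best[3] / n_bins)
}

# Deterministic initialization: signed distance to the Otsu-thresholded
# bright region within the ROI. Starting from an intensity split separates
# the two phase means immediately, so the descent never has to escape the
# symmetric-partition saddle that geometric initializations sit on.
otsu_init_phi <- function(img, roi) {
  v <- img[roi]
  rng <- range(v)
  if (diff(rng) <= 0) return(signed_distance(roi & FALSE))
  vn <- (v - rng[1]) / diff(rng)
  th <- tryCatch(EBImage::otsu(matrix(vn, nrow = 1), range = c(0, 1)),
                 error = function(e) 0.5)
  bright <- roi
  bright[roi] <- vn > th
  pmin(pmax(signed_distance(bright), -8), 8)
}

curvature_term <- function(phi) {
  n <- nrow(phi); m <- ncol(phi)
  pad <- function(p) rbind(p[1, , drop = FALSE], p, p[n, , drop = FALSE])
  padc <- function(p) cbind(p[, 1, drop = FALSE], p, p[, m, drop = FALSE])
  p <- padc(pad(phi))
  cx <- (p[3:(n + 2), 2:(m + 1)] - p[1:n, 2:(m + 1)]) / 2
  cy <- (p[2:(n + 1), 3:(m + 2)] - p[2:(n + 1), 1:m]) / 2
  grad <- sqrt(cx^2 + cy^2) + 1e-8
  nx <- cx / grad; ny <- cy / grad
  npx <- padc(pad(nx)); npy <- padc(pad(ny))
  (npx[3:(n + 2), 2:(m + 1)] - npx[1:n, 2:(m + 1)]) / 2 +
    (npy[2:(n + 1), 3:(m + 2)] - npy[2:(n + 1), 1:m]) / 2
}

# optimal class means for a partition, under bias field b (b = 1 when plain)
class_means <- function(img, b, mask, roi) {
  inside <- mask & roi; outside <- roi & !mask
  c1 <- if (any(inside)) sum(img[inside] * b[inside]) / sum(b[inside]^2) else 0
  c2 <- if (any(outside)) sum(img[outside] * b[outside]) / sum(b[outside]^2) else 0
  c(c1, c2)
}

discrete_energy <- function(img, b, mask, roi, params) {
  cm <- class_means(img, b, mask, roi)
  inside <- mask & roi; outside <- roi & !mask
  params$lambda_inside * sum((img[inside] - b[inside] * cm[1])^2) +
    params$lambda_outside * sum((img[outside] - b[outside] * cm[2])^2) +
    params$length_weight * perimeter_edges(mask)
}

bias_basis <- function(dims, order) {
  tx <- seq(-1, 1, length.out = dims[1])
  ty <- seq(-1, 1, length.out = dims[2])
  X <- matrix(tx, dims[1], dims[2]); Y <- matrix(ty, dims[1], dims[2], byrow = TRUE)
  cols <- list(rep(1, prod(dims)))
  if (order >= 1) cols <- c(cols, list(as.vector(X), as.vector(Y)))
  if (order >= 2) cols <- c(cols, list(as.vector(X^2), as.vector(X * Y), as.vector(Y^2)))
  do.call(cbind, cols)
}

# weighted least squares fit of the multiplicative bias given the partition
update_bias <- function(img, basis, mask, roi, b_cur, params) {
  cm <- class_means(img, b_cur, mask, roi)
  cpx <- ifelse(mask, cm[1], cm[2])
  idx <- which(roi)
  X <- basis[idx, , drop = FALSE] * cpx[idx]
  beta <- tryCatch(solve(crossprod(X), crossprod(X, img[idx])),
                   error = function(e) NULL)
  if (is.null(beta)) return(b_cur)
  b <- matrix(basis %*% beta, nrow(img), ncol(img))
  if (params$bias_kernel_sigma_px > 0) {
    b <- as.matrix(EBImage::gblur(b, params$bias_kernel_sigma_px))
  }
  b <- pmax(b, 0.2)
  # fix the b*c scale ambiguity: unit mean bias over the ROI
  b / mean(b[roi])
}

# Core engine. init_phi: signed level-set function (positive = phase 1).
# Returns mask of phase 1 (within roi) plus diagnostics.
ls_evolve <- function(img, roi, params, init_phi, bias = FALSE) {
  stopifnot(identical(dim(img), dim(roi)))
  if (!any(roi)) stop("ROI is empty", call. = FALSE)
  rng <- range(img[roi])
  img_n <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0

  basis <- if (bias) bias_basis(dim(img), params$bias_basis_order) else NULL
  b <- matrix(1, nrow(img), ncol(img))
  phi <- init_phi
  mask <- phi > 0 & roi
  energy <- discrete_energy(img_n, b, mask, roi, params)
  trace <- numeric(0)
  idx_roi <- which(roi)
  calm <- 0L
  iter <- 0L
  converged <- FALSE

  while (iter < params$max_iterations) {
    iter <- iter + 1L
    cm <- class_means(img_n, b, mask, roi)
    e_in <- (img_n - b * cm[1])^2
    e_out <- (img_n - b * cm[2])^2
    # global data force (not banded by the delta function) so interior pixels
    # of the wrong phase are reached; curvature acts near the zero level
    force_f <- params$length_weight * delta_eps(phi) * curvature_term(phi) -
      params$lambda_inside * e_in + params$lambda_outside * e_out

    dt <- params$time_step
    accepted <- FALSE
    mean_change <- 0
    for (try in 1:9) {
      phi_try <- phi
      phi_try[idx_roi] <- pmin(pmax(phi[idx_roi] + dt * force_f[idx_roi], -8), 8)
      mask_try <- phi_try > 0 & roi
      e_try <- discrete_energy(img_n, b, mask_try, roi, params)
      if (e_try <= energy + 1e-12) {
        mean_change <- mean(abs(phi_try[idx_roi] - phi[idx_roi]))
        phi <- phi_try; mask <- mask_try; energy <- e_try
        accepted <- TRUE
        break
      }
      dt <- dt / 2
    }
    if (!accepted) mean_change <- 0  # stalled step counts toward convergence

    if (bias && iter %% params$bias_update_interval == 0L) {
      b <- update_bias(img_n, basis, mask, roi, b, params)
      energy <- discrete_energy(img_n, b, mask, roi, params)
    }
    trace <- c(trace, energy)

    calm <- if (mean_change < params$convergence_tol) calm + 1L else 0L
    if (calm >= 10L) { converged <- TRUE; break }

    if (iter %% params$reinit_interval == 0L) {
      phi <- pmin(pmax(signed_distance(mask), -8), 8)
    }
  }
  if (!converged) {
    warning(sprintf("level set did not converge within %d iterations",
                    params$max_iterations), call. = FALSE)
  }
  if (bias) {  # final exact re-fit of the bias on the settled partition
    b <- update_bias(img_n, basis, mask, roi, b, params)
    energy <- discrete_energy(img_n, b, mask, roi, params)
    trace <- c(trace, energy)
  }
  cm <- class_means(img_n, b, mask, roi)
  list(mask = mask, iterations_used = iter, converged = converged,
       energy_trace = trace, means = cm, bias_field = b, img_norm = img_n,
       roi = roi)
}

phase_sd_pooled <- function(img_n, b, mask, roi, cm) {
  inside <- mask & roi; outside <- roi & !mask
  ss <- sum((img_n[inside] - b[inside] * cm[1])^2) +
    sum((img_n[outside] - b[outside] * cm[2])^2)
  sqrt(ss / max(1, sum(roi) - 2))
}

#' Detect epicardial and endocardial LV contours on one short-axis slice
#'
#' Automated contour detection: the slice is lightly smoothed and split into
#' background / myocardium / blood by two-threshold (three-class) Otsu
#' thresholding, which stays robust even when the apical blood pool is a
#' small fraction of the slice. The blood pool is the largest bright
#' component; the smooth endocardial outline is obtained by hole filling
#' plus morphological closing so that trabeculae and papillary muscles fall
#' *inside* the endocardial boundary. The epicardial mask is the filled
#' outline of the whole tissue region.
#'
#' @param slice Numeric matrix, one LV short-axis cross-section with blood
#'   brighter than myocardium.
#' @param pixel_spacing_mm In-plane pixel size (for the plausibility check).
#' @param min_area_mm2 Smallest blood-pool area accepted as an LV cavity.
#' @param closing_radius_px Structuring-element radius for the smoothing
#'   closing step.
#' @return List with `endo_mask`, `epi_mask` (logical matrices; endocardial
#'   strictly inside epicardial) and the matching 1-px `endo_border`,
#'   `epi_border` curves.
#' @export
detect_epi_endo_contours <- function(slice, pixel_spacing_mm = 1,
                                     min_area_mm2 = 80, closing_radius_px = 3) {
  stopifnot(is.matrix(slice), is.numeric(slice))
  if (diff(range(slice)) < 1e-9) {
    stop("LV not found: slice has no intensity contrast", call. = FALSE)
  }
  sm <- as.matrix(EBImage::gblur(slice, sigma = 1))
  rng <- range(sm)
  smn <- (sm - rng[1]) / diff(rng)
  th <- otsu_two_thresholds(smn)                 # background | myocardium | blood
  tissue <- smn > th[1]
  raw_blood <- smn > th[2]
  # class-separation guard: a featureless (noise-only) slice splits into
  # three classes whose means sit within ~2.3 pooled within-class SDs of
  # each other; real blood/myocardium/background contrast is far larger
  lab <- 1L + (smn > th[1]) + (smn > th[2])
  mk <- vapply(1:3, function(k) mean(smn[lab == k]), numeric(1))
  vk <- vapply(1:3, function(k) stats::var(as.vector(smn[lab == k])), numeric(1))
  wk <- vapply(1:3, function(k) mean(lab == k), numeric(1))
  s_w <- sqrt(sum(wk * ifelse(is.na(vk), 0, vk)))
  if (any(is.na(mk)) || min(diff(mk)) < 3 * s_w) {
    stop("LV not found: slice lacks the blood/myocardium/background contrast ",
         "of a short-axis LV section", call. = FALSE)
  }
  # plausibility guard: the brightest class must contain one compact pool
  raw_cc_area <- sum(largest_component(raw_blood)) * prod(rep(pixel_spacing_mm, 2)[1:2])
  if (raw_cc_area < min_area_mm2) {
    stop(sprintf(paste0("LV not found: largest bright component is %.1f mm^2 ",
                        "(< %.1f mm^2); check the field of view or intensities"),
                 raw_cc_area, min_area_mm2), call. = FALSE)
  }
  # close before picking the component: thin trabecular recesses must not
  # fragment the blood pool
  blood <- largest_component(morph_close(raw_blood, closing_radius_px))
  area_mm2 <- sum(blood) * pixel_spacing_mm^2
  if (area_mm2 < min_area_mm2) {
    stop(sprintf(paste0("LV not found: largest bright component is %.1f mm^2 ",
                        "(< %.1f mm^2); check the field of view or intensities"),
                 area_mm2, min_area_mm2), call. = FALSE)
  }
  endo <- morph_close(fill_closed_border(blood), closing_radius_px)
  endo <- fill_closed_border(endo)

  heart <- largest_component(tissue)
  epi <- morph_close(fill_closed_border(heart), closing_radius_px)
  epi <- fill_closed_border(epi) | endo

  list(endo_mask = endo, epi_mask = epi,
       endo_border = mask_boundary(endo), epi_border = mask_boundary(epi))
}

#' Segment trabeculae and papillary muscle inside the endocardium
#'
#' Two-phase piecewise-constant level-set segmentation driven only by
#' intensities inside the endocardial mask: the converged dark phase is the
#' TPM, the bright complement the residual blood pool. The level set is
#' initialized deterministically from an Otsu split of the ROI intensities,
#' which separates the phase means immediately and avoids the symmetric
#' partition saddle. When the two recovered phase means are
#' not separated beyond three pooled within-phase standard deviations the
#' cavity is declared TPM-free and an empty mask returned.
#'
#' @param slice Numeric image matrix.
#' @param endocardial_mask Logical matrix; segmentation never alters pixels
#'   outside it.
#' @param params A [level_set_params()].
#' @return A `segmentation_result`: list with `mask` (TPM pixels),
#'   `iterations_used`, `converged`, `energy_trace` (non-increasing), `means`.
#' @export
segment_tpm <- function(slice, endocardial_mask, params = level_set_params()) {
  roi <- as_binary_matrix(endocardial_mask, "endocardial_mask")
  if (!any(roi)) stop("endocardial mask is empty", call. = FALSE)
  phi0 <- otsu_init_phi(slice, roi)
  res <- ls_evolve(slice, roi, params, phi0, bias = FALSE)

  dark_first <- res$means[1] < res$means[2]
  tpm <- if (dark_first) res$mask else (roi & !res$mask)
  sdp <- phase_sd_pooled(res$img_norm, matrix(1, nrow(slice), ncol(slice)),
                         res$mask, roi, res$means)
  if (abs(diff(res$means)) < 3 * sdp) tpm <- roi & FALSE  # unimodal cavity
  structure(list(mask = tpm, iterations_used = res$iterations_used,
                 converged = res$converged, energy_trace = res$energy_trace,
                 means = sort(res$means)),
            class = "segmentation_result")
}

#' Extract the endocardial border with interleaved bias correction
#'
#' Segments the blood pool inside the supplied ROI with the two-phase
#' level-set model under a multiplicative polynomial bias field; level-set
#' evolution and bias re-estimation are interleaved. The returned border is
#' the 1-px-wide, 8-connected outline of the converged blood-pool mask and
#' preserves trabecular recesses, making it suitable for box-counting
#' fractal analysis. With `bias_basis_order = 0` the model reduces to the
#' plain region-based segmentation.
#'
#' @param slice Numeric image matrix.
#' @param roi_mask Logical matrix (e.g. the epicardial mask); pixels outside
#'   it are never touched.
#' @param params A [level_set_params()].
#' @return A `segmentation_result` with additional elements `border`
#'   (logical matrix) and `bias_field` (estimated multiplicative field,
#'   unit mean over the ROI).
#' @export
extract_endocardial_border <- function(slice, roi_mask,
                                       params = level_set_params()) {
  roi <- as_binary_matrix(roi_mask, "roi_mask")
  if (!any(roi)) stop("ROI mask is empty", call. = FALSE)
  phi0 <- otsu_init_phi(slice, roi)
  res <- ls_evolve(slice, roi, params, phi0,
                   bias = params$bias_basis_order > 0)

  bright_first <- res$means[1] >= res$means[2]
  blood <- if (bright_first) res$mask else (roi & !res$mask)
  blood <- largest_component(blood)
  structure(list(mask = blood, border = mask_boundary(blood),
                 bias_field = res$bias_field,
                 iterations_used = res$iterations_used,
                 converged = res$converged, energy_trace = res$energy_trace,
                 means = sort(res$means, decreasing = TRUE)),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("level-set segmentation: %d px in mask, %d iterations, %s\n",
              sum(x$mask), x$iterations_used,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
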