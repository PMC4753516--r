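# Extracellular volume fraction from paired pre/post-contrast T1 maps.
#
# ECV = (delta R1 of myocardium / delta R1 of blood) * (1 - hematocrit),
# with delta R1 = 1/T1_post - 1/T1_pre, computed from ROI-averaged T1 values
# per slice and averaged over the stack after pixel-level exclusion of any
# late-gadolinium-enhanced (LGE) myocardium.

#' Mean T1 over a region of interest
#' @param map Numeric T1 map (ms).
#' @param roi Logical mask, non-empty.
#' @return Mean T1 in ms.
#' @export
roi_mean_t1 <- function(map, roi) {
  roi <- as_binary_matrix(roi, "roi")
  if (!any(roi)) stop("ROI is empty", call. = FALSE)
  mean(map[roi])
}

#' Change in longitudinal relaxation rate
#'
#' @param t1_pre_ms,t1_post_ms Pre- and post-contrast T1 (ms), positive.
#' @return Delta R1 = 1/T1_post - 1/T1_pre, in 1/ms; positive when the
#'   post-contrast T1 is shorter.
#' @export
delta_r1 <- function(t1_pre_ms, t1_post_ms) {
  if (any(c(t1_pre_ms, t1_post_ms) <= 0)) {
    stop("T1 values must be positive", call. = FALSE)
  }
  1 / t1_post_ms - 1 / t1_pre_ms
}

#' Single-slice ECV from myocardial and blood relaxation-rate changes
#'
#' @param dr1_myo,dr1_blood Delta R1 of the myocardial and blood ROIs (1/ms).
#' @param hematocrit Hematocrit fraction in (0, 1).
#' @return ECV in percent.
#' @export
ecv_slice <- function(dr1_myo, dr1_blood, hematocrit) {
  assert_scalar_num(hematocrit, "hematocrit", lower = 0, upper = 1)
  if (dr1_blood <= 0) {
    stop("blood delta R1 must be positive (post-contrast T1 must be shorter)",
         call. = FALSE)
  }
  100 * (dr1_myo / dr1_blood) * (1 - hematocrit)
}

#' Construct a pre/post-contrast T1 pair for one subject
#'
#' @param t1_pre_ms,t1_post_ms Numeric T1 maps in ms: matrices (one slice) or
#'   3D arrays (x, y, slice).
#' @param blood_roi,myo_roi Logical masks (matching 2D/3D shape), disjoint.
#' @param hematocrit Hematocrit fraction in (0, 1).
#' @param lge_mask Optional logical mask of late-gadolinium-enhanced tissue.
#' @return A `t1_pair` object.
#' @export
t1_pair <- function(t1_pre_ms, t1_post_ms, blood_roi, myo_roi, hematocrit,
                    lge_mask = NULL) {
  to3 <- function(x) if (length(dim(x)) == 2L) array(x, c(dim(x), 1L)) else x
  t1_pre_ms <- to3(t1_pre_ms); t1_post_ms <- to3(t1_post_ms)
  blood_roi <- to3(blood_roi) > 0; myo_roi <- to3(myo_roi) > 0
  if (!is.null(lge_mask)) lge_mask <- to3(lge_mask) > 0
  stopifnot(identical(dim(t1_pre_ms), dim(t1_post_ms)),
            identical(dim(t1_pre_ms), dim(blood_roi)),
            identical(dim(t1_pre_ms), dim(myo_roi)))
  if (any(t1_pre_ms <= 0) || any(t1_post_ms <= 0)) {
    stop("T1 maps must be strictly positive", call. = FALSE)
  }
  if (any(blood_roi & myo_roi)) stop("blood and myocardial ROIs overlap", call. = FALSE)
  assert_scalar_num(hematocrit, "hematocrit", lower = 1e-6, upper = 1 - 1e-6)
  structure(list(t1_pre_ms = t1_pre_ms, t1_post_ms = t1_post_ms,
                 blood_roi = blood_roi, myo_roi = myo_roi,
                 lge_mask = lge_mask, hematocrit = hematocrit),
            class = "t1_pair")
}

#' Subject-level ECV with LGE exclusion and slice averaging
#'
#' For each slice the myocardial ROI is reduced by any pixels flagged in the
#' LGE mask; slices whose myocardial (or blood) ROI becomes empty are
#' excluded with a logged reason. Per-slice ECV values are computed from
#' ROI-mean T1 values and averaged into the subject value.
#'
#' @param pair A [t1_pair()] (multi-slice arrays).
#' @return An `ecv_result` tibble with one row per slice (`slice`,
#'   `ecv_pct`, `included`, `reason`) and attributes `subject_ecv_pct` and
#'   `hematocrit`.
#' @export
ecv_subject <- function(pair) {
  stopifnot(inherits(pair, "t1_pair"))
  n <- dim(pair$t1_pre_ms)[3]
  rows <- purrr::map_dfr(seq_len(n), function(i) {
    myo <- pair$myo_roi[, , i]
    blood <- pair$blood_roi[, , i]
    if (!is.null(pair$lge_mask)) myo <- myo & !pair$lge_mask[, , i]
    if (!any(myo)) {
      return(tibble::tibble(slice = i, ecv_pct = NA_real_, included = FALSE,
                            reason = "myocardial ROI empty after LGE exclusion"))
    }
    if (!any(blood)) {
      return(tibble::tibble(slice = i, ecv_pct = NA_real_, included = FALSE,
                            reason = "blood ROI empty"))
    }
    dr1_m <- delta_r1(roi_mean_t1(pair$t1_pre_ms[, , i], myo),
                      roi_mean_t1(pair$t1_post_ms[, , i], myo))
    dr1_b <- delta_r1(roi_mean_t1(pair$t1_pre_ms[, , i], blood),
                      roi_mean_t1(pair$t1_post_ms[, , i], blood))
    tibble::tibble(slice = i,
                   ecv_pct = ecv_slice(dr1_m, dr1_b, pair$hematocrit),
                   included = TRUE, reason = NA_character_)
  })
  if (!any(rows$included)) {
    stop("all slices excluded: no myocardial ROI left to average", call. = FALSE)
  }
  attr(rows, "subject_ecv_pct") <- mean(rows$ecv_pct[rows$included])
  attr(rows, "hematocrit") <- pair$hematocrit
  class(rows) <- c("ecv_result", class(rows))
  rows
}

#' @export
print.ecv_result <- function(x, ...) {
  NextMethod()
  cat(sprintf("subject ECV: %.2f%% (mean of %d included slices)\n",
              attr(x, "subject_ecv_pct"), sum(x$included)))
  invisible(x)
}

#' Specify a synthetic T1-mapping phantom
#'
#' The post-contrast myocardial T1 is solved from the ECV relation so that
#' the noise-free recovered ECV equals `target_ecv` exactly:
#' 1/T1_post_myo = 1/T1_pre_myo + target_ecv / (1 - hct) * delta R1_blood.
#'
#' @param t1_pre_blood_ms,t1_post_blood_ms,t1_pre_myo_ms Blood and myocardial
#'   T1 set-points (ms); post-contrast blood must be shorter than
#'   pre-contrast.
#' @param hematocrit Hematocrit fraction in (0, 1).
#' @param target_ecv Ground-truth ECV fraction in (0, 1).
#' @param noise_sigma_ms Additive Gaussian noise on the maps (ms).
#' @param lge_fraction Fraction of the myocardial ROI replaced by a
#'   contiguous hyperenhanced (LGE) septal region, in \[0, 1).
#' @param lge_ecv ECV fraction planted inside the LGE region.
#' @param seed Integer seed.
#' @return A `t1_phantom_spec` list.
#' @export
t1_phantom_spec <- function(t1_pre_blood_ms = 1800, t1_post_blood_ms = 350,
                            t1_pre_myo_ms = 1200, hematocrit = 0.42,
                            target_ecv = 0.278, noise_sigma_ms = 0,
                            lge_fraction = 0, lge_ecv = 0.55, seed = 1L) {
  assert_scalar_num(t1_pre_blood_ms, "t1_pre_blood_ms", lower = 1e-6)
  assert_scalar_num(t1_post_blood_ms, "t1_post_blood_ms", lower = 1e-6)
  assert_scalar_num(t1_pre_myo_ms, "t1_pre_myo_ms", lower = 1e-6)
  assert_scalar_num(hematocrit, "hematocrit", lower = 1e-6, upper = 1 - 1e-6)
  assert_scalar_num(target_ecv, "target_ecv", lower = 1e-6, upper = 1 - 1e-6)
  assert_scalar_num(noise_sigma_ms, "noise_sigma_ms", lower = 0)
  assert_scalar_num(lge_fraction, "lge_fraction", lower = 0, upper = 1 - 1e-9)
  assert_scalar_num(lge_ecv, "lge_ecv", lower = 1e-6, upper = 1 - 1e-6)
  if (t1_post_blood_ms >= t1_pre_blood_ms) {
    stop("post-contrast blood T1 must be shorter than pre-contrast", call. = FALSE)
  }
  structure(list(t1_pre_blood_ms = t1_pre_blood_ms,
                 t1_post_blood_ms = t1_post_blood_ms,
                 t1_pre_myo_ms = t1_pre_myo_ms, hematocrit = hematocrit,
                 target_ecv = target_ecv, noise_sigma_ms = noise_sigma_ms,
                 lge_fraction = lge_fraction, lge_ecv = lge_ecv,
                 seed = as.integer(seed)),
            class = "t1_phantom_spec")
}

# post-contrast myocardial T1 consistent with a given ECV
solve_t1_post_myo <- function(t1_pre_myo_ms, ecv, hematocrit, dr1_blood) {
  r1_post <- 1 / t1_pre_myo_ms + ecv / (1 - hematocrit) * dr1_blood
  if (r1_post <= 0) {
    stop("no positive post-contrast myocardial T1 exists for this target ECV ",
         "and hematocrit", call. = FALSE)
  }
  1 / r1_post
}

#' Generate a pre/post-contrast T1 phantom pair with known ECV
#'
#' Builds a five-slice T1 map pair on the LV geometry of `geometry` (blood
#' ROI: central cavity disk; myocardial ROI: septal wall sector), with the
#' post-contrast myocardial T1 solved from the ECV relation so the noise-free
#' analysis recovers `target_ecv` exactly. If `lge_fraction > 0`, a
#' contiguous septal sub-sector carries the higher `lge_ecv` and is flagged
#' in the LGE mask.
#'
#' @param spec A [t1_phantom_spec()].
#' @param geometry A [lv_phantom_spec()] providing grid and cavity geometry.
#' @param n_slices Number of T1 slices (default 5).
#' @return A [t1_pair()] with attribute `truth` (list: `target_ecv`,
#'   `t1_post_myo_ms`, `lge_ecv`, `seed`).
#' @export
generate_t1_pair <- function(spec, geometry = lv_phantom_spec(),
                             n_slices = 5L) {
  stopifnot(inherits(spec, "t1_phantom_spec"))
  g <- geometry$grid_size
  px <- geometry$pixel_spacing_mm
  axes <- geometry$cavity_semi_axes_mm
  centre <- (g + 1) / 2
  x <- matrix(seq_len(g) - centre, g, g)
  y <- matrix(seq_len(g) - centre, g, g, byrow = TRUE)
  a_px <- axes[1] * 0.85 / px; b_px <- axes[2] * 0.85 / px
  wall_px <- geometry$wall_thickness_mm / px
  rn <- sqrt((x / a_px)^2 + (y / b_px)^2)

  blood2d <- rn <= 0.45                       # central cavity
  ring <- rn > 1 & sqrt((x / (a_px + wall_px))^2 + (y / (b_px + wall_px))^2) <= 1
  ang <- atan2(y, x)
  myo2d <- ring & ang > (100 * pi / 180) & ang < (170 * pi / 180)   # septal sector
  if (!any(myo2d) || !any(blood2d)) stop("T1 phantom geometry degenerate", call. = FALSE)

  dr1_b <- delta_r1(spec$t1_pre_blood_ms, spec$t1_post_blood_ms)
  t1_post_myo <- solve_t1_post_myo(spec$t1_pre_myo_ms, spec$target_ecv,
                                   spec$hematocrit, dr1_b)
  t1_post_lge <- solve_t1_post_myo(spec$t1_pre_myo_ms, spec$lge_ecv,
                                   spec$hematocrit, dr1_b)

  lge2d <- myo2d & FALSE
  if (spec$lge_fraction > 0) {
    # contiguous hyperenhanced sub-sector at the start of the septal arc
    amin <- 100 * pi / 180
    acut <- amin + spec$lge_fraction * (70 * pi / 180)
    lge2d <- myo2d & ang < acut
  }

  base_pre <- matrix(1000, g, g)   # non-LV background tissue
  base_post <- matrix(600, g, g)
  pre2d <- base_pre; post2d <- base_post
  pre2d[blood2d] <- spec$t1_pre_blood_ms
  post2d[blood2d] <- spec$t1_post_blood_ms
  pre2d[myo2d] <- spec$t1_pre_myo_ms
  post2d[myo2d] <- t1_post_myo
  post2d[lge2d] <- t1_post_lge

  rep3 <- function(m) array(m, c(g, g, n_slices))
  pre <- rep3(pre2d); post <- rep3(post2d)
  if (spec$noise_sigma_ms > 0) {
    noise <- with_seed_(spec$seed, list(
      array(stats::rnorm(length(pre), 0, spec$noise_sigma_ms), dim(pre)),
      array(stats::rnorm(length(post), 0, spec$noise_sigma_ms), dim(post))))
    pre <- pmax(pre + noise[[1]], 1)
    post <- pmax(post + noise[[2]], 1)
  }
  pair <- t1_pair(pre, post, rep3(blood2d), rep3(myo2d), spec$hematocrit,
                  lge_mask = if (any(lge2d)) rep3(lge2d) else NULL)
  attr(pair, "truth") <- list(target_ecv = spec$target_ecv,
                              t1_post_myo_ms = t1_post_myo,
                              lge_ecv = spec$lge_ecv, seed = spec$seed)
  pair
}
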