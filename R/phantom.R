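# Synthetic short-axis LV phantom generator.
#
# Geometry: the cavity is the basal half of an ellipsoid with semi-axes
# (a, b, c) mm; slice i sits at depth z_i = (i - 1/2) * (thickness + gap)
# from the base, and its cross-section is the ellipse with semi-axes
# (a, b) * sqrt(1 - (z_i/c)^2). The wall is a constant-thickness rind
# around the cavity. Trabeculae are radial spokes plus two papillary
# disks, rasterized inside the cavity with their pixel areas recorded as
# ground truth. End-systole reuses the same geometry with the in-plane
# cavity semi-axes contracted by `es_scale`.

#' Specify a synthetic left-ventricular short-axis phantom
#'
#' All lengths are millimetres. Intensities are arbitrary units; the four
#' tissue classes must have distinct noise-free levels.
#'
#' @param n_slices Number of short-axis slices, base to apex.
#' @param pixel_spacing_mm In-plane pixel size (isotropic).
#' @param slice_thickness_mm Slice thickness (default 8).
#' @param slice_gap_mm Inter-slice gap (default 2).
#' @param grid_size Image matrix size (pixels per side).
#' @param cavity_semi_axes_mm Length-3 vector (a, b, c): in-plane semi-axes
#'   at the base and the base-to-apex semi-axis.
#' @param wall_thickness_mm Myocardial wall thickness.
#' @param trabecula_count Number of radial trabecular spokes (0 for none).
#' @param trabecula_width_mm Spoke width; also sets the papillary disk size.
#' @param border_class Endocardial border family: `"smooth"` (ellipse),
#'   `"koch"` (triadic Koch island, theoretical box-counting dimension
#'   log 4 / log 3), or `"midpoint_displacement"` (random rough closed curve).
#' @param border_param Iteration depth (koch) or roughness in (0, 1)
#'   (midpoint_displacement); ignored for `"smooth"`.
#' @param intensity_levels Named vector with entries `background`,
#'   `myocardium`, `tpm`, `blood`.
#' @param bias_amplitude Amplitude of the multiplicative low-order polynomial
#'   bias field, as a fraction of 1 (0 disables).
#' @param noise_sigma Additive noise standard deviation, image units.
#' @param noise_model `"gaussian"` (default) or `"rician"`.
#' @param es_scale In-plane cavity contraction factor at end-systole.
#' @param seed Integer seed; drives every random element of the phantom.
#' @return A `phantom_spec` list.
#' @export
lv_phantom_spec <- function(n_slices = 8,
                            pixel_spacing_mm = 1.25,
                            slice_thickness_mm = 8,
                            slice_gap_mm = 2,
                            grid_size = 128,
                            cavity_semi_axes_mm = c(24, 22, 85),
                            wall_thickness_mm = 9,
                            trabecula_count = 6,
                            trabecula_width_mm = 3,
                            border_class = c("smooth", "koch", "midpoint_displacement"),
                            border_param = 0.5,
                            intensity_levels = c(background = 50, myocardium = 400,
                                                 tpm = 350, blood = 1000),
                            bias_amplitude = 0,
                            noise_sigma = 0,
                            noise_model = c("gaussian", "rician"),
                            es_scale = 0.65,
                            seed = 1L) {
  border_class <- match.arg(border_class)
  noise_model <- match.arg(noise_model)
  assert_scalar_num(n_slices, "n_slices", lower = 2)
  assert_scalar_num(pixel_spacing_mm, "pixel_spacing_mm", lower = 1e-6)
  assert_scalar_num(slice_thickness_mm, "slice_thickness_mm", lower = 1e-6)
  assert_scalar_num(slice_gap_mm, "slice_gap_mm", lower = 0)
  assert_scalar_num(grid_size, "grid_size", lower = 16)
  assert_scalar_num(wall_thickness_mm, "wall_thickness_mm", lower = 1e-6)
  assert_scalar_num(trabecula_count, "trabecula_count", lower = 0)
  assert_scalar_num(trabecula_width_mm, "trabecula_width_mm", lower = 1e-6)
  assert_scalar_num(bias_amplitude, "bias_amplitude", lower = 0)
  assert_scalar_num(noise_sigma, "noise_sigma", lower = 0)
  assert_scalar_num(es_scale, "es_scale", lower = 0.1, upper = 1)
  if (length(cavity_semi_axes_mm) != 3L || any(cavity_semi_axes_mm <= 0)) {
    stop("`cavity_semi_axes_mm` must be three positive lengths (a, b, c)", call. = FALSE)
  }
  req <- c("background", "myocardium", "tpm", "blood")
  if (!all(req %in% names(intensity_levels))) {
    stop("`intensity_levels` must name background, myocardium, tpm and blood", call. = FALSE)
  }
  if (anyDuplicated(intensity_levels[req])) {
    stop("tissue intensity levels must be pairwise distinct", call. = FALSE)
  }

  spec <- list(
    n_slices = as.integer(n_slices),
    pixel_spacing_mm = pixel_spacing_mm,
    slice_thickness_mm = slice_thickness_mm,
    slice_gap_mm = slice_gap_mm,
    grid_size = as.integer(grid_size),
    cavity_semi_axes_mm = as.numeric(cavity_semi_axes_mm),
    wall_thickness_mm = wall_thickness_mm,
    trabecula_count = as.integer(trabecula_count),
    trabecula_width_mm = trabecula_width_mm,
    border_class = border_class,
    border_param = border_param,
    intensity_levels = intensity_levels[req],
    bias_amplitude = bias_amplitude,
    noise_sigma = noise_sigma,
    noise_model = noise_model,
    es_scale = es_scale,
    seed = as.integer(seed)
  )
  class(spec) <- "phantom_spec"
  validate_phantom_geometry(spec)
  spec
}

validate_phantom_geometry <- function(spec) {
  a <- spec$cavity_semi_axes_mm[1]; b <- spec$cavity_semi_axes_mm[2]
  c_ax <- spec$cavity_semi_axes_mm[3]
  half_extent_px <- (max(a, b) + spec$wall_thickness_mm) / spec$pixel_spacing_mm
  if (2 * half_extent_px + 8 > spec$grid_size) {
    stop(sprintf(paste0("phantom does not fit: epicardial extent needs %.0f px + 4 px ",
                        "margin per side but grid_size = %d; reduce cavity_semi_axes_mm[%d] ",
                        "or wall_thickness_mm, or enlarge grid_size"),
                 2 * half_extent_px, spec$grid_size, which.max(c(a, b))),
         call. = FALSE)
  }
  spacing <- spec$slice_thickness_mm + spec$slice_gap_mm
  z_last <- (spec$n_slices - 0.5) * spacing
  if (z_last >= c_ax) {
    stop(sprintf(paste0("phantom does not fit: the most apical slice centre sits at ",
                        "%.1f mm but cavity_semi_axes_mm[3] = %.1f mm; reduce n_slices ",
                        "or enlarge cavity_semi_axes_mm[3]"), z_last, c_ax),
         call. = FALSE)
  }
  invisible(spec)
}

#' Geometry record shared by the volumetric routines
#' @param pixel_spacing_mm In-plane pixel size, one value (isotropic) or two.
#' @param slice_thickness_mm Slice thickness (mm).
#' @param slice_gap_mm Inter-slice gap (mm), zero allowed.
#' @return A `slice_geometry` list.
#' @export
slice_geometry <- function(pixel_spacing_mm, slice_thickness_mm = 8, slice_gap_mm = 2) {
  if (length(pixel_spacing_mm) == 1L) pixel_spacing_mm <- rep(pixel_spacing_mm, 2L)
  if (any(pixel_spacing_mm <= 0)) stop("`pixel_spacing_mm` must be positive", call. = FALSE)
  assert_scalar_num(slice_thickness_mm, "slice_thickness_mm", lower = 1e-6)
  assert_scalar_num(slice_gap_mm, "slice_gap_mm", lower = 0)
  structure(list(pixel_spacing_mm = as.numeric(pixel_spacing_mm),
                 slice_thickness_mm = slice_thickness_mm,
                 slice_gap_mm = slice_gap_mm),
            class = "slice_geometry")
}

slice_spacing_mm <- function(geometry) {
  geometry$slice_thickness_mm + geometry$slice_gap_mm
}

# ---- border polygons -------------------------------------------------------

# Closed polygon for each border family, centred at the origin and scaled so
# the maximum vertex radius is exactly 1. Returned as a two-column matrix of
# (x, y) vertices, not repeating the first point.
border_polygon <- function(border_class, border_param, seed = 1L) {
  poly <- switch(border_class,
    smooth = {
      th <- seq(0, 2 * pi, length.out = 721L)[-721L]
      cbind(cos(th), sin(th))
    },
    koch = koch_island_polygon(depth = max(1L, as.integer(border_param))),
    midpoint_displacement = midpoint_displacement_polygon(
      roughness = border_param, seed = seed),
    stop("unknown border_class", call. = FALSE)
  )
  r <- sqrt(rowSums(poly^2))
  poly / max(r)
}

# Triadic Koch island (snowflake): equilateral triangle, each edge replaced by
# four edges of a third the length with an outward-pointing tip. Similarity
# dimension of the limiting curve: log 4 / log 3.
koch_island_polygon <- function(depth = 4L) {
  th <- c(pi / 2, pi / 2 + 2 * pi / 3, pi / 2 + 4 * pi / 3)
  pts <- cbind(cos(th), sin(th))
  for (d in seq_len(depth)) {
    n <- nrow(pts)
    out <- matrix(0, 4L * n, 2L)
    for (i in seq_len(n)) {
      p <- pts[i, ]; q <- pts[if (i == n) 1L else i + 1L, ]
      dvec <- q - p
      tip <- p + dvec / 2 + c(dvec[2], -dvec[1]) * sqrt(3) / 6  # outward for CCW
      out[(4L * i - 3L):(4L * i), ] <- rbind(p, p + dvec / 3, tip, p + 2 * dvec / 3)
    }
    pts <- out
  }
  pts
}

# Rough closed curve: radius function on the circle refined by midpoint
# displacement. `roughness` in (0, 1) scales the displacement decay; larger
# values give more persistent, space-filling borders.
midpoint_displacement_polygon <- function(roughness = 0.5, seed = 1L,
                                          n_points = 1024L) {
  if (roughness <= 0 || roughness >= 1) {
    stop("`border_param` (roughness) must lie in (0, 1) for midpoint_displacement",
         call. = FALSE)
  }
  with_seed_(seed, {
    r <- rep(1, 8L)
    amp <- 0.45 * roughness
    while (length(r) < n_points) {
      n <- length(r)
      mid <- (r + r[c(2:n, 1L)]) / 2 + stats::rnorm(n, 0, amp)
      r2 <- numeric(2L * n)
      r2[seq(1L, 2L * n, 2L)] <- r
      r2[seq(2L, 2L * n, 2L)] <- mid
      r <- r2
      amp <- amp * roughness
    }
    r <- pmin(pmax(r, 0.25), 2)
    th <- seq(0, 2 * pi, length.out = length(r) + 1L)[-(length(r) + 1L)]
    cbind(r * cos(th), r * sin(th))
  })
}

# Mark pixels along a closed polygon outline (dense sampling; yields a
# 1-px-wide 8-connected closed curve). `poly_px` in pixel coordinates.
draw_polygon_border <- function(poly_px, grid_size) {
  n <- nrow(poly_px)
  xs <- numeric(0); ys <- numeric(0)
  for (i in seq_len(n)) {
    p <- poly_px[i, ]; q <- poly_px[if (i == n) 1L else i + 1L, ]
    len <- sqrt(sum((q - p)^2))
    k <- max(2L, ceiling(len / 0.3))
    t <- seq(0, 1, length.out = k)
    xs <- c(xs, p[1] + t * (q[1] - p[1]))
    ys <- c(ys, p[2] + t * (q[2] - p[2]))
  }
  ix <- pmin(pmax(round(xs), 1L), grid_size)
  iy <- pmin(pmax(round(ys), 1L), grid_size)
  m <- matrix(FALSE, grid_size, grid_size)
  m[cbind(ix, iy)] <- TRUE
  m
}

#' Rasterize a closed border of known fractal class
#'
#' Test fixture for the box-counting stage: a 1-px-wide, 8-connected closed
#' curve whose theoretical box-counting dimension is known (`smooth` -> 1,
#' `koch` -> log 4 / log 3 ~ 1.2619) or controllable
#' (`midpoint_displacement`).
#'
#' @inheritParams lv_phantom_spec
#' @param grid_size Image side in pixels; >= 256 required for koch depth >= 3.
#' @param seed Seed for the random border class (ignored otherwise).
#' @return Logical `grid_size` x `grid_size` matrix.
#' @export
rasterize_fractal_border <- function(border_class = c("smooth", "koch", "midpoint_displacement"),
                                     border_param = 4, grid_size = 512, seed = 1L) {
  border_class <- match.arg(border_class)
  assert_scalar_num(grid_size, "grid_size", lower = 64)
  if (border_class == "koch") {
    depth <- max(1L, as.integer(border_param))
    if (depth >= 3L && grid_size < 256) {
      stop("koch borders at depth >= 3 need grid_size >= 256", call. = FALSE)
    }
    side <- 0.40 * grid_size * sqrt(3)      # base triangle edge in px
    if (side / 3^depth < 2) {
      stop(sprintf(paste0("koch features at depth %d would be sub-pixel ",
                          "(segment length %.2f px); use a larger grid_size"),
                   depth, side / 3^depth), call. = FALSE)
    }
  }
  poly <- border_polygon(border_class, border_param, seed)
  centre <- (grid_size + 1) / 2
  poly_px <- poly * (0.40 * grid_size) + centre
  out <- draw_polygon_border(poly_px, as.integer(grid_size))
  # annotate the self-similar regime: box-counting is meaningful only at
  # scales that do not resolve the fixture below its finest constructed
  # feature (a finite-depth koch curve is a polyline at smaller scales)
  attr(out, "finest_feature_px") <- switch(border_class,
    smooth = NA_real_,
    koch = 0.40 * grid_size * sqrt(3) / 3^max(1L, as.integer(border_param)),
    midpoint_displacement = 2 * pi * 0.40 * grid_size / 1024)
  attr(out, "theoretical_fd") <- switch(border_class,
    smooth = 1.0, koch = log(4) / log(3), NA_real_)
  out
}

# ---- LV stack generation ---------------------------------------------------

# In-plane masks for one slice. `a_px`, `b_px`: cavity semi-axes in pixels.
# Returns cavity/epi masks plus the TPM mask rasterized strictly inside the
# endocardial outline.
rasterize_slice_masks <- function(spec, a_px, b_px, wall_px, poly) {
  g <- spec$grid_size
  centre <- (g + 1) / 2
  x <- matrix(seq_len(g) - centre, g, g)
  y <- matrix(seq_len(g) - centre, g, g, byrow = TRUE)

  if (spec$border_class == "smooth") {
    cavity <- (x / a_px)^2 + (y / b_px)^2 <= 1
  } else {
    border <- draw_polygon_border(cbind(poly[, 1] * a_px + centre,
                                        poly[, 2] * b_px + centre), g)
    cavity <- fill_closed_border(border)
  }
  epi <- (x / (a_px + wall_px))^2 + (y / (b_px + wall_px))^2 <= 1

  tpm <- matrix(FALSE, g, g)
  if (spec$trabecula_count > 0) {
    # normalized elliptical radius; TPM confined to r_norm <= 0.95 so that the
    # structures stay strictly inside the endocardial boundary
    u <- x / a_px; v <- y / b_px
    rn <- sqrt(u^2 + v^2)
    half_w_px <- spec$trabecula_width_mm / (2 * spec$pixel_spacing_mm)
    min_ax <- min(a_px, b_px)
    # keep >= 1.5 px of blood between TPM and the endocardial boundary so the
    # structures stay strictly inside it even after rasterization
    r_out <- min(0.95, (min_ax - 1.5 - half_w_px) / min_ax)
    if (min_ax * 0.45 > 2 * half_w_px && r_out > 0.55) {  # skip slices too small to host spokes
      angles <- 2 * pi * (seq_len(spec$trabecula_count) - 1) / spec$trabecula_count
      for (th in angles) {
        # distance (px) from each pixel to the radial segment r_norm in [0.5, 0.95]
        dir <- c(cos(th), sin(th))
        px0 <- dir * c(a_px, b_px) * 0.5
        px1 <- dir * c(a_px, b_px) * r_out
        dvec <- px1 - px0
        L2 <- sum(dvec^2)
        t <- ((x - px0[1]) * dvec[1] + (y - px0[2]) * dvec[2]) / L2
        t <- pmin(pmax(t, 0), 1)
        dist <- sqrt((x - (px0[1] + t * dvec[1]))^2 + (y - (px0[2] + t * dvec[2]))^2)
        tpm <- tpm | (dist <= half_w_px & rn <= r_out)
      }
      # two papillary disks
      pap_r_px <- 1.8 * half_w_px
      for (th in c(110, 250) * pi / 180) {
        cx <- cos(th) * a_px * 0.45; cy <- sin(th) * b_px * 0.45
        tpm <- tpm | (((x - cx)^2 + (y - cy)^2) <= pap_r_px^2 & rn <= r_out)
      }
      tpm <- tpm & cavity
    }
  }
  list(cavity = cavity, epi = epi, tpm = tpm)
}

polynomial_bias_field <- function(grid_size, amplitude, seed) {
  if (amplitude <= 0) return(matrix(1, grid_size, grid_size))
  co <- with_seed_(seed + 1000L, stats::runif(5, -1, 1))
  t <- seq(-1, 1, length.out = grid_size)
  X <- matrix(t, grid_size, grid_size)
  Y <- matrix(t, grid_size, grid_size, byrow = TRUE)
  p <- co[1] * X + co[2] * Y + co[3] * X^2 + co[4] * X * Y + co[5] * Y^2
  # normalize over the central half of the grid (where the LV sits), so the
  # amplitude describes the bias the imaged organ actually experiences
  # rather than a corner extreme
  ctr <- abs(X) <= 0.5 & abs(Y) <= 0.5
  1 + amplitude * p / max(abs(p[ctr]))
}

#' Generate a synthetic short-axis LV image stack with ground truth
#'
#' Produces a two-phase (end-diastole, end-systole) multi-slice stack with the
#' specified tissue intensities, a multiplicative polynomial bias field and
#' additive noise, together with noise-free ground-truth contours, the TPM
#' mask and a `phantom_truth` ledger (volumes, per-slice TPM areas, TPM mass
#' at 1.05 g/cc, theoretical fractal class). Identical seeds give bit-identical
#' output.
#'
#' @param spec A [lv_phantom_spec()].
#' @return A list of class `lv_phantom` with elements `stack` (phases `ED`,
#'   `ES`: grid x grid x n_slices arrays; `geometry`), `contours` (per phase:
#'   `endo`, `epi` logical arrays), `tpm_mask` (ED-phase logical array) and
#'   `truth` (class `phantom_truth`).
#' @export
generate_lv_stack <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_geometry(spec)
  g <- spec$grid_size
  n <- spec$n_slices
  px <- spec$pixel_spacing_mm
  sp <- spec$slice_thickness_mm + spec$slice_gap_mm
  axes <- spec$cavity_semi_axes_mm
  lv <- spec$intensity_levels

  poly <- if (spec$border_class == "smooth") NULL else
    border_polygon(spec$border_class, spec$border_param, spec$seed)

  phases <- list(ED = 1, ES = spec$es_scale)
  imgs <- list(); endo <- list(); epi <- list()
  tpm_ed <- array(FALSE, c(g, g, n))
  tpm_area <- numeric(n)
  cav_vol <- c(ED = 0, ES = 0); wall_vol <- c(ED = 0, ES = 0)

  bias <- polynomial_bias_field(g, spec$bias_amplitude, spec$seed)

  for (ph in names(phases)) {
    f <- phases[[ph]]
    img <- array(lv[["background"]], c(g, g, n))
    endo_m <- array(FALSE, c(g, g, n)); epi_m <- array(FALSE, c(g, g, n))
    for (i in seq_len(n)) {
      z <- (i - 0.5) * sp
      s <- sqrt(max(0, 1 - (z / axes[3])^2))
      masks <- rasterize_slice_masks(spec,
                                     a_px = axes[1] * s * f / px,
                                     b_px = axes[2] * s * f / px,
                                     wall_px = spec$wall_thickness_mm / px,
                                     poly = poly)
      sl <- matrix(lv[["background"]], g, g)
      sl[masks$epi] <- lv[["myocardium"]]
      sl[masks$cavity] <- lv[["blood"]]
      sl[masks$tpm] <- lv[["tpm"]]
      img[, , i] <- sl
      endo_m[, , i] <- masks$cavity
      epi_m[, , i] <- masks$epi
      cav_vol[ph] <- cav_vol[ph] + sum(masks$cavity) * px^2 * sp
      wall_vol[ph] <- wall_vol[ph] + sum(masks$epi & !masks$cavity) * px^2 * sp
      if (ph == "ED") {
        tpm_ed[, , i] <- masks$tpm
        tpm_area[i] <- sum(masks$tpm) * px^2
      }
    }
    imgs[[ph]] <- img
    endo[[ph]] <- endo_m
    epi[[ph]] <- epi_m
  }

  # corruption: one bias field, noise seeded once across both phases
  clean <- imgs
  imgs <- with_seed_(spec$seed, {
    lapply(clean, function(arr) {
      for (i in seq_len(dim(arr)[3])) arr[, , i] <- arr[, , i] * bias
      if (spec$noise_sigma > 0) {
        if (spec$noise_model == "gaussian") {
          arr <- arr + array(stats::rnorm(length(arr), 0, spec$noise_sigma), dim(arr))
        } else {
          n1 <- array(stats::rnorm(length(arr), 0, spec$noise_sigma), dim(arr))
          n2 <- array(stats::rnorm(length(arr), 0, spec$noise_sigma), dim(arr))
          arr <- sqrt((arr + n1)^2 + n2^2)
        }
      }
      arr
    })
  })

  truth <- structure(list(
    true_cavity_volume_ml = unname(cav_vol["ED"]) / 1000,
    true_cavity_es_volume_ml = unname(cav_vol["ES"]) / 1000,
    true_wall_volume_ml = unname(wall_vol["ED"]) / 1000,
    true_tpm_area_mm2_per_slice = tpm_area,
    true_tpm_mass_g = sum(tpm_area) * sp * 1.05 / 1000,
    true_ecv_fraction = NA_real_,
    theoretical_fd = switch(spec$border_class, smooth = 1.0,
                            koch = log(4) / log(3), NA_real_),
    analytic_cavity_volume_ml = if (spec$border_class == "smooth") {
      zmax <- n * sp
      pi * axes[1] * axes[2] * (zmax - zmax^3 / (3 * axes[3]^2)) / 1000
    } else NA_real_,
    bias_field = bias,
    seed = spec$seed
  ), class = "phantom_truth")

  structure(list(
    stack = structure(list(phases = imgs,
                           geometry = slice_geometry(px, spec$slice_thickness_mm,
                                                     spec$slice_gap_mm),
                           spec = spec),
                      class = "lv_stack"),
    contours = list(ED = list(endo = endo$ED, epi = epi$ED),
                    ES = list(endo = endo$ES, epi = epi$ES)),
    tpm_mask = tpm_ed,
    truth = truth
  ), class = "lv_phantom")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("LV phantom spec: %d slices, %d px grid, %.2f mm px, cavity (%s) mm\n",
              x$n_slices, x$grid_size, x$pixel_spacing_mm,
              paste(x$cavity_semi_axes_mm, collapse = ", ")))
  cat(sprintf("  border %s, %d trabeculae, bias %.2f, noise %.1f (%s), seed %d\n",
              x$border_class, x$trabecula_count, x$bias_amplitude,
              x$noise_sigma, x$noise_model, x$seed))
  invisible(x)
}
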