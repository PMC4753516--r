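# LV volumetrics and mass from contours and TPM masks.
#
# Volumes use the disc-summation (Simpson) convention: per-slice contoured
# area times the contiguous slice spacing (thickness + gap), summed over the
# stack. Myocardium density is 1.05 g/cc throughout.

MYOCARDIUM_DENSITY_G_PER_CC <- 1.05

#' Area enclosed by a binary contour mask
#'
#' @param mask Logical (or 0/1) matrix.
#' @param pixel_spacing_mm Pixel size, one value (isotropic) or two (dx, dy).
#' @return Area in mm^2 (0 for an empty mask).
#' @export
contour_area <- function(mask, pixel_spacing_mm) {
  mask <- as_binary_matrix(mask)
  if (length(pixel_spacing_mm) == 1L) pixel_spacing_mm <- rep(pixel_spacing_mm, 2L)
  if (any(pixel_spacing_mm <= 0)) stop("`pixel_spacing_mm` must be positive", call. = FALSE)
  sum(mask) * prod(pixel_spacing_mm)
}

#' Chamber volume by disc summation (Simpson's rule, cardiac convention)
#'
#' @param areas_mm2 Per-slice contoured areas (mm^2), base to apex.
#' @param geometry A [slice_geometry()]; slice spacing is thickness + gap.
#' @return Volume in ml.
#' @export
simpson_volume <- function(areas_mm2, geometry) {
  stopifnot(inherits(geometry, "slice_geometry"))
  if (length(areas_mm2) < 2L) {
    stop("disc summation needs at least 2 slices", call. = FALSE)
  }
  if (any(!is.finite(areas_mm2)) || any(areas_mm2 < 0)) {
    stop("slice areas must be finite and non-negative", call. = FALSE)
  }
  sum(areas_mm2) * slice_spacing_mm(geometry) / 1000
}

#' Left-ventricular mass from epicardial and endocardial volumes
#'
#' LV mass is the end-diastolic epicardial-minus-endocardial (cavity) volume
#' times the myocardial density, 1.05 g/cc.
#'
#' @param epicardial_ed_volume_ml Epicardial volume at end-diastole (ml).
#' @param lvedv_ml End-diastolic cavity volume (ml).
#' @return Mass in grams.
#' @export
lv_mass <- function(epicardial_ed_volume_ml, lvedv_ml) {
  assert_scalar_num(epicardial_ed_volume_ml, "epicardial_ed_volume_ml", lower = 0)
  assert_scalar_num(lvedv_ml, "lvedv_ml", lower = 0)
  if (epicardial_ed_volume_ml < lvedv_ml) {
    stop("contour inversion: epicardial volume is smaller than the cavity volume",
         call. = FALSE)
  }
  (epicardial_ed_volume_ml - lvedv_ml) * MYOCARDIUM_DENSITY_G_PER_CC
}

#' Trabeculae and papillary muscle mass from per-slice TPM masks
#'
#' Sums per-slice TPM area times the contiguous slice spacing and converts to
#' grams at 1.05 g/cc. If endocardial masks are supplied, every TPM mask must
#' lie inside its endocardial mask.
#'
#' @param tpm_masks List of logical matrices (or a logical 3D array), base to
#'   apex; alternatively a numeric vector of per-slice TPM areas in mm^2.
#' @param geometry A [slice_geometry()].
#' @param endo_masks Optional list/array of endocardial masks for the
#'   containment check.
#' @return Mass in grams.
#' @export
tpm_mass <- function(tpm_masks, geometry, endo_masks = NULL) {
  stopifnot(inherits(geometry, "slice_geometry"))
  if (is.numeric(tpm_masks) && is.null(dim(tpm_masks))) {
    areas <- tpm_masks
  } else {
    if (is.array(tpm_masks) && length(dim(tpm_masks)) == 3L) {
      tpm_masks <- lapply(seq_len(dim(tpm_masks)[3]), function(i) tpm_masks[, , i])
    }
    if (is.array(endo_masks) && length(dim(endo_masks)) == 3L) {
      endo_masks <- lapply(seq_len(dim(endo_masks)[3]), function(i) endo_masks[, , i])
    }
    px <- geometry$pixel_spacing_mm
    areas <- vapply(seq_along(tpm_masks), function(i) {
      m <- as_binary_matrix(tpm_masks[[i]], sprintf("tpm_masks[[%d]]", i))
      if (!is.null(endo_masks)) {
        e <- as_binary_matrix(endo_masks[[i]])
        if (any(m & !e)) {
          stop(sprintf("TPM mask extends outside the endocardium on slice %d", i),
               call. = FALSE)
        }
      }
      sum(m) * prod(px)
    }, numeric(1))
  }
  sum(areas) * slice_spacing_mm(geometry) * MYOCARDIUM_DENSITY_G_PER_CC / 1000
}

#' Body surface area
#'
#' @param height_cm,weight_kg Subject height (cm) and weight (kg).
#' @param formula `"mosteller"` (default), sqrt(h * w / 3600), or `"dubois"`.
#' @return BSA in m^2.
#' @export
body_surface_area <- function(height_cm, weight_kg,
                              formula = c("mosteller", "dubois")) {
  formula <- match.arg(formula)
  assert_scalar_num(height_cm, "height_cm", lower = 1e-6)
  assert_scalar_num(weight_kg, "weight_kg", lower = 1e-6)
  switch(formula,
         mosteller = sqrt(height_cm * weight_kg / 3600),
         dubois = 0.007184 * height_cm^0.725 * weight_kg^0.425)
}

#' Assemble the per-subject quantification row
#'
#' Computes LVEF, BSA (Mosteller by default), the BSA-indexed volumes and
#' masses, and the TPM-to-LV-mass percentage, returning one tidy row.
#'
#' @param lvedv_ml,lvesv_ml End-diastolic and end-systolic cavity volumes (ml).
#' @param lvm_g LV mass (g).
#' @param tpm_mass_g TPM mass (g).
#' @param height_cm,weight_kg Subject body size for BSA indexing.
#' @param bsa_formula Passed to [body_surface_area()].
#' @return A one-row tibble: `lvedv_ml`, `lvesv_ml`, `lvef_pct`, `lvm_g`,
#'   `tpm_mass_g`, `bsa_m2`, `lvedvi_ml_m2`, `lvesvi_ml_m2`, `lvmi_g_m2`,
#'   `tpmi_g_m2`, `tpm_lvm_ratio_pct`.
#' @export
index_and_ratios <- function(lvedv_ml, lvesv_ml, lvm_g, tpm_mass_g,
                             height_cm, weight_kg,
                             bsa_formula = c("mosteller", "dubois")) {
  assert_scalar_num(lvedv_ml, "lvedv_ml", lower = 0)
  assert_scalar_num(lvesv_ml, "lvesv_ml", lower = 0)
  assert_scalar_num(lvm_g, "lvm_g", lower = 0)
  assert_scalar_num(tpm_mass_g, "tpm_mass_g", lower = 0)
  if (lvedv_ml <= 0) stop("LVEDV is zero: ejection fraction undefined", call. = FALSE)
  if (lvesv_ml > lvedv_ml) {
    stop("LVESV exceeds LVEDV; check end-diastole/end-systole assignment",
         call. = FALSE)
  }
  bsa <- body_surface_area(height_cm, weight_kg, match.arg(bsa_formula))
  tibble::tibble(
    lvedv_ml = lvedv_ml,
    lvesv_ml = lvesv_ml,
    lvef_pct = 100 * (lvedv_ml - lvesv_ml) / lvedv_ml,
    lvm_g = lvm_g,
    tpm_mass_g = tpm_mass_g,
    bsa_m2 = bsa,
    lvedvi_ml_m2 = lvedv_ml / bsa,
    lvesvi_ml_m2 = lvesv_ml / bsa,
    lvmi_g_m2 = lvm_g / bsa,
    tpmi_g_m2 = tpm_mass_g / bsa,
    tpm_lvm_ratio_pct = if (lvm_g > 0) 100 * tpm_mass_g / lvm_g else NA_real_
  )
}

#' Quantify one subject from segmented masks
#'
#' Runs the full volumetric chain on per-phase endocardial/epicardial masks
#' and ED-phase TPM masks: disc-summation volumes per phase, ED/ES selection
#' as the maximal/minimal cavity volume, LV mass from the end-diastolic
#' epicardial and cavity volumes, TPM mass, then BSA indexing.
#'
#' @param endo_masks,epi_masks Named lists of per-phase logical 3D arrays (or
#'   lists of matrices), e.g. `list(ED = ..., ES = ...)`.
#' @param tpm_masks TPM masks for the end-diastolic phase.
#' @param geometry A [slice_geometry()].
#' @inheritParams index_and_ratios
#' @return One-row tibble, as [index_and_ratios()].
#' @export
quantify_subject <- function(endo_masks, epi_masks, tpm_masks, geometry,
                             height_cm = 170, weight_kg = 70,
                             bsa_formula = c("mosteller", "dubois")) {
  stopifnot(inherits(geometry, "slice_geometry"))
  px <- geometry$pixel_spacing_mm
  phase_vol <- function(masks) {
    if (is.array(masks) && length(dim(masks)) == 3L) {
      masks <- lapply(seq_len(dim(masks)[3]), function(i) masks[, , i])
    }
    simpson_volume(vapply(masks, contour_area, numeric(1),
                          pixel_spacing_mm = px), geometry)
  }
  cav <- vapply(endo_masks, phase_vol, numeric(1))
  ed_phase <- names(cav)[which.max(cav)]
  lvedv <- max(cav); lvesv <- min(cav)
  epi_ed <- phase_vol(epi_masks[[ed_phase]])
  lvm <- lv_mass(epi_ed, lvedv)
  tpm_g <- tpm_mass(tpm_masks, geometry, endo_masks = endo_masks[[ed_phase]])
  index_and_ratios(lvedv, lvesv, lvm, tpm_g, height_cm, weight_kg,
                   bsa_formula = match.arg(bsa_formula))
}
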