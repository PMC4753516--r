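# NIfTI/PNG/CSV/JSON I/O, pipeline configuration, and the end-to-end driver
# tying phantom generation, segmentation, quantification, fractal analysis,
# ECV and cohort statistics together.

#' Write an image stack as NIfTI-1 with millimetre spacings
#'
#' The slice axis is the third axis; the third pixdim stores the contiguous
#' slice spacing (thickness + gap).
#'
#' @param data 3D numeric/logical array (x, y, slice) or an `lv_stack`
#'   (its end-diastolic phase is written).
#' @param path Output `.nii` / `.nii.gz` path.
#' @param geometry A [slice_geometry()]; taken from the stack if omitted.
#' @return `path`, invisibly.
#' @export
write_stack <- function(data, path, geometry = NULL) {
  if (inherits(data, "lv_stack")) {
    geometry <- geometry %||% data$geometry
    data <- data$phases$ED
  }
  if (is.null(geometry)) stop("`geometry` is required for plain arrays", call. = FALSE)
  stopifnot(inherits(geometry, "slice_geometry"))
  arr <- array(as.numeric(data), dim(data))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(geometry$pixel_spacing_mm[1],
                           geometry$pixel_spacing_mm[2],
                           slice_spacing_mm(geometry))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 image stack
#'
#' @param path NIfTI file.
#' @param geometry Optional explicit [slice_geometry()] override; required
#'   when the file header carries no usable pixel spacing.
#' @return List with `data` (3D array) and `geometry` (the slice spacing is
#'   returned as thickness with zero gap, since NIfTI stores only the
#'   contiguous spacing).
#' @export
read_stack <- function(path, geometry = NULL) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  if (is.null(geometry)) {
    pd <- RNifti::pixdim(img)
    if (length(pd) < 3 || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0) ||
        all(pd[1:3] == 1)) {
      if (all(pd[1:3] == 1)) {
        # pixdim of exactly (1,1,1) is the NIfTI default for headers written
        # without geometry; demand an explicit override rather than guess
        stop("file carries no pixel-spacing metadata; pass `geometry` explicitly",
             call. = FALSE)
      }
      stop("file carries invalid pixel-spacing metadata; pass `geometry` explicitly",
           call. = FALSE)
    }
    geometry <- slice_geometry(pd[1:2], pd[3], 0)
  }
  list(data = arr, geometry = geometry)
}

#' Read a stack of PNG masks/images as a 3D array (test fixtures)
#'
#' @param paths PNG files, base to apex.
#' @param geometry User-supplied [slice_geometry()] (PNG has no spacing).
#' @return List with `data` and `geometry`.
#' @export
read_stack_png <- function(paths, geometry) {
  stopifnot(inherits(geometry, "slice_geometry"))
  slices <- lapply(paths, function(p) {
    m <- png::readPNG(p)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    t(m)[, rev(seq_len(nrow(m))), drop = FALSE]  # image row order -> matrix
  })
  list(data = array(unlist(slices), c(dim(slices[[1]]), length(slices))),
       geometry = geometry)
}

#' Write phantom ground truth as a JSON side-car
#' @param truth A `phantom_truth` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_phantom_truth <- function(truth, path) {
  stopifnot(inherits(truth, "phantom_truth"))
  x <- unclass(truth)
  x$bias_field <- NULL  # image-sized; regenerate from the seed instead
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# ---- configuration ---------------------------------------------------------

default_pipeline_config <- function() {
  list(
    seed = 1L,
    output_dir = NULL,
    log_level = "info",
    phantom = list(
      n_subjects = 10L, n_slices = 8L, grid_size = 96L, pixel_spacing_mm = 1.7,
      slice_thickness_mm = 8, slice_gap_mm = 2, noise_sigma = 50,
      bias_amplitude = 0.15, trabecula_count = 6, trabecula_width_mm = 3.5,
      es_scale = 0.65
    ),
    levelset = list(
      lambda_inside = 1, lambda_outside = 1, length_weight = 0.05,
      time_step = 10, max_iterations = 300L, convergence_tol = 1e-4,
      reinit_interval = 20L, bias_basis_order = 2L, bias_kernel_sigma_px = 0
    ),
    fractal = list(offset_mode = "fixed"),
    ecv = list(
      t1_pre_blood_ms = 1800, t1_post_blood_ms = 350, t1_pre_myo_ms = 1200,
      noise_sigma_ms = 20, n_slices = 5L
    ),
    stats = list(alpha = 0.05, age_bands = c(60, 75), lvef_bands = c(35, 50))
  )
}

check_config_keys <- function(cfg, template, path = "") {
  unknown <- setdiff(names(cfg), names(template))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "), call. = FALSE)
  }
  for (k in names(cfg)) {
    if (is.list(template[[k]]) && !is.null(names(template[[k]]))) {
      if (!is.list(cfg[[k]])) next
      check_config_keys(cfg[[k]], template[[k]], paste0(path, k, "$"))
    }
  }
  invisible(TRUE)
}

#' Build a validated pipeline configuration
#'
#' Named-list overrides are merged onto the defaults section by section;
#' unknown keys are rejected. The configuration round-trips losslessly
#' through JSON ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param ... Top-level overrides (`seed`, `output_dir`, `log_level`) or
#'   section lists (`phantom`, `levelset`, `fractal`, `ecv`, `stats`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  overrides <- list(...)
  cfg <- default_pipeline_config()
  check_config_keys(overrides, cfg)
  for (k in names(overrides)) {
    if (is.list(cfg[[k]]) && !is.null(names(cfg[[k]]))) {
      check_config_keys(overrides[[k]], cfg[[k]], paste0(k, "$"))
      cfg[[k]][names(overrides[[k]])] <- overrides[[k]]
    } else {
      cfg[k] <- list(overrides[[k]])   # keeps NULL values as NULL entries
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

# coerce a value read from JSON to the storage type of its template default
coerce_like <- function(template, value) {
  if (is.list(template) && !is.null(names(template))) {
    for (k in intersect(names(value), names(template))) {
      value[k] <- list(coerce_like(template[[k]], value[[k]]))
    }
    return(value)
  }
  if (is.null(value) || is.null(template)) return(value)
  mode_fun <- switch(class(template)[1],
                     integer = as.integer, numeric = as.numeric,
                     character = as.character, logical = as.logical,
                     identity)
  mode_fun(value)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- coerce_like(default_pipeline_config(), raw)
  do.call(pipeline_config, raw)
}

# ---- end-to-end driver -----------------------------------------------------

subject_params_from_config <- function(cfg, i) {
  p <- cfg$phantom
  with_seed_(cfg$seed + 17L * i, {
    jit <- function(x, f) x * stats::runif(1, 1 - f, 1 + f)
    spec <- lv_phantom_spec(
      n_slices = p$n_slices, pixel_spacing_mm = p$pixel_spacing_mm,
      slice_thickness_mm = p$slice_thickness_mm, slice_gap_mm = p$slice_gap_mm,
      grid_size = p$grid_size,
      cavity_semi_axes_mm = c(jit(24, 0.08), jit(22, 0.08), jit(88, 0.05)),
      wall_thickness_mm = jit(9, 0.1),
      trabecula_count = max(3L, p$trabecula_count + sample(-2:2, 1)),
      trabecula_width_mm = jit(p$trabecula_width_mm, 0.1),
      bias_amplitude = p$bias_amplitude, noise_sigma = p$noise_sigma,
      es_scale = min(0.95, max(0.4, jit(p$es_scale, 0.08))),
      seed = cfg$seed + 1000L + i
    )
    list(
      spec = spec,
      height_cm = round(stats::runif(1, 150, 185)),
      weight_kg = round(stats::runif(1, 50, 95)),
      age_years = round(stats::runif(1, 45, 85)),
      gender = sample(c("male", "female"), 1),
      htn = stats::runif(1) < 0.8, dm = stats::runif(1) < 0.3,
      etiology = sample(c("CAD", "non-CAD"), 1),
      hematocrit = round(stats::runif(1, 0.36, 0.48), 3),
      target_ecv = round(stats::runif(1, 0.25, 0.34), 3),
      lge_fraction = if (stats::runif(1) < 0.4) round(stats::runif(1, 0.1, 0.4), 2) else 0
    )
  })
}

run_stage <- function(stage, subject_id, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline aborted at stage `%s` for subject `%s`: %s",
                 stage, subject_id, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full phantom-cohort analysis pipeline
#'
#' Generates one phantom per subject, segments contours and TPM, quantifies
#' volumes/masses, extracts the endocardial border and its fractal
#' dimension, computes ECV from a matched T1 phantom, and runs the cohort
#' statistics on the assembled table. Identical configuration and seed give
#' identical outputs. If `config$output_dir` is set, `results.csv` and
#' `comparisons.csv` are written with a provenance header (config hash and
#' seed).
#'
#' @param config A [pipeline_config()].
#' @return List with `results` (per-subject tibble), `comparisons` (list of
#'   `group_comparison`), `regression` (a `tpm_regression` or NULL when the
#'   cohort is too small), `config`, `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  # provenance hash covers the analysis parameters, not output routing
  hashable <- unclass(config)
  hashable$output_dir <- NULL
  hashable$log_level <- NULL
  cfg_hash <- rlang::hash(hashable)
  n <- config$phantom$n_subjects
  lsp <- do.call(level_set_params, config$levelset)
  groups <- rep(GROUP_LEVELS, length.out = n)

  rows <- purrr::map_dfr(seq_len(n), function(i) {
    id <- sprintf("P%03d", i)
    sp <- subject_params_from_config(config, i)
    ph <- run_stage("phantom", id, generate_lv_stack(sp$spec))
    geom <- ph$stack$geometry
    nz <- sp$spec$n_slices

    seg <- run_stage("segment", id, {
      per_phase <- lapply(c(ED = "ED", ES = "ES"), function(phn) {
        arr <- ph$stack$phases[[phn]]
        endo <- array(FALSE, dim(arr)); epi <- array(FALSE, dim(arr))
        for (s in seq_len(nz)) {
          ct <- detect_epi_endo_contours(arr[, , s], sp$spec$pixel_spacing_mm)
          endo[, , s] <- ct$endo_mask; epi[, , s] <- ct$epi_mask
        }
        list(endo = endo, epi = epi)
      })
      tpm <- array(FALSE, dim(ph$stack$phases$ED))
      for (s in seq_len(nz)) {
        r <- suppressWarnings(
          segment_tpm(ph$stack$phases$ED[, , s], per_phase$ED$endo[, , s], lsp))
        tpm[, , s] <- r$mask
      }
      list(per_phase = per_phase, tpm = tpm)
    })

    quant <- run_stage("quantify", id,
      quantify_subject(
        endo_masks = list(ED = seg$per_phase$ED$endo, ES = seg$per_phase$ES$endo),
        epi_masks = list(ED = seg$per_phase$ED$epi, ES = seg$per_phase$ES$epi),
        tpm_masks = seg$tpm, geometry = geom,
        height_cm = sp$height_cm, weight_kg = sp$weight_kg))

    fd_res <- run_stage("fd", id, {
      borders <- lapply(seq_len(nz), function(s) {
        suppressWarnings(extract_endocardial_border(
          ph$stack$phases$ED[, , s], seg$per_phase$ED$epi[, , s], lsp))$border
      })
      fd_stack(borders, offset_mode = config$fractal$offset_mode)
    })

    ecv_res <- run_stage("ecv", id, {
      t1spec <- t1_phantom_spec(
        t1_pre_blood_ms = config$ecv$t1_pre_blood_ms,
        t1_post_blood_ms = config$ecv$t1_post_blood_ms,
        t1_pre_myo_ms = config$ecv$t1_pre_myo_ms,
        hematocrit = sp$hematocrit, target_ecv = sp$target_ecv,
        noise_sigma_ms = config$ecv$noise_sigma_ms,
        lge_fraction = sp$lge_fraction, seed = cfg_seed_offset(config$seed, i))
      ecv_subject(generate_t1_pair(t1spec, sp$spec,
                                   n_slices = config$ecv$n_slices))
    })

    dplyr::bind_cols(
      tibble::tibble(id = id, group = groups[i], age_years = sp$age_years,
                     gender = sp$gender, htn = sp$htn, dm = sp$dm,
                     etiology = sp$etiology, lge = sp$lge_fraction > 0,
                     hematocrit = sp$hematocrit),
      quant,
      tibble::tibble(
        ecv_pct = attr(ecv_res, "subject_ecv_pct"),
        fd = attr(fd_res, "max_apical_fd"),
        true_tpm_mass_g = ph$truth$true_tpm_mass_g,
        true_lvedv_ml = ph$truth$true_cavity_volume_ml,
        true_ecv_pct = 100 * sp$target_ecv)
    )
  })

  results <- rows |>
    dplyr::rename(lvmi = lvmi_g_m2, lvedvi = lvedvi_ml_m2, lvef = lvef_pct,
                  tpmi = tpmi_g_m2, tpm_lvm_ratio = tpm_lvm_ratio_pct)

  comparisons <- NULL
  if (all(tabulate(factor(results$group, levels = GROUP_LEVELS)) >= 3L)) {
    comparisons <- lapply(c("tpmi", "tpm_lvm_ratio", "fd", "ecv_pct"),
                          function(v) compare_groups(results, v))
    names(comparisons) <- c("tpmi", "tpm_lvm_ratio", "fd", "ecv_pct")
  }
  regression <- NULL
  if (nrow(results) >= 60L) {
    regression <- fit_outcome_model(results, "tpmi",
                                    age_bands = config$stats$age_bands,
                                    lvef_bands = config$stats$lvef_bands,
                                    alpha = config$stats$alpha)
  }

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- sprintf("# trabeculr pipeline | config_hash=%s | seed=%d",
                   cfg_hash, config$seed)
    res_path <- file.path(config$output_dir, "results.csv")
    writeLines(hdr, res_path)
    suppressWarnings(utils::write.table(results, res_path, sep = ",",
                                        row.names = FALSE, append = TRUE))
    if (!is.null(comparisons)) {
      cmp_tbl <- purrr::map_dfr(comparisons, glance)
      cmp_path <- file.path(config$output_dir, "comparisons.csv")
      writeLines(hdr, cmp_path)
      suppressWarnings(utils::write.table(cmp_tbl, cmp_path, sep = ",",
                                          row.names = FALSE, append = TRUE))
    }
  }

  list(results = results, comparisons = comparisons, regression = regression,
       config = config, config_hash = cfg_hash)
}

# subject-level seed derived from the global seed, kept within 32-bit range
cfg_seed_offset <- function(seed, i) {
  as.integer((as.numeric(seed) + 104729 * i) %% .Machine$integer.max)
}
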