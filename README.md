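# trabeculr

Quantification of left-ventricular (LV) trabeculation from short-axis
cardiac MR, for imaging scientists studying endocardial remodeling in heart
failure.

During ventricular remodeling the trabecular layer changes along with
chamber size and function, and three quantitative markers capture it:

* **TPM mass** — the mass of trabeculae and papillary muscle inside the
  smooth endocardial outline, segmented by a region-based level set driven
  only by intensities inside the endocardium, and its ratio to LV mass
  (TPMm/LVM, %);
* **fractal dimension (FD)** — the box-counting dimension of the binary
  endocardial border (extracted by a level set with interleaved bias-field
  correction): FD = −slope of ln *N(s)* on ln *s*, summarized per subject
  as the maximal FD over the apical half of the stack;
* **extracellular volume fraction (ECV)** — diffuse-fibrosis marker from
  paired pre/post-contrast T1 maps,
  ECV = (ΔR1<sub>myo</sub>/ΔR1<sub>blood</sub>) × (1 − hematocrit) with
  ΔR1 = 1/T1<sub>post</sub> − 1/T1<sub>pre</sub>, averaged over slices
  after excluding late-gadolinium-enhanced myocardium.

Around these sit standard LV volumetrics (disc-summation Simpson volumes,
ejection fraction, LV mass at 1.05 g/cc, BSA indexing) and the cohort
statistics that relate the markers to covariates: Kruskal–Wallis /
Mann–Whitney group comparisons and tertile-coded multiple linear regression
with a dual (univariate **and** multivariate) significance rule.

Patient images of this kind are not publicly distributable, so the package
includes a synthetic phantom generator with exact ground truth — ellipsoidal
cavities with an analytic volume, trabecular spokes of recorded area,
borders of known fractal class (including a Koch island with theoretical
FD = log 4/log 3), T1 pairs solved to match a chosen ECV, and cohort tables
with planted effects — making every stage testable end to end.

## Worked example

Generate a noisy, bias-corrupted phantom, segment the TPM on one slice, and
compare against the generator's truth:

```r
library(trabeculr)

spec <- lv_phantom_spec(trabecula_count = 6, noise_sigma = 50,
                        bias_amplitude = 0.15, seed = 1)
ph  <- generate_lv_stack(spec)
ct  <- detect_epi_endo_contours(ph$stack$phases$ED[, , 3], spec$pixel_spacing_mm)
seg <- segment_tpm(ph$stack$phases$ED[, , 3], ct$endo_mask)
seg
#> level-set segmentation: 117 px in mask, 13 iterations, converged
dice(seg$mask, ph$tpm_mask[, , 3])
#> [1] 0.987
```

The full pipeline over a small phantom cohort returns one tidy row per
subject:

```r
res <- run_pipeline(pipeline_config(phantom = list(n_subjects = 6L), seed = 42L))
dplyr::select(res$results, id, group, lvedv_ml, lvef, lvm_g,
              tpm_mass_g, tpm_lvm_ratio, fd, ecv_pct)
#> # A tibble: 6 × 9
#>   id    group  lvedv_ml  lvef lvm_g tpm_mass_g tpm_lvm_ratio    fd ecv_pct
#>   <chr> <chr>     <dbl> <dbl> <dbl>      <dbl>         <dbl> <dbl>   <dbl>
#> 1 P001  SHF       106.   53.1 103.        14.0          13.6  1.42    30.5
#> 2 P002  HFpEF      98.8  61.7 116.        12.5          10.8  1.58    30.2
#> 3 P003  non-HF     96.9  57.5 108.        20.9          19.4  1.52    28.3
#> 4 P004  SHF       113.   60.6 121.        18.9          15.6  1.50    29.4
#> 5 P005  HFpEF      97.8  60.2 106.        15.8          15.0  1.51    28.4
#> 6 P006  non-HF     93.8  56.1  95.3       17.2          18.1  1.47    25.5
```

`lvedv_ml` is the end-diastolic cavity volume, `lvm_g` the LV mass,
`tpm_mass_g` the segmented TPM mass (each subject's value lands within the
±10% recovery tolerance of its generator truth), `fd` the maximal apical
fractal dimension and `ecv_pct` the LGE-excluded, slice-averaged ECV.
The ECV chain is an exact inverse of its generator at zero noise:

```r
pair <- generate_t1_pair(t1_phantom_spec(target_ecv = 0.30, hematocrit = 0.42))
ecv_subject(pair)
#> # A tibble: 5 × 4
#>   slice ecv_pct included reason
#> 1     1      30 TRUE     NA
#> ...
#> subject ECV: 30.00% (mean of 5 included slices)
```

Result objects have `tidy()`, `glance()` and `autoplot()` methods
(`fd_stack()` results, `ecv_subject()` results, `fit_outcome_model()` fits),
and `compare_groups()` / `fit_outcome_model()` produce the median-IQR and
coefficient-CI tables of a standard cohort analysis.

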