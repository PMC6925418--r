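#' Extraction-parameter grid
#'
#' The three extraction parameters whose Cartesian product defines the
#' texture-feature combinations: isotropic voxel size, quantization
#' algorithm and number of grey levels. The default 4 x 3 x 4 grid gives 48
#' combinations, hence 48 x 43 = 2064 textural features plus 4 geometric
#' features = 2068 per VOI.
#'
#' @param scales_mm isotropic voxel sizes, mm.
#' @param algorithms quantization algorithms (subset of `Equal`, `Uniform`,
#'   `Lloyd`).
#' @param gray_levels numbers of grey levels.
#' @return An `extraction_grid` object.
#' @export
extraction_grid <- function(scales_mm = c(1, 2, 3, 4),
                            algorithms = c("Equal", "Uniform", "Lloyd"),
                            gray_levels = c(8, 16, 32, 64)) {
  algorithms <- match.arg(algorithms, c("Equal", "Uniform", "Lloyd"),
                          several.ok = TRUE)
  stopifnot(all(scales_mm > 0), all(gray_levels >= 2))
  structure(list(scales_mm = as.numeric(scales_mm),
                 algorithms = algorithms,
                 gray_levels = as.integer(gray_levels)),
            class = "extraction_grid")
}

n_features <- function(grid) {
  4L + 43L * length(grid$scales_mm) * length(grid$algorithms) *
    length(grid$gray_levels)
}

texture_block_names <- function() {
  c(paste0("global.", global_feature_names),
    paste0("glcm.", glcm_feature_names),
    paste0("glrlm.", rl_feature_names),
    paste0("glszm.", sz_feature_names),
    paste0("ngtdm.", ngtdm_feature_names))
}

#' Deterministic feature-name order for a grid
#'
#' `geometry.*` first, then for each scale, algorithm and grey-level count
#' (in grid order) the 43-feature block named
#' `<family>.<feature>.s<scale>.<algo>.g<Ng>`. The Global histogram
#' features depend only on the scale but are repeated in every block so
#' each combination uniformly contributes 43 features.
#'
#' @param grid an [extraction_grid()].
#' @return Character vector of feature names.
#' @export
feature_names <- function(grid) {
  geo <- paste0("geometry.", c("volume_mm3", "size_mm", "solidity",
                               "eccentricity"))
  blocks <- character(0)
  base <- texture_block_names()
  for (s in grid$scales_mm)
    for (a in grid$algorithms)
      for (g in grid$gray_levels)
        blocks <- c(blocks, sprintf("%s.s%g.%s.g%d", base, s, a, g))
  c(geo, blocks)
}

#' Extract the full radiomics feature vector of one VOI
#'
#' Geometric features come from the native-resolution mask; for every
#' combination of the extraction grid the image and mask are resampled to
#' the isotropic scale, quantized, the four texture-matrix families are
#' built and the 43 texture features computed. Deterministic: the same
#' (image, mask, grid) always yields the same vector.
#'
#' @param image an [image_volume()] (normalized upstream if desired).
#' @param mask an aligned nonempty [voi_mask()].
#' @param grid an [extraction_grid()].
#' @return Named numeric vector of length `4 + 43 * (number of
#'   combinations)` (2068 under the default grid).
#' @export
extract_features <- function(image, mask, grid = extraction_grid()) {
  stopifnot(inherits(grid, "extraction_grid"))
  out <- numeric(n_features(grid))
  names(out) <- feature_names(grid)
  out[1:4] <- geometric_features(mask)
  pos <- 5L
  for (s in grid$scales_mm) {
    res <- tryCatch(resample_isotropic(image, mask, s),
                    error = function(e)
                      stop(sprintf("extraction failed at scale %g mm: %s",
                                   s, conditionMessage(e))))
    intens <- res$image$voxels[res$mask$voxels]
    glob <- stats_global(intens)
    for (a in grid$algorithms) {
      for (g in grid$gray_levels) {
        q <- suppressWarnings(quantize(res$image, res$mask, a, g))
        m <- tryCatch(build_texture_matrices(q),
                      error = function(e)
                        stop(sprintf(
                          "extraction failed at scale %g mm, %s, %d levels: %s",
                          s, a, g, conditionMessage(e))))
        fx <- c(glob,
                stats_glcm(m$glcm),
                stats_rl(m$glrlm, m$n_voxels, "glrlm", rl_feature_names),
                stats_rl(m$glszm, m$n_voxels, "glszm", sz_feature_names),
                stats_ngtdm(m$ngtdm))
        out[pos:(pos + 42L)] <- fx
        pos <- pos + 43L
      }
    }
  }
  out
}

#' Feature table of a cohort for one delineation variant
#'
#' Normalizes each image (z-score over the whole volume by default),
#' applies the variant perturbation to the Baseline mask, extracts the full
#' feature vector, and assembles the subjects x features table with
#' `subject_id`, `label` and `split` columns.
#'
#' @param cases list of `synthetic_case` objects (or cases read by
#'   [read_cohort()]).
#' @param grid an [extraction_grid()].
#' @param variant one of `Baseline`, `Erosion`, `Smoothing`, `Dilation`,
#'   `Dilation5`, `Dilation7`.
#' @param normalize normalization method passed to [normalize_intensity()],
#'   or `NULL` to skip.
#' @return data.frame: one row per subject, feature columns in
#'   [feature_names()] order plus `subject_id`, `label`, `split`.
#' @export
cohort_feature_table <- function(cases, grid = extraction_grid(),
                                 variant = "Baseline",
                                 normalize = "zscore") {
  rows <- lapply(cases, function(cs) {
    img <- cs$image
    if (!is.null(normalize))
      img <- normalize_intensity(img, normalize)
    msk <- variant_mask(cs$mask, variant)
    if (!any(msk$voxels))
      stop(sprintf("empty VOI for subject %s variant %s",
                   cs$subject_id, variant))
    extract_features(img, msk, grid)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  tab$subject_id <- vapply(cases, function(cs) cs$subject_id, character(1))
  tab$label <- vapply(cases, function(cs) as.integer(cs$class_label),
                      integer(1))
  tab$split <- vapply(cases, function(cs) cs$split, character(1))
  tab
}

variant_mask <- function(baseline, variant) {
  switch(variant,
         Baseline = baseline,
         Erosion = perturb_mask(baseline, "erode", 3L),
         Smoothing = perturb_mask(baseline, "smooth"),
         Dilation = perturb_mask(baseline, "dilate", 3L),
         Dilation5 = perturb_mask(baseline, "dilate", 5L),
         Dilation7 = perturb_mask(baseline, "dilate", 7L),
         stop(sprintf("unknown variant '%s'", variant)))
}

#' Standard variant names
#' @return Character vector of the six delineation-variant tags.
#' @export
variant_names <- function() {
  c("Baseline", "Erosion", "Smoothing", "Dilation", "Dilation5", "Dilation7")
}
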