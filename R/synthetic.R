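#' Specification of a synthetic two-class lesion cohort
#'
#' Describes a cohort of 3D images with star-convex lesion masks whose two
#' classes (NM = 0, TM = 1) differ in intra-lesion texture correlation
#' length and/or mean lesion intensity. The generator emulates the
#' statistical structure a delineation-sensitivity radiomics study assumes:
#' slice-wise delineated irregular lesions, anisotropic voxel spacing,
#' class-dependent intra-lesion heterogeneity, Gaussian acquisition noise.
#'
#' @param n_per_class cases per class (>= 1).
#' @param image_shape integer length-3 voxel grid size.
#' @param spacing_mm positive length-3 voxel spacing in mm (in-plane,
#'   in-plane, through-plane).
#' @param lesion_radius_range_vox in-plane base-radius interval, voxels.
#' @param boundary_irregularity radial perturbation amplitude as a fraction
#'   of the base radius (star-convex boundary stays star-convex).
#' @param texture_effect class difference in lesion texture correlation
#'   length, voxels (class 1 gets the longer correlation length).
#' @param intensity_effect class difference in mean lesion intensity, in
#'   units of `noise_sd` (added to class 1).
#' @param noise_sd Gaussian noise standard deviation, intensity units.
#' @param validation_fraction stratified hold-out fraction (0.25 mirrors a
#'   238-case nasopharyngeal cohort split; 0.33 a 146-case breast cohort).
#' @param seed integer RNG seed; the cohort is a pure function of the spec.
#' @param background_level,lesion_contrast_sd,field_sd,corr_len_base,psf_sigma
#'   scene parameters: flat background level; lesion-over-background
#'   contrast and intra-lesion texture-field SD (both in `noise_sd` units);
#'   class-0 correlation length (voxels); partial-volume blur SD (voxels)
#'   applied to the lesion contribution, emulating the scanner point-spread
#'   so lesion/background contrast leaks into rim voxels.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_per_class,
                        image_shape = c(64, 64, 16),
                        spacing_mm = c(0.9, 0.9, 4.0),
                        lesion_radius_range_vox = c(8, 12),
                        boundary_irregularity = 0.25,
                        texture_effect = 0,
                        intensity_effect = 0,
                        noise_sd = 1,
                        validation_fraction = 0.25,
                        seed = 1,
                        background_level = 100,
                        lesion_contrast_sd = 6,
                        field_sd = 2,
                        corr_len_base = 1,
                        psf_sigma = 0.6) {
  stopifnot(n_per_class >= 1, length(image_shape) == 3,
            all(image_shape >= 8), length(spacing_mm) == 3,
            all(spacing_mm > 0), length(lesion_radius_range_vox) == 2,
            lesion_radius_range_vox[1] <= lesion_radius_range_vox[2],
            lesion_radius_range_vox[1] > 0,
            boundary_irregularity >= 0, boundary_irregularity < 1,
            texture_effect >= 0, intensity_effect >= 0, noise_sd >= 0,
            validation_fraction > 0, validation_fraction < 1)
  # The largest perturbation dilates by 7 px slice-wise; the lesion must
  # keep that margin from the in-plane border so no variant ever clips.
  jitter <- 3
  max_extent <- jitter + lesion_radius_range_vox[2] *
    (1 + boundary_irregularity) + 7
  if (max_extent > min(image_shape[1:2]) / 2 - 1)
    stop(sprintf(paste0("lesion cannot fit: max in-plane extent %.1f vox ",
                        "(radius + irregularity + dilation margin 7) exceeds ",
                        "half image size %.1f"),
                 max_extent, min(image_shape[1:2]) / 2 - 1))
  structure(
    list(n_per_class = as.integer(n_per_class),
         image_shape = as.integer(image_shape),
         spacing_mm = as.numeric(spacing_mm),
         lesion_radius_range_vox = as.numeric(lesion_radius_range_vox),
         boundary_irregularity = boundary_irregularity,
         texture_effect = texture_effect,
         intensity_effect = intensity_effect,
         noise_sd = noise_sd,
         validation_fraction = validation_fraction,
         seed = as.integer(seed),
         background_level = background_level,
         lesion_contrast_sd = lesion_contrast_sd,
         field_sd = field_sd,
         corr_len_base = corr_len_base,
         psf_sigma = psf_sigma),
    class = "cohort_spec"
  )
}

# Separable Gaussian smoothing with zero padding; sigma per axis in voxels.
gauss_smooth3 <- function(arr, sigma) {
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s < 0.05) next
    h <- max(1L, ceiling(3 * s))
    k <- exp(-((-h:h)^2) / (2 * s^2))
    k <- k / sum(k)
    arr <- conv_axis(arr, k, ax)
  }
  arr
}

# 1D zero-padded convolution of a 3D array along one axis.
conv_axis <- function(arr, k, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = d[axis])
  h <- (length(k) - 1L) / 2L
  n <- d[axis]
  out <- matrix(0, n, ncol(m))
  for (t in seq_along(k)) {
    off <- t - 1L - h
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    if (!any(ok)) next
    out[ok, ] <- out[ok, ] + k[t] * m[src[ok], , drop = FALSE]
  }
  aperm(array(out, d[perm]), order(perm))
}

# Theoretical SD of zero-mean unit-variance white noise after the same
# separable Gaussian smoothing; used to rescale the texture field exactly.
smooth_noise_sd <- function(sigma) {
  f <- 1
  for (s in sigma) {
    if (s < 0.05) next
    h <- max(1L, ceiling(3 * s))
    k <- exp(-((-h:h)^2) / (2 * s^2))
    k <- k / sum(k)
    f <- f * sqrt(sum(k^2))
  }
  f
}

# Build one star-convex lesion mask: per-slice radial function
# r(theta, z) = base in-plane radius * elliptical z-profile *
# (1 + irregularity * smooth periodic perturbation).
make_lesion_mask <- function(shape, center, r0, rz, irr, coef) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  xs <- seq_len(nx) - center[1]
  ys <- seq_len(ny) - center[2]
  dx <- matrix(xs, nx, ny)
  dy <- matrix(ys, nx, ny, byrow = TRUE)
  rho <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  pert <- matrix(0, nx, ny)
  for (m in seq_len(nrow(coef)))
    pert <- pert + coef[m, 1] * cos(coef[m, 3] * theta) +
                   coef[m, 2] * sin(coef[m, 3] * theta)
  mx <- max(abs(pert))
  if (mx > 0) pert <- pert / mx
  mask <- array(FALSE, shape)
  for (z in seq_len(nz)) {
    zf <- 1 - ((z - center[3]) / rz)^2
    if (zf <= 0) next
    rad <- r0 * sqrt(zf) * (1 + irr * pert)
    mask[, , z] <- rho <= rad
  }
  mask
}

#' Generate a synthetic two-class cohort
#'
#' Deterministic given the spec (including its seed). Each case carries an
#' [image_volume()], its Baseline [voi_mask()], a class label and a
#' stratified training/validation split assignment. The lesion interior is a
#' correlated Gaussian random field (white noise smoothed at the
#' class-dependent correlation length) on top of a class-dependent mean
#' shift; the lesion contribution is blurred by a small point-spread kernel
#' so class contrast is also expressed at the lesion rim, as in real
#' partial-volume imaging.
#'
#' @param spec a [cohort_spec()].
#' @return List of `synthetic_case` objects (length `2 * n_per_class`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  shape <- spec$image_shape
  n <- spec$n_per_class
  cases <- vector("list", 2L * n)
  idx <- 0L
  for (label in c(0L, 1L)) {
    for (i in seq_len(n)) {
      idx <- idx + 1L
      center <- c(shape[1] / 2 + stats::runif(1, -3, 3),
                  shape[2] / 2 + stats::runif(1, -3, 3),
                  shape[3] / 2 + stats::runif(1, -0.5, 0.5))
      r0 <- stats::runif(1, spec$lesion_radius_range_vox[1],
                         spec$lesion_radius_range_vox[2])
      rz <- stats::runif(1, 0.2, 0.3) * shape[3]
      modes <- 2:5
      coef <- cbind(stats::rnorm(length(modes)) / modes,
                    stats::rnorm(length(modes)) / modes, modes)
      mask <- make_lesion_mask(shape, center, r0, rz,
                               spec$boundary_irregularity, coef)
      # intra-lesion correlated field at the class correlation length
      clen <- spec$corr_len_base + spec$texture_effect * label
      sig <- c(clen, clen, clen / 2)
      wn <- array(stats::rnorm(prod(shape)), shape)
      field <- gauss_smooth3(wn, sig) / smooth_noise_sd(sig)
      contrast <- spec$noise_sd *
        (spec$lesion_contrast_sd + spec$intensity_effect * label)
      delta <- array(0, shape)
      delta[mask] <- contrast + spec$noise_sd * spec$field_sd * field[mask]
      psf <- c(spec$psf_sigma, spec$psf_sigma, spec$psf_sigma / 2)
      delta <- gauss_smooth3(delta, psf)
      vox <- spec$background_level + delta +
        spec$noise_sd * array(stats::rnorm(prod(shape)), shape)
      cases[[idx]] <- structure(
        list(subject_id = sprintf("S%03d", idx),
             class_label = label,
             image = image_volume(vox, spec$spacing_mm),
             mask = voi_mask(mask, spec$spacing_mm, variant = "Baseline"),
             split = "training"),
        class = "synthetic_case")
    }
  }
  # stratified validation split
  for (label in c(0L, 1L)) {
    of_class <- which(vapply(cases, function(cs) cs$class_label,
                             integer(1)) == label)
    n_val <- max(1L, round(spec$validation_fraction * length(of_class)))
    val <- sample(of_class, n_val)
    for (j in val) cases[[j]]$split <- "validation"
  }
  cases
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Write a cohort to disk
#'
#' One NIfTI image and one NIfTI Baseline mask per case, plus a CSV
#' manifest (`subject_id`, `label`, `split`, `image`, `mask` with paths
#' relative to the manifest).
#'
#' @param cases list of `synthetic_case` objects.
#' @param out_dir output directory (created if absent).
#' @return Path of the manifest CSV.
#' @export
write_cohort <- function(cases, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop(sprintf("cannot create cohort directory '%s'", out_dir))
  rows <- lapply(cases, function(cs) {
    img_rel <- sprintf("%s_image.nii.gz", cs$subject_id)
    msk_rel <- sprintf("%s_mask_baseline.nii.gz", cs$subject_id)
    write_volume(cs$image, file.path(out_dir, img_rel))
    write_volume(cs$mask, file.path(out_dir, msk_rel))
    data.frame(subject_id = cs$subject_id, label = cs$class_label,
               split = cs$split, image = img_rel, mask = msk_rel,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  path
}

#' Read a cohort written by [write_cohort()]
#'
#' @param manifest_path path to the manifest CSV.
#' @return List of `synthetic_case` objects.
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop(sprintf("manifest '%s' not found", manifest_path))
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    structure(
      list(subject_id = man$subject_id[i],
           class_label = as.integer(man$label[i]),
           image = read_volume(file.path(base, man$image[i])),
           mask = read_volume(file.path(base, man$mask[i]), mask = TRUE),
           split = man$split[i]),
      class = "synthetic_case")
  })
}
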