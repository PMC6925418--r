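#' Resample an image and mask onto an isotropic grid
#'
#' Resamples both volumes onto an isotropic grid at `scale_mm`, covering the
#' mask's bounding box with a one-voxel pad. The image is interpolated
#' trilinearly; the mask is interpolated linearly as a 0/1 field and
#' re-thresholded at 0.5, which keeps it binary and approximates
#' half-voxel-accurate nearest resampling. Source coordinates outside the
#' volume are clamped (replicate border).
#'
#' @param image an [image_volume()].
#' @param mask an aligned [voi_mask()].
#' @param scale_mm target isotropic voxel size in mm (> 0).
#' @return List with elements `image` ([image_volume()]) and `mask`
#'   ([voi_mask()]), both at spacing `rep(scale_mm, 3)`.
#' @export
resample_isotropic <- function(image, mask, scale_mm) {
  stopifnot(scale_mm > 0)
  check_aligned(image, mask)
  if (!any(mask$voxels)) stop("mask is empty")
  sp <- image$spacing_mm
  d <- dim(image$voxels)
  idx <- which(mask$voxels, arr.ind = TRUE)
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  # target grid covering the bounding box with a one-voxel pad, built in
  # mask-relative coordinates: the offsets depend only on the box extents,
  # so whole-voxel translations of the input shift the grid exactly and
  # every interpolation weight is reproduced bit-for-bit
  src <- lapply(1:3, function(a) {
    ext <- (hi[a] - lo[a]) * sp[a]
    n_t <- floor((ext + 2 * scale_mm) / scale_mm) + 1L
    off <- (seq_len(n_t) - 1) * scale_mm - scale_mm
    s <- lo[a] + off / sp[a]
    # snap near-integer coordinates: keeps the binary mask threshold off
    # the floating-point knife edge, so translated inputs resample
    # identically
    near <- abs(s - round(s)) < 1e-9
    s[near] <- round(s[near])
    pmin(pmax(s, 1), d[a])
  })
  img_r <- trilinear(image$voxels, src)
  # half-maximum threshold with a tolerance absorbing the rounding error
  # of structurally-exact half weights
  msk_r <- trilinear(array(as.numeric(mask$voxels), d), src) >= 0.5 - 1e-9
  if (!any(msk_r))
    stop(sprintf("resampled mask empty at scale %g mm", scale_mm))
  list(image = image_volume(img_r, rep(scale_mm, 3)),
       mask = voi_mask(msk_r, rep(scale_mm, 3), variant = mask$variant))
}

# separable trilinear interpolation of arr at the tensor grid src
# (list of 3 vectors of continuous 1-based indices, already clamped)
trilinear <- function(arr, src) {
  d <- dim(arr)
  i0 <- lapply(1:3, function(a) pmin(floor(src[[a]]), d[a] - 1))
  i0 <- lapply(1:3, function(a) pmax(i0[[a]], 1))
  fr <- lapply(1:3, function(a) src[[a]] - i0[[a]])
  nt <- vapply(src, length, integer(1))
  out <- array(0, nt)
  for (ax in 0:1) for (ay in 0:1) for (az in 0:1) {
    wx <- if (ax == 0) 1 - fr[[1]] else fr[[1]]
    wy <- if (ay == 0) 1 - fr[[2]] else fr[[2]]
    wz <- if (az == 0) 1 - fr[[3]] else fr[[3]]
    w <- outer(outer(wx, wy), wz)
    out <- out + w * arr[pmin(i0[[1]] + ax, d[1]),
                         pmin(i0[[2]] + ay, d[2]),
                         pmin(i0[[3]] + az, d[3]), drop = FALSE]
  }
  out
}
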