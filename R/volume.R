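#' 3D image volume
#'
#' Lightweight container for a 3D scalar image: a numeric array plus voxel
#' spacing (mm) and a world origin. This is the substrate every stage of the
#' radiomics pipeline operates on.
#'
#' @param voxels numeric 3D array of finite values.
#' @param spacing_mm positive numeric length-3 voxel spacing, in mm.
#' @param origin_mm numeric length-3 world position of voxel (1,1,1).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing_mm = c(1, 1, 1),
                         origin_mm = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array")
  if (!all(is.finite(voxels)))
    stop("voxels must be finite")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive values")
  structure(
    list(voxels = voxels, spacing_mm = spacing_mm,
         origin_mm = as.numeric(origin_mm)),
    class = "image_volume"
  )
}

#' Binary volume-of-interest mask
#'
#' A binary 3D mask aligned voxel-for-voxel with an [image_volume()], tagged
#' with the delineation variant it represents (`Baseline`, `Erosion`,
#' `Smoothing`, `Dilation`, `Dilation5`, `Dilation7`).
#'
#' @param voxels logical/0-1 3D array.
#' @param spacing_mm positive numeric length-3 voxel spacing, in mm.
#' @param variant delineation-variant tag.
#' @param empty_ok allow an empty mask (e.g. after erosion) without error.
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(voxels, spacing_mm = c(1, 1, 1), variant = "Baseline",
                     empty_ok = FALSE) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("mask voxels must be a 3D array")
  storage.mode(voxels) <- "logical"
  if (!any(voxels) && !empty_ok)
    stop("mask has no foreground voxels")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive values")
  structure(
    list(voxels = voxels, spacing_mm = spacing_mm,
         variant = as.character(variant)),
    class = "voi_mask"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing %s mm, range [%.3g, %.3g]\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing_mm), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("<voi_mask> %s voxels, %d foreground, variant %s\n",
              paste(dim(x$voxels), collapse = "x"),
              sum(x$voxels), x$variant))
  invisible(x)
}

check_aligned <- function(a, b) {
  if (!identical(dim(a$voxels), dim(b$voxels)))
    stop("volumes are not aligned: shapes differ")
  if (max(abs(a$spacing_mm - b$spacing_mm)) > 1e-6)
    stop("volumes are not aligned: spacings differ")
  invisible(TRUE)
}

#' Read a NIfTI volume
#'
#' @param path path to a `.nii`/`.nii.gz` file.
#' @param mask read as a binary [voi_mask()] (threshold at 0.5) rather than
#'   an [image_volume()].
#' @param variant variant tag attached when `mask = TRUE`.
#' @return An [image_volume()] or [voi_mask()].
#' @export
read_volume <- function(path, mask = FALSE, variant = "Baseline") {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  arr <- array(as.numeric(img), dim = dim(img)[1:3])
  if (mask) {
    voi_mask(arr > 0.5, spacing_mm = sp, variant = variant, empty_ok = TRUE)
  } else {
    image_volume(arr, spacing_mm = sp)
  }
}

#' Write a volume or mask to NIfTI
#'
#' Spacing is stored in the header `pixdim` (single precision, as the NIfTI-1
#' format defines).
#'
#' @param x an [image_volume()] or [voi_mask()].
#' @param path output path (`.nii.gz` recommended).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  arr <- x$voxels
  if (is.logical(arr)) storage.mode(arr) <- "integer"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- x$spacing_mm
  ok <- try(RNifti::writeNifti(img, path), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop(sprintf("failed to write NIfTI file '%s'", path))
  invisible(path)
}
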