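#' Geometric (non-texture) features of a VOI
#'
#' Computed once per VOI from the native-resolution mask:
#'
#' * `volume_mm3`: foreground voxel count times voxel volume.
#' * `size_mm`: longest axis of the inertia-equivalent ellipsoid, i.e.
#'   \eqn{2\sqrt{5\lambda_{max}}} of the voxel-coordinate covariance
#'   eigenvalues in physical units (a solid ball of radius r has
#'   covariance eigenvalues \eqn{r^2/5}, so `size_mm` recovers its
#'   diameter).
#' * `solidity`: mask voxel count divided by the number of voxels in the
#'   rasterized 3D convex hull (voxels whose center lies inside the hull
#'   of the mask's voxel centers — the convex-image convention, so a
#'   digital cuboid has solidity exactly 1 and the value never exceeds 1).
#'   Affine invariance of the hull makes this independent of voxel
#'   spacing.
#' * `eccentricity`: \eqn{\sqrt{1-\lambda_{min}/\lambda_{max}}} of the same
#'   eigenvalues (0 for a ball).
#'
#' Degenerate masks (all voxels collinear/coplanar, hull volume 0) report
#' solidity 1 with a warning rather than NaN.
#'
#' @param mask a nonempty [voi_mask()].
#' @return Named numeric vector `volume_mm3`, `size_mm`, `solidity`,
#'   `eccentricity`.
#' @export
geometric_features <- function(mask) {
  stopifnot(inherits(mask, "voi_mask"))
  m <- mask$voxels
  if (!any(m)) stop("mask is empty")
  sp <- mask$spacing_mm
  idx <- which(m, arr.ind = TRUE)
  n <- nrow(idx)
  vol <- n * prod(sp)
  pts <- sweep(idx, 2, sp, `*`)
  if (n >= 2) {
    ev <- eigen(stats::cov(pts) * (n - 1) / n, symmetric = TRUE,
                only.values = TRUE)$values
    ev <- pmax(ev, 0)
  } else ev <- c(0, 0, 0)
  size <- 2 * sqrt(5 * max(ev))
  ecc <- if (max(ev) > 0) sqrt(1 - min(ev) / max(ev)) else 0
  sol <- hull_solidity(m, idx)
  c(volume_mm3 = vol, size_mm = size, solidity = sol, eccentricity = ecc)
}

# Rasterized convex-image solidity: the hull is built from the surface
# voxel centers (whose hull equals that of all centers) and every voxel
# center of the bounding box is tested for membership.
hull_solidity <- function(m, idx) {
  surf <- surface_voxels(m)
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  queries <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2],
                                   z = lo[3]:hi[3]))
  storage.mode(surf) <- "double"
  storage.mode(queries) <- "double"
  inside <- cpp_hull_inside_count(surf, queries)
  if (inside < 0) {
    warning("degenerate mask: convex hull undefined, solidity set to 1")
    return(1)
  }
  min(nrow(idx) / inside, 1)
}

# voxels with any 6-neighbour outside the mask or the array
surface_voxels <- function(m) {
  d <- dim(m)
  interior <- array(TRUE, d)
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    shifted <- array(FALSE, d)
    n <- d[ax]
    src <- seq_len(n) - s
    ok <- src >= 1L & src <= n
    ia <- function(v) switch(ax, list(v, TRUE, TRUE), list(TRUE, v, TRUE),
                             list(TRUE, TRUE, v))
    shifted <- do.call(`[<-`, c(list(shifted), ia(which(ok)),
      list(do.call(`[`, c(list(m), ia(src[ok]), list(drop = FALSE))))))
    interior <- interior & shifted
  }
  surf <- which(m & !interior, arr.ind = TRUE)
  if (nrow(surf) == 0) surf <- which(m, arr.ind = TRUE)
  surf
}
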