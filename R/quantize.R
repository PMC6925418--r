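#' Grey-level quantization of a resampled VOI
#'
#' Maps in-mask intensities to integer grey levels 1..`ng` with one of
#' three algorithms:
#'
#' * `Uniform`: equal-width bins spanning the in-mask \[min, max\].
#' * `Equal`: equal-frequency bins at the in-mask quantile edges.
#' * `Lloyd`: Lloyd-Max scalar quantizer — alternate centroid (bin mean)
#'   and boundary (centroid midpoint) updates from a Uniform start until
#'   the centroids move less than 1e-7 of the intensity range, or 500
#'   iterations.
#'
#' A constant in-mask intensity maps every voxel to level 1 with a warning
#' (downstream texture features then take their degenerate values).
#'
#' @param image a resampled [image_volume()].
#' @param mask the aligned resampled [voi_mask()].
#' @param algorithm `"Uniform"`, `"Equal"` or `"Lloyd"`.
#' @param ng number of grey levels (>= 2).
#' @return A `quantized_voi`: list with `levels` (integer array, 0 outside
#'   the mask, 1..`ng` inside), `ng`, `algorithm` and `scale_mm`.
#' @export
quantize <- function(image, mask, algorithm = c("Uniform", "Equal", "Lloyd"),
                     ng = 32L) {
  algorithm <- match.arg(algorithm)
  check_aligned(image, mask)
  ng <- as.integer(ng)
  stopifnot(ng >= 2L)
  sel <- mask$voxels
  x <- image$voxels[sel]
  lev <- array(0L, dim(sel))
  rng <- range(x)
  if (diff(rng) == 0) {
    warning("constant in-mask intensity: all voxels assigned level 1")
    lev[sel] <- 1L
  } else {
    lev[sel] <- switch(algorithm,
      Uniform = {
        w <- diff(rng) / ng
        pmin(as.integer(floor((x - rng[1]) / w)) + 1L, ng)
      },
      Equal = {
        edges <- stats::quantile(x, seq(0, 1, length.out = ng + 1),
                                 names = FALSE, type = 7)
        findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
      },
      Lloyd = lloyd_max(x, ng, rng))
  }
  structure(list(levels = lev, ng = ng, algorithm = algorithm,
                 scale_mm = image$spacing_mm[1]),
            class = "quantized_voi")
}

lloyd_max <- function(x, ng, rng, tol = 1e-7, max_iter = 500L) {
  w <- diff(rng) / ng
  cent <- rng[1] + (seq_len(ng) - 0.5) * w
  tol_abs <- tol * diff(rng)
  lev <- rep(1L, length(x))
  for (it in seq_len(max_iter)) {
    bounds <- (cent[-ng] + cent[-1]) / 2
    lev <- findInterval(x, bounds) + 1L
    new_cent <- cent
    means <- tapply(x, factor(lev, levels = seq_len(ng)), mean)
    filled <- !is.na(means)
    new_cent[filled] <- means[filled]  # empty bins keep their centroid
    if (max(abs(new_cent - cent)) < tol_abs) {
      cent <- new_cent
      break
    }
    cent <- new_cent
  }
  bounds <- (cent[-ng] + cent[-1]) / 2
  as.integer(findInterval(x, bounds) + 1L)
}
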