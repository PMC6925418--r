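#' Delineation-variant perturbation of a VOI mask
#'
#' Applies a morphological operation independently to every axial slice of a
#' Baseline mask, producing one of the delineation variants used throughout
#' the package:
#'
#' * `erode` / `dilate`: Euclidean-disk structuring element
#'   \eqn{\{(dx,dy): dx^2+dy^2 \le r^2\}} (an exact disk, not the octagonal
#'   approximation some toolboxes default to — the exact disk is
#'   oracle-checkable: radius 3 has 29 pixels).
#' * `smooth`: 2D Gaussian correlation filter, sigma 3 px in a 7x7 window
#'   with replicate (nearest-border) padding, then re-binarized at 0.5 so a
#'   constant slice is a fixed point. For a symmetric Gaussian kernel,
#'   correlation and convolution coincide.
#'
#' The image voxels are never modified — only the mask changes.
#'
#' @param mask a nonempty [voi_mask()].
#' @param operation `"erode"`, `"dilate"` or `"smooth"`.
#' @param radius_px disk radius in pixels (erosion uses 3; dilation 3, 5
#'   or 7).
#' @param sigma_px Gaussian sigma in pixels for `smooth`.
#' @param window_px Gaussian window size for `smooth` (odd).
#' @return A [voi_mask()] with the variant tag set (`Erosion`, `Smoothing`,
#'   `Dilation`, `Dilation5`, `Dilation7`, or `<op><radius>` for
#'   non-standard radii). If erosion empties every slice the mask is
#'   returned empty with attribute `empty_after_erosion = TRUE` and a
#'   warning.
#' @export
perturb_mask <- function(mask, operation = c("erode", "dilate", "smooth"),
                         radius_px = 3L, sigma_px = 3, window_px = 7L) {
  operation <- match.arg(operation)
  stopifnot(inherits(mask, "voi_mask"))
  if (!any(mask$voxels)) stop("baseline mask is empty")
  m <- mask$voxels
  nz <- dim(m)[3]
  out <- array(FALSE, dim(m))
  if (operation == "smooth") {
    h <- (as.integer(window_px) - 1L) %/% 2L
    g <- outer(-h:h, -h:h, function(a, b)
      exp(-(a^2 + b^2) / (2 * sigma_px^2)))
    g <- g / sum(g)
    for (z in seq_len(nz)) {
      sl <- m[, , z]
      if (!any(sl)) next
      out[, , z] <- smooth_slice(sl, g) >= 0.5
    }
    variant <- "Smoothing"
  } else {
    off <- disk_offsets(radius_px)
    for (z in seq_len(nz)) {
      sl <- m[, , z]
      if (!any(sl)) next
      out[, , z] <- if (operation == "dilate") dilate_slice(sl, off)
                    else erode_slice(sl, off)
    }
    variant <- if (operation == "erode") {
      if (radius_px == 3L) "Erosion" else sprintf("Erosion%d", radius_px)
    } else {
      switch(as.character(radius_px), "3" = "Dilation",
             "5" = "Dilation5", "7" = "Dilation7",
             sprintf("Dilation%d", radius_px))
    }
  }
  if (!any(out)) {
    warning("perturbation emptied the mask on every slice")
    res <- voi_mask(out, mask$spacing_mm, variant, empty_ok = TRUE)
    attr(res, "empty_after_erosion") <- TRUE
    return(res)
  }
  voi_mask(out, mask$spacing_mm, variant)
}

#' @return integer matrix of (dx, dy) offsets of the exact Euclidean disk.
#' @noRd
disk_offsets <- function(r) {
  r <- as.integer(r)
  stopifnot(r >= 1L)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  as.matrix(g[g$dx^2 + g$dy^2 <= r^2, , drop = FALSE])
}

# shift-and-combine morphology on one logical slice
dilate_slice <- function(sl, off) {
  d <- dim(sl)
  out <- matrix(FALSE, d[1], d[2])
  for (k in seq_len(nrow(off)))
    out <- out | shift_slice(sl, off[k, 1], off[k, 2], fill = FALSE)
  out
}

erode_slice <- function(sl, off) {
  d <- dim(sl)
  out <- matrix(TRUE, d[1], d[2])
  for (k in seq_len(nrow(off))) {
    out <- out & shift_slice(sl, -off[k, 1], -off[k, 2], fill = FALSE)
    if (!any(out)) break
  }
  out
}

shift_slice <- function(sl, dx, dy, fill = FALSE) {
  d <- dim(sl)
  out <- matrix(fill, d[1], d[2])
  xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
  ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
  if (length(xs) < 1 || length(ys) < 1) return(out)
  out[xs, ys] <- sl[xs - dx, ys - dy]
  out
}

# 2D correlation filter with replicate-border padding
smooth_slice <- function(sl, g) {
  h <- (nrow(g) - 1L) %/% 2L
  d <- dim(sl)
  pad <- matrix(0, d[1] + 2L * h, d[2] + 2L * h)
  pad[(h + 1):(h + d[1]), (h + 1):(h + d[2])] <- sl
  # replicate edges
  pad[1:h, ] <- pad[rep(h + 1L, h), ]
  pad[(h + d[1] + 1):(d[1] + 2 * h), ] <- pad[rep(h + d[1], h), ]
  pad[, 1:h] <- pad[, rep(h + 1L, h)]
  pad[, (h + d[2] + 1):(d[2] + 2 * h)] <- pad[, rep(h + d[2], h)]
  out <- matrix(0, d[1], d[2])
  for (a in seq_len(nrow(g)))
    for (b in seq_len(ncol(g)))
      out <- out + g[a, b] * pad[(a - 1) + seq_len(d[1]),
                                 (b - 1) + seq_len(d[2])]
  out
}

#' All standard delineation variants of a Baseline mask
#'
#' @param mask Baseline [voi_mask()].
#' @return Named list: `Baseline`, `Erosion` (r=3), `Smoothing` (sigma 3,
#'   7x7), `Dilation` (r=3), `Dilation5`, `Dilation7`.
#' @export
voi_variants <- function(mask) {
  list(Baseline = mask,
       Erosion = perturb_mask(mask, "erode", 3L),
       Smoothing = perturb_mask(mask, "smooth"),
       Dilation = perturb_mask(mask, "dilate", 3L),
       Dilation5 = perturb_mask(mask, "dilate", 5L),
       Dilation7 = perturb_mask(mask, "dilate", 7L))
}

#' Volume ratio of a perturbed mask to its baseline
#'
#' @param perturbed,baseline aligned [voi_mask()] objects.
#' @return Foreground voxel count of `perturbed` divided by that of
#'   `baseline`.
#' @export
volume_ratio <- function(perturbed, baseline) {
  check_aligned(perturbed, baseline)
  nb <- sum(baseline$voxels)
  if (nb == 0) stop("baseline mask is empty")
  sum(perturbed$voxels) / nb
}

#' Per-slice bounding-rectangle margin distances between two delineations
#'
#' For every axial slice where both masks have foreground, fits each mask's
#' smallest axis-aligned bounding rectangle and returns the absolute
#' differences of the four edges (up, down, left, right), in pixels. Rows
#' follow the first array axis (up = smaller index side) and columns the
#' second. Pooling the values across slices and subjects gives the
#' inter-observer margin-distance distribution.
#'
#' @param mask_a,mask_b aligned [voi_mask()] objects.
#' @return data.frame with columns `slice`, `up`, `down`, `left`, `right`.
#' @export
margin_distances <- function(mask_a, mask_b) {
  check_aligned(mask_a, mask_b)
  nz <- dim(mask_a$voxels)[3]
  rows <- list()
  for (z in seq_len(nz)) {
    sa <- mask_a$voxels[, , z]
    sb <- mask_b$voxels[, , z]
    if (!any(sa) || !any(sb)) next
    ba <- bbox2d(sa); bb <- bbox2d(sb)
    rows[[length(rows) + 1L]] <- data.frame(
      slice = z,
      up = abs(ba[1] - bb[1]), down = abs(ba[2] - bb[2]),
      left = abs(ba[3] - bb[3]), right = abs(ba[4] - bb[4]))
  }
  if (length(rows) == 0)
    stop("no slice where both masks have foreground")
  do.call(rbind, rows)
}

bbox2d <- function(sl) {
  rws <- which(rowSums(sl) > 0)
  cls <- which(colSums(sl) > 0)
  c(min(rws), max(rws), min(cls), max(cls))
}
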