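#' Intensity normalization
#'
#' Standardizes image intensities before feature extraction, reducing
#' between-acquisition variability. Two methods:
#'
#' * `zscore`: subtract the mean and divide by the SD, computed over the
#'   body mask when given, else over the whole volume. Idempotent.
#' * `landmark`: piecewise-linear histogram mapping sending the image's own
#'   percentile landmarks (1st, deciles, 99th) onto a fixed \[0, 100\]
#'   reference scale. This is a simplified single-image variant of
#'   training-set landmark normalization: no cohort-level landmark averaging
#'   is performed, so it standardizes the histogram shape per image rather
#'   than learning a scanner-specific map.
#'
#' Bias-field correction is assumed to have been applied upstream; this
#' package does not implement it.
#'
#' @param image an [image_volume()].
#' @param method `"zscore"` or `"landmark"`.
#' @param body_mask optional [voi_mask()] restricting the statistics.
#' @return A normalized [image_volume()] (spacing/origin unchanged).
#' @export
normalize_intensity <- function(image, method = c("zscore", "landmark"),
                                body_mask = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(image, "image_volume"))
  v <- image$voxels
  sel <- if (is.null(body_mask)) rep(TRUE, length(v)) else {
    check_aligned(image, body_mask)
    if (!any(body_mask$voxels)) stop("body_mask is empty")
    as.vector(body_mask$voxels)
  }
  x <- v[sel]
  if (method == "zscore") {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      stop("degenerate intensity distribution")
    out <- (v - mean(x)) / s
  } else {
    probs <- c(0.01, seq(0.1, 0.9, by = 0.1), 0.99)
    lm_src <- stats::quantile(x, probs, names = FALSE, type = 7)
    if (max(lm_src) - min(lm_src) == 0)
      stop("degenerate intensity distribution")
    lm_ref <- 100 * (probs - min(probs)) / (max(probs) - min(probs))
    dup <- duplicated(lm_src)  # flat histogram stretches collapse landmarks
    lm_src <- lm_src[!dup]
    lm_ref <- lm_ref[!dup]
    # piecewise-linear interpolation, linear extrapolation at the tails
    out <- array(stats::approx(lm_src, lm_ref, xout = as.vector(v),
                               rule = 2, ties = "ordered")$y, dim(v))
    below <- v < lm_src[1]
    above <- v > lm_src[length(lm_src)]
    sl_lo <- (lm_ref[2] - lm_ref[1]) / (lm_src[2] - lm_src[1])
    k <- length(lm_src)
    sl_hi <- (lm_ref[k] - lm_ref[k - 1]) / (lm_src[k] - lm_src[k - 1])
    out[below] <- lm_ref[1] + sl_lo * (v[below] - lm_src[1])
    out[above] <- lm_ref[k] + sl_hi * (v[above] - lm_src[k])
  }
  image_volume(out, image$spacing_mm, image$origin_mm)
}
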