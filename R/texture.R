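#' The 13 unique 3D line directions
#'
#' Voxel offsets for distance-1 neighbours, one per line orientation (each
#' direction and its negation are the same line).
#'
#' @return 13 x 3 integer matrix.
#' @export
directions_13 <- function() {
  matrix(c(1, 0, 0,  0, 1, 0,  0, 0, 1,
           1, 1, 0,  1, -1, 0,  1, 0, 1,  1, 0, -1,
           0, 1, 1,  0, 1, -1,
           1, 1, 1,  1, 1, -1,  1, -1, 1,  1, -1, -1),
         ncol = 3, byrow = TRUE)
}

#' Texture matrices of a quantized VOI
#'
#' Builds the four texture-matrix families from a [quantize()]d VOI:
#'
#' * GLCM: distance-1 voxel pairs pooled over the supplied directions into
#'   one merged matrix (not per-direction feature averaging), symmetrized
#'   and normalized to sum 1.
#' * GLRLM: maximal equal-level runs pooled over the directions
#'   (counts, grey level x run length).
#' * GLSZM: 26-connected equal-level zones (counts, grey level x zone
#'   size).
#' * NGTDM: per-level sums of the absolute difference between each voxel's
#'   level and the mean level of its in-mask 26-neighbours, with the
#'   per-level voxel counts.
#'
#' @param q a `quantized_voi`.
#' @param directions direction set for GLCM/GLRLM (default
#'   [directions_13()]).
#' @return A `texture_matrices` list: `glcm`, `glrlm`, `glszm`, `ngtdm`
#'   (list `s`, `n`), `n_voxels`.
#' @export
build_texture_matrices <- function(q, directions = directions_13()) {
  stopifnot(inherits(q, "quantized_voi"))
  lev <- q$levels
  storage.mode(lev) <- "integer"
  dirs <- matrix(as.integer(directions), ncol = 3)
  n_vox <- sum(lev > 0L)
  glcm <- cpp_glcm(lev, q$ng, dirs)
  if (sum(glcm) == 0)
    stop("no voxel pairs: mask too small for co-occurrence statistics")
  structure(
    list(glcm = glcm,
         glrlm = cpp_glrlm(lev, q$ng, dirs),
         glszm = cpp_glszm(lev, q$ng),
         ngtdm = cpp_ngtdm(lev, q$ng),
         n_voxels = n_vox),
    class = "texture_matrices")
}

glcm_feature_names <- c("energy", "contrast", "entropy", "homogeneity",
                        "correlation", "sum_average", "variance",
                        "dissimilarity", "autocorrelation")
rl_feature_names <- c("sre", "lre", "gln", "rln", "rp", "lgre", "hgre",
                      "srlge", "srhge", "lrlge", "lrhge", "glv", "rlv")
sz_feature_names <- c("sze", "lze", "gln", "zsn", "zp", "lgze", "hgze",
                      "szlge", "szhge", "lzlge", "lzhge", "glv", "zsv")
ngtdm_feature_names <- c("coarseness", "contrast", "busyness", "complexity",
                         "strength")
global_feature_names <- c("hist_variance", "hist_skewness", "hist_kurtosis")

#' The 43 texture features of one extraction-parameter combination
#'
#' Global (3: variance, skewness and kurtosis of the 100-bin in-mask
#' intensity histogram), GLCM (9), GLRLM (13), GLSZM (13) and NGTDM (5)
#' features, with standard matrix-statistics definitions. Degenerate
#' matrices yield the features' defined limits (e.g. entropy 0 and energy 1
#' for a single-cell GLCM; NGTDM coarseness capped at 1e6), never NaN.
#'
#' @param m a `texture_matrices` object.
#' @param intensities in-mask intensities of the same resampled VOI (feeds
#'   the Global histogram features).
#' @return Named numeric vector of length 43 (names prefixed `global.`,
#'   `glcm.`, `glrlm.`, `glszm.`, `ngtdm.`).
#' @export
texture_features <- function(m, intensities) {
  stopifnot(inherits(m, "texture_matrices"))
  c(stats_global(intensities),
    stats_glcm(m$glcm),
    stats_rl(m$glrlm, m$n_voxels, "glrlm", rl_feature_names),
    stats_rl(m$glszm, m$n_voxels, "glszm", sz_feature_names),
    stats_ngtdm(m$ngtdm))
}

stats_global <- function(x, n_bins = 100L) {
  rng <- range(x)
  if (diff(rng) == 0) {
    out <- c(0, 0, 3)
  } else {
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
    cnt <- tabulate(findInterval(x, edges, rightmost.closed = TRUE,
                                 all.inside = TRUE), nbins = n_bins)
    p <- cnt / sum(cnt)
    ctr <- (edges[-1] + edges[-(n_bins + 1)]) / 2
    mu <- sum(p * ctr)
    v <- sum(p * (ctr - mu)^2)
    if (v > 0) {
      out <- c(v, sum(p * (ctr - mu)^3) / v^1.5,
               sum(p * (ctr - mu)^4) / v^2)
    } else out <- c(v, 0, 3)
  }
  names(out) <- paste0("global.", global_feature_names)
  out
}

stats_glcm <- function(p) {
  ng <- nrow(p)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p)
  mu_x <- sum(seq_len(ng) * px)
  var_x <- sum((seq_len(ng) - mu_x)^2 * px)
  corr <- if (var_x > 0) {
    (sum(i * j * p) - mu_x^2) / var_x  # symmetric: mu_y = mu_x
  } else 1
  out <- c(sum(p^2),
           sum((i - j)^2 * p),
           -sum(p[p > 0] * log2(p[p > 0])),
           sum(p / (1 + abs(i - j))),
           corr,
           sum((i + j) / 2 * p),
           sum((i - mu_x)^2 * p),
           sum(abs(i - j) * p),
           sum(i * j * p))
  names(out) <- paste0("glcm.", glcm_feature_names)
  out
}

# Shared run-length / size-zone statistics: counts is grey level x run
# length (or zone size); the 13 features use the normalized matrix
# p = counts / total and the level (i) and length (j) weightings.
stats_rl <- function(counts, n_voxels, prefix, feat_names) {
  total <- sum(counts)
  ng <- nrow(counts)
  nl <- ncol(counts)
  if (total == 0) {
    out <- rep(0, 13)
    names(out) <- paste0(prefix, ".", feat_names)
    return(out)
  }
  p <- counts / total
  i <- matrix(seq_len(ng), ng, nl)
  j <- matrix(seq_len(nl), ng, nl, byrow = TRUE)
  mu_i <- sum(p * i)
  mu_j <- sum(p * j)
  out <- c(sum(p / j^2),
           sum(p * j^2),
           sum(rowSums(counts)^2) / total,
           sum(colSums(counts)^2) / total,
           total / n_voxels,
           sum(p / i^2),
           sum(p * i^2),
           sum(p / (i^2 * j^2)),
           sum(p * i^2 / j^2),
           sum(p * j^2 / i^2),
           sum(p * i^2 * j^2),
           sum(p * (i - mu_i)^2),
           sum(p * (j - mu_j)^2))
  names(out) <- paste0(prefix, ".", feat_names)
  out
}

stats_ngtdm <- function(ng_acc, cap = 1e6) {
  s <- ng_acc$s
  n <- ng_acc$n
  total <- sum(n)
  out <- rep(0, 5)
  names(out) <- paste0("ngtdm.", ngtdm_feature_names)
  if (total == 0) {
    out["ngtdm.coarseness"] <- cap
    return(out)
  }
  p <- n / total
  present <- which(n > 0)
  lv <- seq_along(p)
  denom_c <- sum(p * s)
  out["ngtdm.coarseness"] <- if (denom_c > 1 / cap) 1 / denom_c else cap
  np <- length(present)
  if (np >= 2) {
    pi_ <- p[present]; li <- lv[present]; si <- s[present]
    dif2 <- outer(li, li, function(a, b) (a - b)^2)
    out["ngtdm.contrast"] <- sum(outer(pi_, pi_) * dif2) /
      (np * (np - 1)) * sum(s) / total
    denom_b <- sum(abs(outer(li * pi_, li * pi_, `-`)))
    out["ngtdm.busyness"] <- if (denom_b > 0) denom_c / denom_b else 0
    psi <- pi_ * si
    psum <- outer(pi_, pi_, `+`)
    out["ngtdm.complexity"] <- sum(abs(outer(li, li, `-`)) *
      outer(psi, psi, `+`) / psum) / total
    ssum <- sum(si)
    out["ngtdm.strength"] <- if (ssum > 0)
      sum(psum * dif2) / ssum else 0
  }
  out
}
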