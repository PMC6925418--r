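#' Rank-statistic AUC
#'
#' Area under the ROC curve computed as the normalized Mann-Whitney
#' statistic: the probability that a random class-1 score exceeds a random
#' class-0 score, with ties counted half. Invariant under strictly
#' monotone transforms of the scores.
#'
#' @param scores numeric predicted scores (higher = more class 1).
#' @param labels binary 0/1 labels.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes required to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Placement values: for each class-1 subject the fraction of class-0
# subjects it outranks (ties half), and vice versa. The empirical AUC is
# the mean of either vector; their variances drive the DeLong machinery.
placements <- function(scores, labels) {
  labels <- as.integer(labels)
  x <- scores[labels == 1L]
  y <- scores[labels == 0L]
  v10 <- vapply(x, function(xi)
    mean((xi > y) + 0.5 * (xi == y)), numeric(1))
  v01 <- vapply(y, function(yj)
    mean((x > yj) + 0.5 * (x == yj)), numeric(1))
  list(v10 = v10, v01 = v01)
}

#' Variance of an empirical AUC (DeLong)
#'
#' @param scores,labels as in [auc_rank()].
#' @return The structural-component variance estimate of the AUC.
#' @export
auc_variance <- function(scores, labels) {
  pl <- placements(scores, labels)
  stats::var(pl$v10) / length(pl$v10) + stats::var(pl$v01) / length(pl$v01)
}

#' DeLong test for two correlated ROC curves
#'
#' Compares the AUCs of two score vectors over the same subjects using the
#' placement-value (structural component) estimate of the variance of the
#' AUC difference, which accounts for the correlation induced by the shared
#' subjects. The p-value is the two-sided normal tail of
#' \eqn{z = (AUC_a - AUC_b) / \sqrt{V_{aa} + V_{bb} - 2V_{ab}}}.
#'
#' @param scores_a,scores_b score vectors on the same subjects.
#' @param labels shared binary 0/1 labels.
#' @return List: `auc_a`, `auc_b`, `z`, `p` and `degenerate` (TRUE with
#'   p = 1 when the variance of the difference vanishes, e.g. identical
#'   scores).
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(scores_b),
            length(labels) == length(scores_a))
  pa <- placements(scores_a, labels)
  pb <- placements(scores_b, labels)
  auc_a <- mean(pa$v10)
  auc_b <- mean(pb$v10)
  m <- length(pa$v10)
  n <- length(pa$v01)
  v <- stats::var(pa$v10 - pb$v10) / m + stats::var(pa$v01 - pb$v01) / n
  if (!is.finite(v) || v <= .Machine$double.eps) {
    return(list(auc_a = auc_a, auc_b = auc_b, z = 0, p = 1,
                degenerate = TRUE))
  }
  z <- (auc_a - auc_b) / sqrt(v)
  list(auc_a = auc_a, auc_b = auc_b, z = z,
       p = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
}
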