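#' Feature-selection configuration
#'
#' Two-stage selection on the training cohort: an mRMR shortlist followed
#' by 0.632+ bootstrap-AUC ranking of the final top-predictive set. The
#' study defaults are a 100-feature shortlist, 20 final features and 1000
#' bootstrap iterations at 63.2% resampling; smaller values are routinely
#' used for testing.
#'
#' @param shortlist_size mRMR shortlist length.
#' @param final_size number of top-predictive features to rank.
#' @param n_bootstrap bootstrap iterations for the 0.632+ estimator.
#' @param resample_fraction training fraction drawn per iteration (without
#'   replacement, class-stratified). With `replace = TRUE` the classic
#'   with-replacement bootstrap is used instead (63.2% is the expected
#'   unique fraction of that scheme, which motivates the default).
#' @param ranking_mode `"stepwise"` (greedy forward maximization of the
#'   0.632+ AUC of the growing set, the default) or `"univariate"`
#'   (single-feature 0.632+ AUC).
#' @param replace use with-replacement bootstrap resampling.
#' @param ridge ridge regularization of the selection-stage linear
#'   discriminant, as a fraction of the mean pooled variance.
#' @param seed integer seed controlling all resampling.
#' @return A `selection_config` object.
#' @export
selection_config <- function(shortlist_size = 100L, final_size = 20L,
                             n_bootstrap = 1000L,
                             resample_fraction = 0.632,
                             ranking_mode = c("stepwise", "univariate"),
                             replace = FALSE, ridge = 1e-3, seed = 1L) {
  ranking_mode <- match.arg(ranking_mode)
  stopifnot(final_size <= shortlist_size, n_bootstrap >= 1,
            resample_fraction > 0, resample_fraction < 1, ridge >= 0)
  structure(list(shortlist_size = as.integer(shortlist_size),
                 final_size = as.integer(final_size),
                 n_bootstrap = as.integer(n_bootstrap),
                 resample_fraction = resample_fraction,
                 ranking_mode = ranking_mode, replace = replace,
                 ridge = ridge, seed = as.integer(seed)),
            class = "selection_config")
}

# --- mutual information on 3-level discretization -------------------------

# discretize each column at mean +/- SD into levels 1/2/3; population SD
# and inclusive outer bins, so a symmetric two-valued feature lands in the
# outer bins rather than collapsing into the middle one
discretize_3lev <- function(x) {
  mu <- colMeans(x)
  sd_ <- sqrt(pmax(colMeans(x^2) - mu^2, 0))
  lev <- matrix(2L, nrow(x), ncol(x))
  lev[sweep(x, 2, mu - sd_, `<=`)] <- 1L
  lev[sweep(x, 2, mu + sd_, `>=`)] <- 3L
  lev
}

# MI (bits) between each column of the discretized matrix and a discrete
# target vector, via one-hot crossproducts
mi_columns <- function(lev, target) {
  n <- nrow(lev)
  tl <- sort(unique(target))
  ti <- matrix(0, n, length(tl))
  for (k in seq_along(tl)) ti[target == tl[k], k] <- 1
  p <- ncol(lev)
  out <- numeric(p)
  oh <- lapply(1:3, function(l) (lev == l) + 0)
  for (k in seq_along(tl)) {
    for (l in 1:3) {
      joint <- colSums(oh[[l]] * ti[, k]) / n
      px <- colSums(oh[[l]]) / n
      py <- sum(ti[, k]) / n
      nz <- joint > 0
      out[nz] <- out[nz] + joint[nz] * log2(joint[nz] / (px[nz] * py))
    }
  }
  out
}

#' mRMR feature ranking (MID criterion)
#'
#' Greedy maximum-relevance minimum-redundancy ranking by mutual
#' information: the first feature maximizes relevance I(f; class); each
#' subsequent pick maximizes relevance minus the mean mutual information
#' with the already-selected set. Features and MI are discretized to three
#' levels at mean +/- SD. Ties break toward the lower column index, so the
#' ranking is deterministic.
#'
#' @param features numeric matrix or data.frame (subjects x features) of
#'   training-cohort feature values.
#' @param labels binary 0/1 class labels.
#' @param m shortlist length (warned and truncated if fewer features).
#' @return Character vector of `m` feature names in rank order.
#' @export
mrmr_rank <- function(features, labels, m = 100L) {
  x <- as.matrix(features)
  stopifnot(nrow(x) == length(labels))
  if (length(unique(labels)) < 2) stop("both classes required")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  p <- ncol(x)
  if (p < m) {
    warning(sprintf("only %d features available for a shortlist of %d", p, m))
    m <- p
  }
  lev <- discretize_3lev(x)
  relevance <- mi_columns(lev, as.integer(labels))
  selected <- integer(0)
  redundancy <- numeric(p)
  candidates <- rep(TRUE, p)
  for (step in seq_len(m)) {
    score <- relevance - if (step == 1) 0 else redundancy / (step - 1)
    score[!candidates] <- -Inf
    pick <- which.max(score)  # first max: ties break to lower index
    selected <- c(selected, pick)
    candidates[pick] <- FALSE
    if (step < m)
      redundancy <- redundancy + mi_columns(lev, lev[, pick])
  }
  colnames(x)[selected]
}

# --- regularized linear discriminant (selection-stage classifier) ---------

# returns a scoring function or NULL when degenerate
fit_rlda <- function(x, y, ridge = 1e-3) {
  x <- as.matrix(x)
  i1 <- y == 1
  if (sum(i1) < 1 || sum(!i1) < 1) return(NULL)
  mu0 <- colMeans(x[!i1, , drop = FALSE])
  mu1 <- colMeans(x[i1, , drop = FALSE])
  xc <- x
  xc[i1, ] <- sweep(x[i1, , drop = FALSE], 2, mu1)
  xc[!i1, ] <- sweep(x[!i1, , drop = FALSE], 2, mu0)
  s <- crossprod(xc) / max(nrow(x) - 2, 1)
  lambda <- ridge * mean(diag(s)) + 1e-12
  w <- try(solve(s + diag(lambda, ncol(x)), mu1 - mu0), silent = TRUE)
  if (inherits(w, "try-error")) return(NULL)
  function(newx) as.numeric(as.matrix(newx) %*% w)
}

#' The 0.632+ combination rule
#'
#' Combines the apparent AUC (train = test) with the average bootstrap
#' out-of-sample AUC: with \eqn{AUC' = \max(AUC_{boot}, 0.5)}, the relative
#' overfitting rate is \eqn{R = (AUC_{app} - AUC') / (AUC_{app} - 0.5)}
#' clipped to \[0, 1\] (R = 0 when \eqn{AUC_{app} \le 0.5}), the weight is
#' \eqn{w = 0.632 / (1 - 0.368 R)}, and the estimate is
#' \eqn{(1 - w) AUC_{app} + w \, AUC'}.
#'
#' @param auc_app apparent AUC.
#' @param auc_boot mean bootstrap test AUC.
#' @return The 0.632+ AUC estimate.
#' @export
combine_632plus <- function(auc_app, auc_boot) {
  auc_prime <- max(auc_boot, 0.5)
  r <- if (auc_app <= 0.5 || auc_app <= auc_prime) 0 else
    min(max((auc_app - auc_prime) / (auc_app - 0.5), 0), 1)
  w <- 0.632 / (1 - 0.368 * r)
  (1 - w) * auc_app + w * auc_prime
}

# draw the list of (train, test) index splits used by the bootstrap;
# class-stratified so every split keeps both classes on both sides
bootstrap_splits <- function(labels, config) {
  i1 <- which(labels == 1)
  i0 <- which(labels == 0)
  lapply(seq_len(config$n_bootstrap), function(b) {
    if (config$replace) {
      tr <- c(sample(i1, length(i1), replace = TRUE),
              sample(i0, length(i0), replace = TRUE))
      te <- setdiff(c(i1, i0), unique(tr))
      if (length(unique(labels[te])) < 2) {
        # rare with-replacement draw leaving a one-class test set
        te <- c(sample(i1, 1), sample(i0, 1))
      }
    } else {
      n1 <- min(max(ceiling(config$resample_fraction * length(i1)), 1),
                length(i1) - 1)
      n0 <- min(max(ceiling(config$resample_fraction * length(i0)), 1),
                length(i0) - 1)
      tr <- c(sample(i1, n1), sample(i0, n0))
      te <- setdiff(c(i1, i0), tr)
    }
    list(train = tr, test = te)
  })
}

#' 0.632+ bootstrap AUC of a feature subset
#'
#' Trains the selection-stage classifier (a ridge-regularized linear
#' discriminant) on the full training set for the apparent AUC, then on
#' `n_bootstrap` class-stratified 63.2% subsamples scored on the held-out
#' remainder, and combines the two with [combine_632plus()]. Degenerate
#' fits score AUC 0.5 for that iterate.
#'
#' @param features training feature matrix/data.frame (subjects x
#'   features); the subset is given by `subset_cols`.
#' @param labels binary 0/1 labels.
#' @param subset_cols column names (or indices) of the evaluated subset.
#' @param config a [selection_config()].
#' @param splits optional precomputed [bootstrap_splits()] (shared across
#'   candidate subsets during stepwise ranking).
#' @return The 0.632+ AUC estimate in \[0, 1\].
#' @export
bootstrap_auc_632plus <- function(features, labels, subset_cols,
                                  config = selection_config(),
                                  splits = NULL) {
  x <- as.matrix(features)[, subset_cols, drop = FALSE]
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes required")
  if (is.null(splits)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(config$seed)
    splits <- bootstrap_splits(labels, config)
  }
  f_app <- fit_rlda(x, labels, config$ridge)
  auc_app <- if (is.null(f_app)) 0.5 else auc_rank(f_app(x), labels)
  auc_b <- vapply(splits, function(sp) {
    f <- fit_rlda(x[sp$train, , drop = FALSE], labels[sp$train],
                  config$ridge)
    if (is.null(f)) return(0.5)
    auc_rank(f(x[sp$test, , drop = FALSE]), labels[sp$test])
  }, numeric(1))
  combine_632plus(auc_app, mean(auc_b))
}

#' Rank the final top-predictive features by 0.632+ bootstrap AUC
#'
#' Stepwise mode (default): starting from the empty set, each step adds
#' the shortlist feature maximizing the 0.632+ AUC of the augmented set,
#' recording the score trajectory. Univariate mode ranks by single-feature
#' 0.632+ AUC. Ties break by shortlist (mRMR) order. Fully seeded: the
#' bootstrap splits are drawn once per step and shared across candidates.
#'
#' @param features training feature matrix/data.frame.
#' @param labels binary 0/1 labels.
#' @param shortlist character vector from [mrmr_rank()].
#' @param config a [selection_config()].
#' @return A `selection_result`: list with `shortlist`, `ranked` (length
#'   `final_size`), `scores` (0.632+ AUC at each step), `mode`, `config`.
#' @export
rank_top_features <- function(features, labels, shortlist,
                              config = selection_config()) {
  x <- as.matrix(features)
  labels <- as.integer(labels)
  stopifnot(all(shortlist %in% colnames(x)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  k_final <- min(config$final_size, length(shortlist))
  if (config$ranking_mode == "univariate") {
    splits <- bootstrap_splits(labels, config)
    sc <- vapply(shortlist, function(f)
      bootstrap_auc_632plus(x, labels, f, config, splits), numeric(1))
    ord <- order(-sc, match(shortlist, shortlist))  # stable: mRMR order ties
    ranked <- shortlist[ord][seq_len(k_final)]
    scores <- sc[ord][seq_len(k_final)]
  } else {
    ranked <- character(0)
    scores <- numeric(0)
    remaining <- shortlist
    for (step in seq_len(k_final)) {
      splits <- bootstrap_splits(labels, config)
      cand_scores <- vapply(remaining, function(f)
        bootstrap_auc_632plus(x, labels, c(ranked, f), config, splits),
        numeric(1))
      best <- which.max(cand_scores)  # first max = shortlist order on ties
      ranked <- c(ranked, remaining[best])
      scores <- c(scores, cand_scores[best])
      remaining <- remaining[-best]
    }
  }
  structure(list(shortlist = shortlist, ranked = unname(ranked),
                 scores = unname(scores), mode = config$ranking_mode,
                 config = config),
            class = "selection_result")
}

#' Full two-stage feature selection on the training cohort
#'
#' @param table feature table from [cohort_feature_table()]; only rows with
#'   `split == "training"` are used.
#' @param config a [selection_config()].
#' @return A `selection_result` (see [rank_top_features()]).
#' @export
select_features <- function(table, config = selection_config()) {
  tr <- table[table$split == "training", , drop = FALSE]
  feats <- as.matrix(tr[, setdiff(names(tr),
                                  c("subject_id", "label", "split")),
                        drop = FALSE])
  shortlist <- mrmr_rank(feats, tr$label, m = config$shortlist_size)
  rank_top_features(feats, tr$label, shortlist, config)
}
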