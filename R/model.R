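#' Random-forest model configuration
#'
#' @param n_trees trees per forest (study setting: 150).
#' @param cv_folds stratified cross-validation folds (study setting: 10);
#'   automatically reduced with a warning when a fold could not contain
#'   both classes.
#' @param max_features cap on the incremental feature count (study
#'   setting: 20).
#' @param prob_threshold class-1 probability threshold for
#'   sensitivity/specificity/accuracy.
#' @param seed integer seed for fold assignment and forest growth.
#' @return A `model_spec` object.
#' @export
model_spec <- function(n_trees = 150L, cv_folds = 10L, max_features = 20L,
                       prob_threshold = 0.5, seed = 1L) {
  stopifnot(n_trees >= 1, cv_folds >= 2, max_features >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 cv_folds = as.integer(cv_folds),
                 max_features = as.integer(max_features),
                 prob_threshold = prob_threshold,
                 seed = as.integer(seed)),
            class = "model_spec")
}

fit_forest <- function(x, y, spec, seed) {
  df <- as.data.frame(x)
  df$.class <- factor(y, levels = c(0, 1))
  ranger::ranger(dependent.variable.name = ".class", data = df,
                 num.trees = spec$n_trees, probability = TRUE,
                 seed = seed, num.threads = 1)
}

predict_forest <- function(fit, x) {
  as.numeric(stats::predict(fit, data = as.data.frame(x),
                            num.threads = 1)$predictions[, "1"])
}

# stratified fold assignment; reduces fold count if a class is too small
make_folds <- function(labels, k) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (min(n1, n0) < k) {
    k_new <- max(2L, min(n1, n0))
    warning(sprintf("reducing folds from %d to %d (smallest class has %d)",
                    k, k_new, min(n1, n0)))
    k <- k_new
  }
  fold <- integer(length(labels))
  for (cl in c(0, 1)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  list(fold = fold, k = k)
}

#' Incremental random-forest models over the ranked features
#'
#' For k = 1..`max_features`, runs stratified `cv_folds`-fold
#' cross-validation of a `n_trees`-tree probability forest on the top-k
#' ranked features of the training table, picks the k maximizing the mean
#' CV AUC (ties resolved toward the smaller, more parsimonious k), and
#' refits that model on the full training set.
#'
#' @param table feature table ([cohort_feature_table()]); rows with
#'   `split == "training"` are used.
#' @param ranked ranked feature names (from [select_features()]).
#' @param spec a [model_spec()].
#' @return List: `chosen_k`, `cv_auc` (per-k mean CV AUC), `fit` (the
#'   refitted forest), `features` (the chosen top-k names), `spec`.
#' @export
build_incremental_models <- function(table, ranked, spec = model_spec()) {
  tr <- table[table$split == "training", , drop = FALSE]
  stopifnot(all(ranked %in% names(tr)))
  y <- as.integer(tr$label)
  if (length(unique(y)) < 2) stop("both classes required in training data")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  folds <- make_folds(y, spec$cv_folds)
  kmax <- min(spec$max_features, length(ranked))
  cv_auc <- numeric(kmax)
  for (k in seq_len(kmax)) {
    x <- as.matrix(tr[, ranked[seq_len(k)], drop = FALSE])
    scores <- rep(NA_real_, length(y))
    for (f in seq_len(folds$k)) {
      inf <- folds$fold == f
      fit <- fit_forest(x[!inf, , drop = FALSE], y[!inf], spec,
                        seed = spec$seed + 1000L * k + f)
      scores[inf] <- predict_forest(fit, x[inf, , drop = FALSE])
    }
    cv_auc[k] <- auc_rank(scores, y)
  }
  chosen_k <- which.max(cv_auc)  # first max = smallest k on ties
  x_full <- as.matrix(tr[, ranked[seq_len(chosen_k)], drop = FALSE])
  fit <- fit_forest(x_full, y, spec, seed = spec$seed)
  list(chosen_k = chosen_k, cv_auc = cv_auc, fit = fit,
       features = ranked[seq_len(chosen_k)], spec = spec)
}

#' Evaluate a fitted model on the validation cohort
#'
#' AUC by rank statistic over predicted class-1 probabilities, 95%
#' confidence interval from the DeLong variance, and sensitivity,
#' specificity and accuracy at the probability threshold.
#'
#' @param model result of [build_incremental_models()].
#' @param table feature table; rows with `split == "validation"` are used.
#' @param threshold probability threshold (default from the model spec).
#' @return List: `auc`, `ci` (length 2), `sensitivity`, `specificity`,
#'   `accuracy`, `scores`, `labels`, `n`.
#' @export
evaluate_model <- function(model, table, threshold = NULL) {
  va <- table[table$split == "validation", , drop = FALSE]
  y <- as.integer(va$label)
  if (length(unique(y)) < 2)
    stop("validation cohort must contain both classes")
  if (is.null(threshold)) threshold <- model$spec$prob_threshold
  x <- as.matrix(va[, model$features, drop = FALSE])
  p <- predict_forest(model$fit, x)
  auc <- auc_rank(p, y)
  v <- auc_variance(p, y)
  ci <- pmin(pmax(auc + c(-1, 1) * 1.96 * sqrt(max(v, 0)), 0), 1)
  pred <- as.integer(p >= threshold)
  list(auc = auc, ci = ci,
       sensitivity = mean(pred[y == 1] == 1),
       specificity = mean(pred[y == 0] == 0),
       accuracy = mean(pred == y),
       scores = p, labels = y, n = length(y))
}

#' Cross-variant transfer AUC matrix
#'
#' Entry (d, d') is the validation AUC of the model trained on variant d,
#' applied to validation features extracted from variant d' using d's
#' selected feature names (the diagonal reproduces the standard
#' evaluation).
#'
#' @param models named list of [build_incremental_models()] results, one
#'   per variant.
#' @param tables named list of feature tables, one per variant; all must
#'   share the validation subjects.
#' @return Numeric matrix, variants x variants, dimnames = variant names.
#' @export
transfer_matrix <- function(models, tables) {
  vs <- names(models)
  stopifnot(!is.null(vs), all(vs %in% names(tables)))
  ref <- tables[[vs[1]]]
  ref_ids <- sort(ref$subject_id[ref$split == "validation"])
  out <- matrix(NA_real_, length(vs), length(vs), dimnames = list(vs, vs))
  for (d in vs) {
    feats <- models[[d]]$features
    for (d2 in vs) {
      va <- tables[[d2]][tables[[d2]]$split == "validation", , drop = FALSE]
      if (!identical(sort(va$subject_id), ref_ids))
        stop("variants do not share the validation subject set")
      missing <- setdiff(feats, names(va))
      if (length(missing) > 0)
        stop(sprintf("schema mismatch: variant %s lacks feature(s) %s",
                     d2, paste(missing, collapse = ", ")))
      p <- predict_forest(models[[d]]$fit,
                          as.matrix(va[, feats, drop = FALSE]))
      out[d, d2] <- auc_rank(p, as.integer(va$label))
    }
  }
  out
}
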