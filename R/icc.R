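#' Intra-class correlation between baseline and variant feature values
#'
#' ICC(2,1): two-way random effects, absolute agreement, single
#' measurement, with the two delineations treated as k = 2 interchangeable
#' raters measuring each subject:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' where the mean squares come from the standard two-way ANOVA
#' decomposition (rows = subjects, columns = raters). Absolute agreement is
#' the default because a systematic shift introduced by a delineation
#' change should count against robustness; `form = "3,1"` (consistency)
#' drops the rater variance term.
#'
#' @param x_baseline,x_variant numeric vectors, one value per subject
#'   (length >= 3).
#' @param form `"2,1"` (absolute agreement, default) or `"3,1"`
#'   (consistency).
#' @return The ICC estimate (may be slightly negative), or `NA` with
#'   attribute `status = "undefined"` when either vector is constant.
#' @export
icc_two_way <- function(x_baseline, x_variant, form = c("2,1", "3,1")) {
  form <- match.arg(form)
  stopifnot(length(x_baseline) == length(x_variant))
  n <- length(x_baseline)
  if (n < 3) stop("ICC requires at least 3 subjects")
  if (!all(is.finite(x_baseline)) || !all(is.finite(x_variant)))
    stop("ICC inputs must be finite")
  if (stats::sd(x_baseline) == 0 || stats::sd(x_variant) == 0) {
    out <- NA_real_
    attr(out, "status") <- "undefined"
    return(out)
  }
  k <- 2
  gm <- (mean(x_baseline) + mean(x_variant)) / 2
  subj <- (x_baseline + x_variant) / 2
  ss_rows <- k * sum((subj - gm)^2)
  ss_cols <- n * ((mean(x_baseline) - gm)^2 + (mean(x_variant) - gm)^2)
  ss_tot <- sum((x_baseline - gm)^2) + sum((x_variant - gm)^2)
  ss_err <- max(ss_tot - ss_rows - ss_cols, 0)
  ms_r <- ss_rows / (n - 1)
  ms_c <- ss_cols / (k - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  if (form == "2,1") {
    denom <- ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e)
  } else {
    denom <- ms_r + (k - 1) * ms_e
  }
  if (denom == 0) {
    out <- NA_real_
    attr(out, "status") <- "undefined"
    return(out)
  }
  (ms_r - ms_e) / denom
}

#' Per-feature ICC of a variant feature table against Baseline
#'
#' Vectorized over feature columns; subjects are matched by `subject_id`.
#'
#' @param tab_baseline,tab_variant feature tables from
#'   [cohort_feature_table()] (must share subjects).
#' @param variant variant tag recorded in the output.
#' @param feature_cols feature column names (default: all columns except
#'   `subject_id`, `label`, `split`).
#' @param form ICC form, see [icc_two_way()].
#' @return data.frame with columns `feature`, `variant`, `icc`, `status`
#'   (`ok` or `undefined`), `n_subjects`.
#' @export
icc_table <- function(tab_baseline, tab_variant, variant = NA_character_,
                      feature_cols = NULL, form = "2,1") {
  if (is.null(feature_cols))
    feature_cols <- setdiff(names(tab_baseline),
                            c("subject_id", "label", "split"))
  ord <- match(tab_baseline$subject_id, tab_variant$subject_id)
  if (anyNA(ord)) stop("tables do not share the same subjects")
  tv <- tab_variant[ord, , drop = FALSE]
  res <- vapply(feature_cols, function(f) {
    v <- icc_two_way(tab_baseline[[f]], tv[[f]], form = form)
    c(icc = as.numeric(v),
      undef = as.numeric(identical(attr(v, "status"), "undefined")))
  }, numeric(2))
  data.frame(feature = feature_cols,
             variant = variant,
             icc = res["icc", ],
             status = ifelse(res["undef", ] == 1, "undefined", "ok"),
             n_subjects = nrow(tab_baseline),
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count robust features per variant
#'
#' Features with ICC at or above the threshold (0.9 by default, the
#' "excellent robustness" rule) are counted per variant; features whose ICC
#' is undefined are excluded from the count and reported separately.
#'
#' @param icc_results data.frame as returned by [icc_table()] (rows from
#'   several variants may be concatenated).
#' @param threshold robustness cutoff on ICC.
#' @return data.frame with columns `variant`, `n_robust`, `n_defined`,
#'   `n_undefined`, `median_icc`.
#' @export
count_robust <- function(icc_results, threshold = 0.9) {
  if (NROW(icc_results) == 0) stop("empty ICC results")
  sp <- split(icc_results, icc_results$variant)
  out <- lapply(names(sp), function(v) {
    d <- sp[[v]]
    ok <- d$status == "ok" & !is.na(d$icc)
    data.frame(variant = v,
               n_robust = sum(d$icc[ok] >= threshold),
               n_defined = sum(ok),
               n_undefined = sum(!ok),
               median_icc = stats::median(d$icc[ok]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
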