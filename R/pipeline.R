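#' Pipeline run configuration
#'
#' Bundles every stage's configuration under one global seed. Stage seeds
#' are derived deterministically from `seed`, so a single integer
#' reproduces the whole run.
#'
#' @param cohort a [cohort_spec()] to simulate, or a path to an existing
#'   cohort manifest CSV.
#' @param out_dir run directory for all artifacts.
#' @param variants delineation variants to analyse (Baseline always
#'   included first).
#' @param grid an [extraction_grid()].
#' @param selection a [selection_config()] (its seed is overridden by the
#'   global seed).
#' @param model a [model_spec()] (its seed is overridden likewise).
#' @param normalize intensity-normalization method (`"zscore"`,
#'   `"landmark"` or `NULL`).
#' @param seed global integer seed.
#' @param verbose print stage progress.
#' @return A `run_config` object.
#' @export
run_config <- function(cohort, out_dir,
                       variants = variant_names(),
                       grid = extraction_grid(),
                       selection = selection_config(),
                       model = model_spec(),
                       normalize = "zscore",
                       seed = 1L, verbose = TRUE) {
  stopifnot(inherits(cohort, "cohort_spec") ||
              (is.character(cohort) && length(cohort) == 1))
  variants <- unique(c("Baseline", variants))
  stopifnot(all(variants %in% variant_names()))
  selection$seed <- as.integer(seed) + 101L
  model$seed <- as.integer(seed) + 202L
  structure(list(cohort = cohort, out_dir = out_dir, variants = variants,
                 grid = grid, selection = selection, model = model,
                 normalize = normalize, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

say <- function(cfg, fmt, ...) {
  if (cfg$verbose) message(sprintf(fmt, ...))
}

#' Validate a cohort manifest
#'
#' Diagnostic checks before a run: files exist, image and mask agree in
#' shape and spacing, masks are nonempty, labels are 0/1 and splits are
#' training/validation. Returns a machine-readable issue list; the
#' pipeline refuses to start on fatal issues.
#'
#' @param manifest_path path to a cohort manifest CSV.
#' @return data.frame with columns `subject_id`, `severity`
#'   (`fatal`/`warning`), `issue`; zero rows when the cohort is
#'   well-formed.
#' @export
validate_inputs <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop(sprintf("manifest '%s' not found", manifest_path))
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  issues <- list()
  add <- function(id, sev, msg)
    issues[[length(issues) + 1L]] <<- data.frame(
      subject_id = id, severity = sev, issue = msg,
      stringsAsFactors = FALSE)
  need <- c("subject_id", "label", "split", "image", "mask")
  if (!all(need %in% names(man))) {
    add("<manifest>", "fatal",
        sprintf("missing column(s): %s",
                paste(setdiff(need, names(man)), collapse = ", ")))
    return(do.call(rbind, issues))
  }
  for (i in seq_len(nrow(man))) {
    id <- man$subject_id[i]
    if (!man$label[i] %in% c(0, 1))
      add(id, "fatal", sprintf("label %s not in {0, 1}", man$label[i]))
    if (!man$split[i] %in% c("training", "validation"))
      add(id, "fatal", sprintf("split '%s' invalid", man$split[i]))
    ip <- file.path(base, man$image[i])
    mp <- file.path(base, man$mask[i])
    if (!file.exists(ip)) { add(id, "fatal", "image file missing"); next }
    if (!file.exists(mp)) { add(id, "fatal", "mask file missing"); next }
    img <- read_volume(ip)
    msk <- read_volume(mp, mask = TRUE)
    if (!identical(dim(img$voxels), dim(msk$voxels)))
      add(id, "fatal", "image/mask shape mismatch")
    else if (max(abs(img$spacing_mm - msk$spacing_mm)) > 1e-5)
      add(id, "fatal", "image/mask spacing mismatch")
    else if (!any(msk$voxels))
      add(id, "fatal", "empty VOI")
  }
  if (length(issues) == 0)
    data.frame(subject_id = character(0), severity = character(0),
               issue = character(0), stringsAsFactors = FALSE)
  else do.call(rbind, issues)
}

read_feature_csv <- function(path) {
  tab <- as.data.frame(data.table::fread(path, sep = ",", header = TRUE,
                                         check.names = FALSE))
  tab$subject_id <- as.character(tab$subject_id)
  tab
}

#' Run the full delineation-sensitivity study
#'
#' Orchestrates simulate (or load) -> perturb -> extract -> ICC -> select
#' -> train -> evaluate -> transfer -> report. All artifacts land under
#' `out_dir`; every stage is idempotent: artifacts already present are
#' reused byte-identically, so deleting a downstream artifact and rerunning
#' recomputes only that stage. Downstream stages always consume the
#' on-disk feature CSVs, which makes two runs with the same config and
#' seed bit-identical (report timestamps excluded).
#'
#' @param config a [run_config()].
#' @return List: `manifest`, `feature_csvs`, `icc`, `robust_counts`,
#'   `selection`, `evaluation` (data.frame mirroring the per-variant AUC /
#'   CI / p / SEN / SPE / ACCU table), `transfer` (variant x variant AUC
#'   matrix), `report_path`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  od <- config$out_dir

  # --- stage 1: cohort ----------------------------------------------------
  manifest <- file.path(od, "cohort", "manifest.csv")
  if (is.character(config$cohort)) {
    manifest <- config$cohort
  } else if (!file.exists(manifest)) {
    say(config, "[cohort] simulating %d cases",
        2L * config$cohort$n_per_class)
    spec <- config$cohort
    spec$seed <- config$seed
    write_cohort(generate_cohort(spec), file.path(od, "cohort"))
  } else say(config, "[cohort] reusing %s", manifest)
  diag <- validate_inputs(manifest)
  if (any(diag$severity == "fatal"))
    stop(sprintf("cohort validation failed: %s (subject %s)",
                 diag$issue[diag$severity == "fatal"][1],
                 diag$subject_id[diag$severity == "fatal"][1]))
  cases <- read_cohort(manifest)

  # --- stage 2+3: perturb + extract per variant ---------------------------
  feature_csvs <- character(0)
  for (v in config$variants) {
    fcsv <- file.path(od, sprintf("features_%s.csv", tolower(v)))
    if (!file.exists(fcsv)) {
      say(config, "[extract] %s (%d cases x %d features)", v,
          length(cases), n_features(config$grid))
      tab <- tryCatch(
        cohort_feature_table(cases, config$grid, v, config$normalize),
        error = function(e) stop(sprintf("stage extract/%s failed: %s",
                                         v, conditionMessage(e))))
      utils::write.csv(tab, fcsv, row.names = FALSE)
    } else say(config, "[extract] reusing %s", fcsv)
    feature_csvs[v] <- fcsv
  }
  tables <- lapply(feature_csvs, read_feature_csv)

  # --- stage 4: ICC robustness -------------------------------------------
  icc_csv <- file.path(od, "icc.csv")
  counts_json <- file.path(od, "robust_counts.json")
  if (!file.exists(icc_csv)) {
    say(config, "[icc] %d variants vs Baseline",
        length(config$variants) - 1L)
    icc_all <- do.call(rbind, lapply(
      setdiff(config$variants, "Baseline"), function(v)
        icc_table(tables$Baseline, tables[[v]], variant = v)))
    utils::write.csv(icc_all, icc_csv, row.names = FALSE)
  } else say(config, "[icc] reusing %s", icc_csv)
  icc_all <- utils::read.csv(icc_csv, stringsAsFactors = FALSE)
  robust <- count_robust(icc_all)
  jsonlite::write_json(robust, counts_json, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)

  # --- stage 5: selection per variant ------------------------------------
  selection <- list()
  for (v in config$variants) {
    sjson <- file.path(od, sprintf("selection_%s.json", tolower(v)))
    if (!file.exists(sjson)) {
      say(config, "[select] %s", v)
      sel <- select_features(tables[[v]], config$selection)
      jsonlite::write_json(
        list(variant = v, shortlist = sel$shortlist, ranked = sel$ranked,
             scores = sel$scores, mode = sel$mode,
             seed = config$selection$seed),
        sjson, auto_unbox = TRUE, digits = NA)
    } else say(config, "[select] reusing %s", sjson)
    selection[[v]] <- jsonlite::read_json(sjson, simplifyVector = TRUE)
  }

  # --- stage 6+7: incremental models + evaluation ------------------------
  models <- list()
  eval_rows <- list()
  evals <- list()
  for (v in config$variants) {
    say(config, "[train] %s", v)
    models[[v]] <- build_incremental_models(tables[[v]],
                                            selection[[v]]$ranked,
                                            config$model)
    evals[[v]] <- evaluate_model(models[[v]], tables[[v]])
  }
  for (v in config$variants) {
    dl <- if (v == "Baseline") list(p = NA_real_) else
      delong_test(evals[[v]]$scores, evals$Baseline$scores,
                  evals[[v]]$labels)
    e <- evals[[v]]
    eval_rows[[v]] <- data.frame(
      variant = v, k = models[[v]]$chosen_k, auc = e$auc,
      ci_lo = e$ci[1], ci_hi = e$ci[2], p_vs_baseline = dl$p,
      sensitivity = e$sensitivity, specificity = e$specificity,
      accuracy = e$accuracy, stringsAsFactors = FALSE)
  }
  evaluation <- do.call(rbind, c(eval_rows, list(make.row.names = FALSE)))
  utils::write.csv(evaluation, file.path(od, "evaluation.csv"),
                   row.names = FALSE)
  jsonlite::write_json(evaluation, file.path(od, "evaluation.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)

  # --- stage 8: transfer matrix ------------------------------------------
  say(config, "[transfer] %d x %d matrix", length(config$variants),
      length(config$variants))
  tm <- transfer_matrix(models, tables)
  utils::write.csv(as.data.frame(tm), file.path(od, "transfer_matrix.csv"))

  # --- stage 9: report ----------------------------------------------------
  report <- file.path(od, "report.md")
  writeLines(c(
    "# Delineation-sensitivity radiomics run",
    "",
    sprintf("- package: voirad %s",
            as.character(utils::packageVersion("voirad"))),
    sprintf("- global seed: %d", config$seed),
    sprintf("- cohort: %s", if (is.character(config$cohort))
      config$cohort else sprintf("simulated, %d per class",
                                 config$cohort$n_per_class)),
    sprintf("- features per VOI: %d", n_features(config$grid)),
    sprintf("- variants: %s", paste(config$variants, collapse = ", ")),
    "",
    "## Robust features (ICC >= 0.9)",
    "",
    sprintf("- %s: %d / %d (median ICC %.3f)", robust$variant,
            robust$n_robust, robust$n_defined, robust$median_icc),
    "",
    "## Validation performance",
    "",
    sprintf(paste0("- %s: k=%d AUC %.3f (%.3f-%.3f) p=%s SEN %.3f ",
                   "SPE %.3f ACCU %.3f"),
            evaluation$variant, evaluation$k, evaluation$auc,
            evaluation$ci_lo, evaluation$ci_hi,
            ifelse(is.na(evaluation$p_vs_baseline), "-",
                   sprintf("%.4f", evaluation$p_vs_baseline)),
            evaluation$sensitivity, evaluation$specificity,
            evaluation$accuracy)),
    report)

  list(manifest = manifest, feature_csvs = feature_csvs,
       icc = icc_all, robust_counts = robust, selection = selection,
       evaluation = evaluation, transfer = tm, report_path = report)
}
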