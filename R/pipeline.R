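#' Build a run configuration
#'
#' Collects every tunable of an end-to-end run with documented defaults.
#' Exactly one data source must be set: `feature_table`/`manifest` paths,
#' or a synthetic [cohort_config()].
#'
#' @param feature_table,manifest Paths to input CSV files, or `NULL`.
#' @param synthetic A [cohort_config()], or `NULL`.
#' @param threshold Valence-correlation selection cutoff.
#' @param redundancy_threshold Mutual-correlation pruning cutoff or `NULL`.
#' @param min_per_valence Minimum utterances per valence class per subject.
#' @param dfs A [dfs_thresholds()] object.
#' @param cost Margin penalty of the linear classifier.
#' @param baseline_top_k FS1 rank cut.
#' @param cv_unit Baseline cross-validation unit.
#' @param seed Integer seed; mandatory, every stochastic step derives
#'   from it.
#' @return An object of class `"emf_run_config"`.
#' @export
run_config <- function(feature_table = NULL, manifest = NULL,
                       synthetic = NULL, threshold = 0.7,
                       redundancy_threshold = NULL, min_per_valence = 3L,
                       dfs = dfs_thresholds(), cost = 1,
                       baseline_top_k = 100L,
                       cv_unit = c("subject", "utterance"), seed = NULL) {
  cv_unit <- match.arg(cv_unit)
  if (is.null(seed)) stop("config error: a seed must be set")
  has_files <- !is.null(feature_table) || !is.null(manifest)
  if (has_files && (is.null(feature_table) || is.null(manifest))) {
    stop("config error: both feature_table and manifest paths are required")
  }
  if (!has_files && is.null(synthetic)) {
    stop("config error: no data source (set feature_table/manifest paths ",
         "or a synthetic cohort_config)")
  }
  if (has_files && !is.null(synthetic)) {
    stop("config error: set either file paths or a synthetic config, not both")
  }
  structure(list(feature_table = feature_table, manifest = manifest,
                 synthetic = synthetic, threshold = threshold,
                 redundancy_threshold = redundancy_threshold,
                 min_per_valence = as.integer(min_per_valence),
                 dfs = dfs, cost = cost,
                 baseline_top_k = as.integer(baseline_top_k),
                 cv_unit = cv_unit, seed = as.integer(seed)),
            class = "emf_run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; `synthetic` and
#' `dfs` are nested maps passed to [cohort_config()] and
#' [dfs_thresholds()].
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's value.
#' @return An `"emf_run_config"`.
#' @export
read_run_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  syn <- if (!is.null(raw$synthetic)) do.call(cohort_config, raw$synthetic)
  dfs <- if (!is.null(raw$dfs)) do.call(dfs_thresholds, raw$dfs)
  else dfs_thresholds()
  run_config(
    feature_table = raw$feature_table, manifest = raw$manifest,
    synthetic = syn,
    threshold = raw$threshold %||% 0.7,
    redundancy_threshold = raw$redundancy_threshold,
    min_per_valence = raw$min_per_valence %||% 3L,
    dfs = dfs, cost = raw$cost %||% 1,
    baseline_top_k = raw$baseline_top_k %||% 100L,
    cv_unit = raw$cv_unit %||% "subject",
    seed = seed %||% raw$seed
  )
}

load_cohort <- function(config) {
  if (!is.null(config$synthetic)) {
    coh <- simulate_cohort(config$synthetic, seed = config$seed)
    list(table = coh$table, manifest = coh$manifest, cohort = coh)
  } else {
    list(table = read_feature_table(config$feature_table),
         manifest = read_manifest(config$manifest), cohort = NULL)
  }
}

artifact_manifest <- function(out_dir, files) {
  paths <- file.path(out_dir, files)
  ok <- file.exists(paths)
  if (!all(ok)) stop("missing artifact: ", files[!ok][1L])
  data.frame(file = files, md5 = as.character(tools::md5sum(paths)),
             stringsAsFactors = FALSE)
}

#' Run the full modulation pipeline
#'
#' Orchestrates data loading (or simulation), cohort validation,
#' valence-correlated feature selection, per-subject modulation fitting,
#' and leave-one-subject-out evaluation with the dynamic selection cascade,
#' writing every report to `out_dir`.
#'
#' @param config An [run_config()] object.
#' @param out_dir Output directory (created if absent).
#' @return An object of class `"emf_artifacts"`: list with `files` (data
#'   frame of emitted files and md5 checksums), `evaluation` (`emf_eval`)
#'   and `fit` (`emf`).
#' @export
run_emf_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "emf_run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  data <- load_cohort(config)
  fit <- emf(data$table, data$manifest, threshold = config$threshold,
             redundancy_threshold = config$redundancy_threshold,
             min_per_valence = config$min_per_valence)
  ev <- loso(fit, thresholds = config$dfs, cost = config$cost)

  write_validation_report(fit$validation,
                          file.path(out_dir, "validation.json"))
  jsonlite::write_json(
    list(names = fit$features$names, n_opt = fit$features$n_opt,
         provenance = lapply(fit$features$provenance, as.integer)),
    file.path(out_dir, "features.json"), auto_unbox = TRUE, digits = NA)
  write_emf_dataset(fit, file.path(out_dir, "emf_dataset.csv"))
  m <- ev$metrics
  jsonlite::write_json(
    list(metrics = unclass(m), subgroup_recall = ev$subgroup_recall,
         predictions = ev$predictions, seed = config$seed),
    file.path(out_dir, "evaluation.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(ev$selection_frequency),
                   file.path(out_dir, "selection_frequency.csv"))
  log_lines <- sprintf(
    "fold subject=%s n_selected=%d score=%.6g prediction=%d truth=%d",
    ev$predictions$subject_id, ev$predictions$n_selected,
    ev$predictions$score, ev$predictions$prediction, ev$predictions$truth)
  writeLines(c(sprintf("seed=%d threshold=%g n_opt=%d", config$seed,
                       config$threshold, fit$features$n_opt), log_lines),
             file.path(out_dir, "run.log"))
  files <- c("validation.json", "features.json", "emf_dataset.csv",
             "emf_dataset.json", "evaluation.json",
             "selection_frequency.csv", "run.log")
  structure(list(files = artifact_manifest(out_dir, files),
                 evaluation = ev, fit = fit, out_dir = out_dir),
            class = "emf_artifacts")
}

#' Run the modulation pipeline against the standard-paradigm baselines
#'
#' Evaluates the modulation (EMF) pipeline alongside the FS1 and FS2
#' utterance-level baselines on the identical cohort and writes a
#' side-by-side summary of balanced accuracies.
#'
#' @inheritParams run_emf_pipeline
#' @return An `"emf_artifacts"` with an additional `summary` data frame
#'   (three rows: EMF, FS1, FS2) and `baselines` list.
#' @export
run_baseline_comparison <- function(config, out_dir) {
  stopifnot(inherits(config, "emf_run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  data <- load_cohort(config)
  fit <- emf(data$table, data$manifest, threshold = config$threshold,
             redundancy_threshold = config$redundancy_threshold,
             min_per_valence = config$min_per_valence)
  ev <- loso(fit, thresholds = config$dfs, cost = config$cost)
  bl <- lapply(c("FS1", "FS2"), function(mode) {
    baseline_evaluate(data$table, data$manifest, mode = mode,
                      top_k = config$baseline_top_k,
                      threshold = config$threshold,
                      cv_unit = config$cv_unit, cost = config$cost,
                      seed = config$seed)
  })
  names(bl) <- c("FS1", "FS2")
  summary_df <- data.frame(
    model = c("EMF", "FS1", "FS2"),
    unit = c("subject", "utterance", "utterance"),
    balanced_accuracy = c(ev$metrics$balanced_accuracy,
                          bl$FS1$metrics$balanced_accuracy,
                          bl$FS2$metrics$balanced_accuracy),
    accuracy = c(ev$metrics$accuracy, bl$FS1$metrics$accuracy,
                 bl$FS2$metrics$accuracy),
    auc = c(ev$metrics$auc, bl$FS1$metrics$auc, bl$FS2$metrics$auc),
    stringsAsFactors = FALSE)
  utils::write.csv(summary_df, file.path(out_dir, "comparison.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(emf = unclass(ev$metrics),
         fs1 = unclass(bl$FS1$metrics), fs2 = unclass(bl$FS2$metrics),
         seed = config$seed),
    file.path(out_dir, "comparison.json"), auto_unbox = TRUE, digits = NA)
  files <- c("comparison.csv", "comparison.json")
  structure(list(files = artifact_manifest(out_dir, files),
                 evaluation = ev, fit = fit, baselines = bl,
                 summary = summary_df, out_dir = out_dir),
            class = "emf_artifacts")
}

#' @export
print.emf_artifacts <- function(x, ...) {
  cat("Run artifacts in ", x$out_dir, ":\n", sep = "")
  for (i in seq_len(nrow(x$files))) {
    cat("  ", x$files$file[i], "  ", x$files$md5[i], "\n", sep = "")
  }
  if (!is.null(x$summary)) {
    cat("Balanced accuracies: ",
        paste(x$summary$model, round(x$summary$balanced_accuracy, 3),
              sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
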