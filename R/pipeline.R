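#' Run the full simulate-extract-compare-classify pipeline
#'
#' End-to-end driver over the package's stages: generate a synthetic study
#' (seeded from the simulation config), write the fixture set, re-read it
#' from disk, extract the frontal features, fit the diagnostic and pooled
#' family-history ANCOVA models with LSD contrasts, apply the threshold
#' classifier, and write every table plus a manifest of output files with
#' content hashes. Re-running with the same config reproduces identical
#' hashes.
#'
#' @param sim_config a [simulation_config()].
#' @param out_dir output directory; must be creatable.
#' @param feat_config a [feature_config()].
#' @param integral_threshold,centroid_threshold_s classification cutoffs.
#' @param write_recordings also write the per-subject recording CSVs
#'   (large); when \code{FALSE} only derived tables are written and the
#'   extraction runs on the in-memory study.
#' @return Invisibly, a list with the output \code{manifest} (file MD5
#'   hashes), the feature table, model results and classification summary.
#' @export
run_pipeline <- function(sim_config = simulation_config(), out_dir,
                         feat_config = feature_config(),
                         integral_threshold = 73, centroid_threshold_s = 54,
                         write_recordings = TRUE) {
  if (missing(out_dir)) stop("out_dir is required", call. = FALSE)
  parent <- dirname(out_dir)
  if (!dir.exists(parent))
    stop("output location does not exist: ", parent, call. = FALSE)
  validate_sim_config(sim_config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  t0 <- proc.time()[["elapsed"]]
  study <- generate_study(sim_config)
  log_stage <- function(stage, start, extra = "") {
    message(sprintf("[%s] %.1f s%s", stage, proc.time()[["elapsed"]] - start,
                    if (nzchar(extra)) paste0(" - ", extra) else ""))
  }
  log_stage("simulate", t0, sprintf("%d subjects", nrow(study$cohort)))

  t1 <- proc.time()[["elapsed"]]
  if (write_recordings) {
    fx_dir <- file.path(out_dir, "fixtures")
    write_fixture_set(study$cohort, study$recordings, fx_dir)
    fx <- read_fixture_set(fx_dir)
    cohort <- fx$cohort
    recordings <- fx$recordings
  } else {
    utils::write.csv(study$cohort, file.path(out_dir, "cohort.csv"),
                     row.names = FALSE, na = "")
    cohort <- study$cohort
    recordings <- study$recordings
  }

  features <- extract_features_cohort(recordings, config = feat_config)
  utils::write.csv(features, file.path(out_dir, "features.csv"),
                   row.names = FALSE, na = "")
  excl <- features[!features$qc_pass, c("subject_id", "n_valid_channels",
                                        "exclusion_reason")]
  utils::write.csv(excl, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE, na = "")
  log_stage("extract", t1, sprintf("%d excluded", nrow(excl)))

  t2 <- proc.time()[["elapsed"]]
  models <- list()
  for (dep in c("integral_value", "centroid_value_s")) {
    fit_dx <- ancova(features, cohort, dependent = dep, grouping = "diagnosis")
    models[[paste0(dep, ".diagnosis")]] <- list(
      ancova = unclass_result(fit_dx), lsd = lsd_posthoc(fit_dx))
    fit_fh <- ancova(features, cohort, dependent = dep,
                     grouping = fh_grouping(cohort, level = "major"))
    models[[paste0(dep, ".fh_pooled")]] <- list(
      ancova = unclass_result(fit_fh), lsd = lsd_posthoc(fit_fh))
  }
  jsonlite::write_json(models, file.path(out_dir, "models.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  log_stage("compare", t2)

  t3 <- proc.time()[["elapsed"]]
  cls <- classify_subjects(features, integral_threshold, centroid_threshold_s)
  utils::write.csv(cls, file.path(out_dir, "classification.csv"),
                   row.names = FALSE, na = "")
  summary_tab <- summarize_classification(features, cohort,
                                          integral_threshold = integral_threshold,
                                          centroid_threshold_s = centroid_threshold_s)
  jsonlite::write_json(summary_tab, file.path(out_dir, "classification_summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  log_stage("classify", t3)

  files <- list.files(out_dir, recursive = TRUE, full.names = FALSE)
  files <- setdiff(files, "manifest.json")
  hashes <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(seed = sim_config$seed,
                   n_subjects = nrow(cohort),
                   files = as.list(stats::setNames(unname(hashes), files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(manifest = manifest, features = features, models = models,
                 classification_summary = summary_tab))
}

# serialisable view of an ancova_result (drop the lm object and data)
unclass_result <- function(fit) {
  fit[c("dependent", "factor_levels", "F", "df_num", "df_den", "p",
        "covariates", "n_used", "n_dropped")]
}
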