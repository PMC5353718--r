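#' Threshold-based individual classification
#'
#' Applies the two fixed cutoffs used for individual-level screening on the
#' frontal features: an integral value below 73 classifies a subject as
#' \code{"patient"} (above as \code{"non-patient"}), and a centroid latency
#' above 54 s classifies a patient-range response as
#' \code{"psychosis-spectrum"} (below as \code{"mdd-like"}). Values exactly
#' at a threshold classify as the case category (patient /
#' psychosis-spectrum), a deterministic conservative tie-break that is
#' reported in the output. An undefined centroid yields
#' \code{"indeterminate"}; quality-control failures yield NA for both
#' labels.
#'
#' @param features feature table (or a single row) from
#'   [extract_features_cohort()].
#' @param integral_threshold integral cutoff (signal units × s).
#' @param centroid_threshold_s centroid cutoff (seconds after task onset).
#' @return data.frame: \code{subject_id, patient_class, psychosis_class,
#'   tie_integral, tie_centroid}.
#' @export
#' @examples
#' row <- data.frame(subject_id = "S001", integral_value = 60,
#'                   centroid_value_s = 58, n_valid_channels = 11,
#'                   qc_pass = TRUE, exclusion_reason = NA)
#' classify_subjects(row)
classify_subjects <- function(features, integral_threshold = 73,
                              centroid_threshold_s = 54) {
  qc <- isTRUE_vec(features$qc_pass)
  int <- features$integral_value
  cen <- features$centroid_value_s

  patient <- ifelse(!qc, NA_character_,
                    ifelse(int <= integral_threshold, "patient", "non-patient"))
  psychosis <- ifelse(!qc, NA_character_,
                      ifelse(is.na(cen), "indeterminate",
                             ifelse(cen >= centroid_threshold_s,
                                    "psychosis-spectrum", "mdd-like")))
  data.frame(subject_id = features$subject_id,
             patient_class = patient,
             psychosis_class = psychosis,
             tie_integral = qc & !is.na(int) & int == integral_threshold,
             tie_centroid = qc & !is.na(cen) & cen == centroid_threshold_s,
             stringsAsFactors = FALSE)
}

#' @rdname classify_subjects
#' @param row a single feature row.
#' @return \code{classify_subject()} returns a list with
#'   \code{patient_class} and \code{psychosis_class}.
#' @export
classify_subject <- function(row, integral_threshold = 73,
                             centroid_threshold_s = 54) {
  out <- classify_subjects(row[1, , drop = FALSE], integral_threshold,
                           centroid_threshold_s)
  list(patient_class = out$patient_class, psychosis_class = out$psychosis_class)
}

#' Per-group classification summary
#'
#' Counts and percentages of quality-control-passing subjects classified
#' as patient and as psychosis-spectrum within each group; indeterminate
#' centroids are reported separately and excluded from the
#' psychosis-spectrum denominator's numerator only (the denominator is all
#' qc-passing subjects in the group). Empty groups yield an n = 0 row with
#' NA percentages.
#'
#' @param features feature table.
#' @param subjects cohort table.
#' @param grouping column name in \code{subjects} or factor (as in
#'   [ancova()]).
#' @inheritParams classify_subjects
#' @return data.frame: one row per group with \code{n},
#'   \code{n_patient, pct_patient}, \code{n_psychosis, pct_psychosis},
#'   \code{n_indeterminate}.
#' @export
summarize_classification <- function(features, subjects, grouping = "diagnosis",
                                     integral_threshold = 73,
                                     centroid_threshold_s = 54) {
  g <- if (is.character(grouping) && length(grouping) == 1L)
    subjects[[grouping]] else grouping
  if (!is.factor(g)) g <- factor(g)  # keep declared (possibly empty) levels
  cls <- classify_subjects(features, integral_threshold, centroid_threshold_s)
  dat <- merge(cls, data.frame(subject_id = subjects$id, .group = g),
               by = "subject_id")
  dat <- dat[!is.na(dat$patient_class) | !is.na(dat$psychosis_class), , drop = FALSE]

  rows <- lapply(levels(g), function(lv) {
    sub <- dat[!is.na(dat$.group) & dat$.group == lv, , drop = FALSE]
    n <- nrow(sub)
    n_pat <- sum(sub$patient_class == "patient", na.rm = TRUE)
    n_psy <- sum(sub$psychosis_class == "psychosis-spectrum", na.rm = TRUE)
    n_ind <- sum(sub$psychosis_class == "indeterminate", na.rm = TRUE)
    data.frame(group = lv, n = n,
               n_patient = n_pat,
               pct_patient = if (n > 0) 100 * n_pat / n else NA_real_,
               n_psychosis = n_psy,
               pct_psychosis = if (n > 0) 100 * n_psy / n else NA_real_,
               n_indeterminate = n_ind,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
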