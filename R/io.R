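#' Write a synthetic study to disk as plain-text fixtures
#'
#' Writes the cohort metadata table (\code{cohort.csv}, missing values as
#' empty fields), one CSV per recording under \code{recordings/} (column 1
#' time in seconds, remaining columns the channels), the generation ground
#' truth (\code{ground_truth.json}: true amplitude, latency and corrupted
#' channels per subject) and a \code{manifest.json} describing the set.
#'
#' @param cohort cohort data.frame from [generate_cohort()].
#' @param recordings list of \code{nirs_recording}, one per cohort row.
#' @param dir output directory (created recursively).
#' @return The manifest, invisibly.
#' @export
write_fixture_set <- function(cohort, recordings, dir) {
  if (nrow(cohort) != length(recordings))
    stop("need exactly one recording per subject", call. = FALSE)
  dir.create(file.path(dir, "recordings"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(file.path(dir, "recordings")))
    stop("cannot create fixture directory: ", dir, call. = FALSE)

  utils::write.csv(cohort, file.path(dir, "cohort.csv"), row.names = FALSE, na = "")

  rec_files <- character(length(recordings))
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    n_samp <- ncol(rec$channels)
    tab <- data.frame(time_s = (seq_len(n_samp) - 1) * rec$sampling_interval_s)
    chans <- t(rec$channels)
    colnames(chans) <- sprintf("ch%02d", seq_len(nrow(rec$channels)))
    rec_files[i] <- file.path("recordings", paste0(rec$subject_id, ".csv"))
    utils::write.csv(cbind(tab, chans), file.path(dir, rec_files[i]),
                     row.names = FALSE)
  }

  truth <- lapply(recordings, function(rec) list(
    subject_id = rec$subject_id,
    true_amplitude = rec$true_amplitude,
    true_latency_s = rec$true_latency_s,
    artifact_channels = as.integer(rec$artifact_channels)
  ))
  names(truth) <- vapply(recordings, `[[`, "", "subject_id")
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)

  first <- recordings[[1]]
  manifest <- list(
    n_subjects = nrow(cohort),
    subject_ids = cohort$id,
    sampling_interval_s = first$sampling_interval_s,
    task_onset_s = first$task_onset_s,
    task_offset_s = first$task_offset_s,
    end_s = first$end_s,
    cohort_file = "cohort.csv",
    ground_truth_file = "ground_truth.json",
    recording_files = as.list(stats::setNames(rec_files, cohort$id))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a recording from a delimited text file
#'
#' Accepts the fixture dialect written by [write_fixture_set()]: first
#' column time in seconds, remaining columns one channel each. Files
#' ending in \code{.tsv} (or \code{.txt}) are read as tab-separated.
#' Task-event timing is not stored in the table and must be supplied (or
#' comes from the set's manifest via [read_fixture_set()]).
#'
#' @param path CSV/TSV file path.
#' @param task_onset_s,task_offset_s task onset/offset in seconds.
#' @param subject_id subject identifier; default the file base name.
#' @return A \code{nirs_recording} (without simulation ground truth).
#' @export
read_recording <- function(path, task_onset_s = 10, task_offset_s = 70,
                           subject_id = NULL) {
  if (!file.exists(path)) stop("recording file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  tab <- tryCatch(utils::read.table(path, header = TRUE, sep = sep),
                  error = function(e) stop("malformed recording file ", path,
                                           ": ", conditionMessage(e), call. = FALSE))
  if (ncol(tab) < 2 || nrow(tab) < 2)
    stop("malformed recording file ", path,
         ": need a time column plus at least one channel", call. = FALSE)
  t_s <- tab[[1]]
  dt <- stats::median(diff(t_s))
  if (!is.finite(dt) || dt <= 0)
    stop("malformed recording file ", path, ": non-increasing time column",
         call. = FALSE)
  structure(list(
    subject_id = if (is.null(subject_id)) sub("\\.[^.]+$", "", basename(path)) else subject_id,
    sampling_interval_s = dt,
    channels = t(as.matrix(tab[, -1, drop = FALSE])),
    deoxy = NULL,
    task_onset_s = task_onset_s,
    task_offset_s = task_offset_s,
    end_s = t_s[length(t_s)] + dt,
    artifact_channels = integer(),
    true_amplitude = NA_real_,
    true_latency_s = NA_real_
  ), class = "nirs_recording")
}

#' Read a fixture set written by [write_fixture_set()]
#'
#' @param dir fixture directory containing \code{manifest.json}.
#' @return A list with \code{cohort}, \code{recordings}, \code{ground_truth}
#'   and \code{manifest}.
#' @export
read_fixture_set <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json under ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  cohort <- read_cohort(file.path(dir, manifest$cohort_file))
  truth <- jsonlite::read_json(file.path(dir, manifest$ground_truth_file),
                               simplifyVector = TRUE)
  recordings <- lapply(cohort$id, function(id) {
    rec <- read_recording(file.path(dir, manifest$recording_files[[id]]),
                          task_onset_s = manifest$task_onset_s,
                          task_offset_s = manifest$task_offset_s,
                          subject_id = id)
    gt <- truth[[id]]
    rec$artifact_channels <- as.integer(gt$artifact_channels)
    rec$true_amplitude <- gt$true_amplitude
    rec$true_latency_s <- gt$true_latency_s
    rec
  })
  names(recordings) <- cohort$id
  list(cohort = cohort, recordings = recordings, ground_truth = truth,
       manifest = manifest)
}

#' Read a cohort metadata CSV
#'
#' Restores the column types written by [write_fixture_set()] (factors for
#' diagnosis/gender/handedness, logicals for the family-history flags;
#' empty fields become NA).
#'
#' @param path CSV file path.
#' @return Cohort data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  tab$diagnosis <- factor(tab$diagnosis, levels = c("HC", "SCZ", "MDD", "BIP"))
  tab$gender <- factor(tab$gender, levels = c("male", "female"))
  tab$handedness <- factor(tab$handedness, levels = c("right", "left", "bilateral"))
  for (f in c("fh_any", "fh_major", "fh_same")) tab[[f]] <- as.logical(tab[[f]])
  tab
}
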