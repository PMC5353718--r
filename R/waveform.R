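#' Frontal channel cluster
#'
#' The 11 measurement channels (1-based indices 25-28, 36-38 and 46-49 on
#' the 52-channel probe layout) averaged into the frontal region-of-interest
#' signal.
#'
#' @return Integer vector of channel indices.
#' @export
frontal_channels <- function() c(25:28, 36:38, 46:49)

#' Read a channel-cluster definition file
#'
#' A JSON array of 1-based channel indices.
#'
#' @param path JSON file path.
#' @return Integer vector of channel indices.
#' @export
read_cluster_definition <- function(path) {
  if (!file.exists(path)) stop("cluster file not found: ", path, call. = FALSE)
  idx <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.numeric(idx) || !length(idx) || any(idx < 1) || any(idx != round(idx)))
    stop("cluster file must hold a non-empty array of positive channel indices",
         call. = FALSE)
  as.integer(idx)
}

#' Feature-extraction configuration
#'
#' @param jump_k bad-channel threshold: a channel is flagged when its
#'   largest absolute sample-to-sample jump exceeds \code{jump_k} times the
#'   raw (unscaled) median absolute deviation of its first differences.
#' @param min_valid_channels minimum usable frontal channels; subjects with
#'   fewer are excluded from analysis (study rule: fewer than 6).
#' @param baseline_mode \code{"prepost"} subtracts the line through the
#'   pre-task mean and the mean of the final seconds of the post-task
#'   window; \code{"pre"} subtracts the pre-task mean only.
#' @param pre_baseline_s,post_baseline_s lengths (s) of the pre-task and
#'   end-of-post-task baseline windows.
#' @param smooth_width_s optional moving-average width (s) applied to the
#'   clustered signal; 0 disables smoothing.
#' @return A list of class \code{"feature_config"}.
#' @export
feature_config <- function(jump_k = 10, min_valid_channels = 6,
                           baseline_mode = c("prepost", "pre"),
                           pre_baseline_s = 10, post_baseline_s = 5,
                           smooth_width_s = 0) {
  structure(list(jump_k = jump_k,
                 min_valid_channels = min_valid_channels,
                 baseline_mode = match.arg(baseline_mode),
                 pre_baseline_s = pre_baseline_s,
                 post_baseline_s = post_baseline_s,
                 smooth_width_s = smooth_width_s),
            class = "feature_config")
}

#' Detect artifact-corrupted or dead channels
#'
#' A channel is flagged when (a) its variance is zero (dead channel), or
#' (b) its largest absolute first difference exceeds \code{jump_k} times
#' the raw median absolute deviation (consistency constant 1) of its first
#' differences - a scale-free detector for step discontinuities and spikes
#' that is insensitive to the smooth hemodynamic response.
#'
#' @param recording a \code{nirs_recording}.
#' @param cluster channel indices to screen (default the frontal cluster).
#' @param jump_k jump threshold multiplier.
#' @return Sorted integer vector of bad channel indices (subset of
#'   \code{cluster}).
#' @export
detect_bad_channels <- function(recording, cluster = frontal_channels(),
                                jump_k = 10) {
  if (length(cluster) == 0) stop("cluster must contain at least one channel",
                                 call. = FALSE)
  if (any(cluster < 1 | cluster > nrow(recording$channels)))
    stop("cluster indices outside the recording's channel range", call. = FALSE)
  bad <- vapply(cluster, function(ch) {
    x <- recording$channels[ch, ]
    if (stats::var(x) == 0) return(TRUE)
    d <- diff(x)
    m <- stats::mad(d, constant = 1)
    if (m == 0) return(any(d != 0))
    max(abs(d)) > jump_k * m
  }, logical(1))
  sort(cluster[bad])
}

#' Baseline-correct a signal
#'
#' In \code{"prepost"} mode, subtracts the straight line through the two
#' anchor points (mean time, mean signal) of the pre-task window and of the
#' late post-task window, removing both offset and linear drift; the
#' corrected pre-task mean is zero up to floating point. In \code{"pre"}
#' mode, subtracts the pre-task mean only.
#'
#' @param signal numeric vector over the full measurement.
#' @param pre_window,post_window integer sample indices of the two baseline
#'   windows (each at least 2 samples; \code{post_window} ignored in
#'   \code{"pre"} mode).
#' @param mode \code{"prepost"} or \code{"pre"}.
#' @return The corrected signal.
#' @export
baseline_correct <- function(signal, pre_window, post_window = NULL,
                             mode = c("prepost", "pre")) {
  mode <- match.arg(mode)
  check_window <- function(w, what) {
    if (length(w) < 2) stop(what, " must span at least 2 samples", call. = FALSE)
    if (any(w < 1 | w > length(signal)))
      stop(what, " lies outside the signal extent", call. = FALSE)
  }
  check_window(pre_window, "pre_window")
  if (mode == "pre") return(signal - mean(signal[pre_window]))
  check_window(post_window, "post_window")
  t1 <- mean(pre_window); v1 <- mean(signal[pre_window])
  t2 <- mean(post_window); v2 <- mean(signal[post_window])
  slope <- (v2 - v1) / (t2 - t1)
  signal - (v1 + slope * (seq_along(signal) - t1))
}

#' Average the frontal cluster into one region-of-interest waveform
#'
#' Baseline-corrects each usable cluster channel and takes their unweighted
#' mean. An empty usable set yields a quality-control-failure waveform
#' (all-NA signal, zero valid channels), not an error.
#'
#' @param recording a \code{nirs_recording}.
#' @param cluster channel indices of the region cluster.
#' @param bad channel indices to exclude (from [detect_bad_channels()]).
#' @param config a [feature_config()].
#' @return An object of class \code{frontal_waveform}: list with
#'   \code{subject_id}, \code{sampling_interval_s}, \code{signal},
#'   \code{n_valid_channels}, \code{task_onset_index},
#'   \code{task_offset_index}.
#' @export
cluster_frontal <- function(recording, cluster = frontal_channels(),
                            bad = integer(), config = feature_config()) {
  dt <- recording$sampling_interval_s
  n_samp <- ncol(recording$channels)
  onset_idx <- round(recording$task_onset_s / dt) + 1L
  offset_idx <- round(recording$task_offset_s / dt) + 1L
  good <- setdiff(cluster, bad)

  if (length(good) == 0) {
    signal <- rep(NA_real_, n_samp)
  } else {
    n_pre <- max(2L, round(config$pre_baseline_s / dt))
    pre_window <- seq_len(min(n_pre, onset_idx - 1L))
    n_post <- max(2L, round(config$post_baseline_s / dt))
    post_window <- seq.int(n_samp - n_post + 1L, n_samp)
    corrected <- vapply(good, function(ch)
      baseline_correct(recording$channels[ch, ], pre_window, post_window,
                       mode = config$baseline_mode),
      numeric(n_samp))
    signal <- rowMeans(corrected)
    if (config$smooth_width_s > 0) {
      w <- max(1L, round(config$smooth_width_s / dt))
      signal <- as.numeric(stats::filter(signal, rep(1 / w, w), sides = 2))
    }
  }

  structure(list(subject_id = recording$subject_id,
                 sampling_interval_s = dt,
                 signal = signal,
                 n_valid_channels = length(good),
                 task_onset_index = onset_idx,
                 task_offset_index = offset_idx),
            class = "frontal_waveform")
}

#' Task-period integral of the frontal waveform
#'
#' Trapezoidal integral of the baseline-corrected region signal from task
#' onset to task offset, in signal units × seconds. Signed: negative
#' deflections subtract.
#'
#' @param w a \code{frontal_waveform}.
#' @return The integral value.
#' @export
compute_integral <- function(w) {
  idx <- w$task_onset_index:w$task_offset_index
  x <- w$signal[idx]
  dt <- w$sampling_interval_s
  dt * (sum(x) - (x[1] + x[length(x)]) / 2)
}

#' Half-area centroid latency of the frontal waveform
#'
#' Considers only positive signal values from task onset through the end
#' of the post-task window. Returns the time (seconds after task onset) at
#' which the cumulative positive area (trapezoid rule) first reaches half
#' of the total positive area, with linear interpolation of cumulative
#' area between the bracketing samples; a tie at exactly half resolves to
#' the earliest crossing. A waveform with no positive area has an
#' undefined centroid and yields \code{NA} (flagged downstream, not an
#' error).
#'
#' @param w a \code{frontal_waveform}.
#' @return Centroid latency in seconds after task onset, or \code{NA_real_}.
#' @export
compute_centroid <- function(w) {
  idx <- w$task_onset_index:length(w$signal)
  pos <- pmax(w$signal[idx], 0)
  dt <- w$sampling_interval_s
  seg <- dt * (pos[-length(pos)] + pos[-1]) / 2
  cum <- cumsum(seg)
  total <- cum[length(cum)]
  if (!is.finite(total) || total <= 0) return(NA_real_)
  half <- total / 2
  j <- which(cum >= half)[1]
  prev <- if (j == 1L) 0 else cum[j - 1L]
  frac <- if (seg[j] > 0) (half - prev) / seg[j] else 0
  (j - 1L + frac) * dt
}

#' Extract the frontal integral and centroid features for one recording
#'
#' Chains bad-channel detection, baseline correction, frontal-cluster
#' averaging and the two waveform statistics, applying the study's
#' exclusion rule: a subject with fewer than \code{min_valid_channels}
#' usable frontal channels is marked \code{qc_pass = FALSE} with reason
#' \code{"insufficient_channels"} and no feature values.
#'
#' @param recording a \code{nirs_recording}.
#' @param cluster frontal channel indices.
#' @param config a [feature_config()].
#' @return One-row data.frame: \code{subject_id, integral_value,
#'   centroid_value_s, n_valid_channels, qc_pass, exclusion_reason}.
#' @export
extract_features <- function(recording, cluster = frontal_channels(),
                             config = feature_config()) {
  bad <- detect_bad_channels(recording, cluster, jump_k = config$jump_k)
  w <- cluster_frontal(recording, cluster, bad, config)
  if (w$n_valid_channels < config$min_valid_channels) {
    return(data.frame(subject_id = recording$subject_id,
                      integral_value = NA_real_,
                      centroid_value_s = NA_real_,
                      n_valid_channels = w$n_valid_channels,
                      qc_pass = FALSE,
                      exclusion_reason = "insufficient_channels",
                      stringsAsFactors = FALSE))
  }
  data.frame(subject_id = recording$subject_id,
             integral_value = compute_integral(w),
             centroid_value_s = compute_centroid(w),
             n_valid_channels = w$n_valid_channels,
             qc_pass = TRUE,
             exclusion_reason = NA_character_,
             stringsAsFactors = FALSE)
}

#' Extract features for a list of recordings
#'
#' @param recordings list of \code{nirs_recording}.
#' @inheritParams extract_features
#' @return data.frame with one row per recording (see [extract_features()]).
#' @export
extract_features_cohort <- function(recordings, cluster = frontal_channels(),
                                    config = feature_config()) {
  rows <- lapply(recordings, extract_features, cluster = cluster, config = config)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
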