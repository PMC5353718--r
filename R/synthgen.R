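#' Hemodynamic response kernel for the verbal-fluency block design
#'
#' Piecewise linear-rise / plateau / exponential-decay template: zero before
#' the (possibly delayed) response onset, a linear ramp to \code{amplitude}
#' over \code{rise_s} seconds, a plateau for the remainder of the task
#' block, and an exponential return toward zero with time constant
#' \code{decay_tau_s} after task offset. A latency shift translates the
#' whole template in time, so
#' \code{response_kernel(t, A, L) == response_kernel(t - L, A, 0)}.
#'
#' @param t_s time in seconds relative to task onset (vectorised).
#' @param amplitude plateau amplitude (signal units).
#' @param latency_shift_s delay of the response onset (s), non-negative.
#' @param task_s task-block duration (s).
#' @param rise_s ramp duration (s).
#' @param decay_tau_s decay time constant (s).
#' @return Numeric vector of kernel values, same length as \code{t_s}.
#' @export
#' @examples
#' t <- seq(-10, 115, by = 0.1)
#' k <- response_kernel(t, amplitude = 1, latency_shift_s = 0)
#' range(k)
response_kernel <- function(t_s, amplitude, latency_shift_s = 0,
                            task_s = 60, rise_s = 15, decay_tau_s = 15) {
  u <- t_s - latency_shift_s
  out <- numeric(length(u))
  ramp <- u >= 0 & u < rise_s
  out[ramp] <- amplitude * u[ramp] / rise_s
  plat <- u >= rise_s & u <= task_s
  out[plat] <- amplitude
  dec <- u > task_s
  out[dec] <- amplitude * exp(-(u[dec] - task_s) / decay_tau_s)
  out
}

#' Closed-form area of the response kernel over the task window
#'
#' Integral of [response_kernel()] over task-relative time
#' \code{[0, task_s]}. For a latency shift L with
#' \code{L + rise_s <= task_s} this equals
#' \code{amplitude * (task_s - L - rise_s / 2)}; partial-ramp cases are
#' handled by clipping. Serves as the analytic reference for noise-free
#' feature extraction and effect-size calibration.
#'
#' @inheritParams response_kernel
#' @return The task-window area (signal units × s).
#' @export
kernel_task_area <- function(amplitude, latency_shift_s = 0,
                             task_s = 60, rise_s = 15, decay_tau_s = 15) {
  L <- latency_shift_s
  a <- max(0, min(L, task_s))
  b <- max(0, min(L + rise_s, task_s))
  ramp_area <- if (b > a) amplitude / (2 * rise_s) * ((b - L)^2 - (a - L)^2) else 0
  plateau_area <- amplitude * max(0, task_s - (L + rise_s))
  ramp_area + plateau_area
}

# Group demographic targets (mean, sd) or category counts that the cohort
# generator reproduces; only used as covariates downstream, so shapes are
# truncated normals / exact-count categoricals.
demographic_targets <- function() {
  list(
    age = list(SCZ = c(35.4, 9.1), MDD = c(41.1, 12.7), BIP = c(39.9, 12.5), HC = c(35.7, 11.9)),
    education = list(SCZ = c(13.2, 1.3), MDD = c(14.3, 2.6), BIP = c(14.7, 2.3), HC = c(16.7, 2.5)),
    premorbid_iq = list(SCZ = c(101.3, 11.6), MDD = c(104.6, 9.2), BIP = c(110.2, 6.2), HC = c(110.0, 6.2)),
    performance = list(SCZ = c(13.0, 5.4), MDD = c(15.7, 5.3), BIP = c(16.9, 5.3), HC = c(15.3, 4.7)),
    cpz_eq = list(SCZ = c(465.3, 407.3), MDD = c(51.4, 88.6), BIP = c(76.7, 131.8)),
    onset_age = list(SCZ = c(25.5, 6.4), MDD = c(33.8, 13.5), BIP = c(30.6, 9.3)),
    male_fraction = c(SCZ = 16 / 45, MDD = 17 / 26, BIP = 13 / 22, HC = 33 / 51),
    handedness_counts = list(SCZ = c(right = 40, left = 3, bilateral = 2),
                             MDD = c(right = 24, left = 2, bilateral = 0),
                             BIP = c(right = 19, left = 1, bilateral = 2),
                             HC = c(right = 46, left = 4, bilateral = 1)),
    symptom = list(SCZ = list(scale = "panss_total", mean = 70, sd = 18),
                   MDD = list(scale = "hamd17", mean = 15, sd = 6),
                   BIP = list(scale = "ymrs", mean = 10, sd = 7))
  )
}

rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Generate a synthetic cohort
#'
#' Draws one subject table under a [simulation_config()]: diagnoses at the
#' configured group sizes, nested family-history indicators with
#' \code{round(fraction * n)} positives per diagnosis, and demographics
#' (age, gender, education, premorbid IQ, handedness, task performance,
#' medication, illness onset, symptom scores) from truncated-normal or
#' exact-count distributions matching the emulated study's group
#' summaries. Healthy controls carry no positive family history and no
#' medication or illness-course fields. Uses the session RNG; seed it (or
#' use [generate_study()]) for reproducibility.
#'
#' @param config a \code{sim_config}.
#' @return A data.frame, one row per subject: \code{id}, \code{diagnosis}
#'   (factor HC/SCZ/MDD/BIP), \code{fh_any}, \code{fh_major},
#'   \code{fh_same} (logical; NA = unknown), \code{age_years},
#'   \code{gender}, \code{education_years}, \code{premorbid_iq},
#'   \code{handedness}, \code{vft_performance}, \code{cpz_eq_mg_day},
#'   \code{onset_age_years}, \code{illness_duration_years}, symptom-score
#'   columns, and \code{sim_group}, the amplitude/latency group label used
#'   by [generate_recording()].
#' @export
generate_cohort <- function(config = simulation_config()) {
  validate_sim_config(config)
  tg <- demographic_targets()
  out <- list()
  for (dx in names(config$group_sizes)) {
    n <- as.integer(config$group_sizes[[dx]])
    if (n == 0L) next

    # nested family-history indicators: same => major => any
    k_any <- round(config$fh_any_fraction[[dx]] * n)
    k_major <- min(k_any, round(config$fh_major_fraction[[dx]] * n))
    k_same <- min(k_major, round(config$fh_same_fraction[[dx]] * n))
    ord <- sample.int(n)
    fh_any <- fh_major <- fh_same <- rep(FALSE, n)
    fh_any[ord[seq_len(k_any)]] <- TRUE
    fh_major[ord[seq_len(k_major)]] <- TRUE
    fh_same[ord[seq_len(k_same)]] <- TRUE
    if (dx != "HC" && config$fh_unknown_rate > 0) {
      unk <- stats::runif(n) < config$fh_unknown_rate
      fh_any[unk] <- fh_major[unk] <- fh_same[unk] <- NA
    }

    age <- rnorm_trunc(n, tg$age[[dx]][1], tg$age[[dx]][2], 18, 75)
    n_male <- round(tg$male_fraction[[dx]] * n)
    gender <- sample(rep(c("male", "female"), c(n_male, n - n_male)))
    hc_counts <- tg$handedness_counts[[dx]]
    handedness <- sample(names(hc_counts), n, replace = TRUE, prob = hc_counts / sum(hc_counts))
    edu <- rnorm_trunc(n, tg$education[[dx]][1], tg$education[[dx]][2], 9, 22)
    iq <- rnorm_trunc(n, tg$premorbid_iq[[dx]][1], tg$premorbid_iq[[dx]][2], 70, 135)
    perf <- round(rnorm_trunc(n, tg$performance[[dx]][1], tg$performance[[dx]][2], 2, 35))

    if (dx == "HC") {
      cpz <- onset <- duration <- rep(NA_real_, n)
    } else {
      cpz <- rnorm_trunc(n, tg$cpz_eq[[dx]][1], tg$cpz_eq[[dx]][2], 0, 2500)
      onset <- pmin(rnorm_trunc(n, tg$onset_age[[dx]][1], tg$onset_age[[dx]][2], 12, 65),
                    age - 0.5)
      duration <- age - onset
    }

    panss <- hamd <- ymrs <- rep(NA_real_, n)
    if (dx != "HC") {
      sy <- tg$symptom[[dx]]
      score <- rnorm_trunc(n, sy$mean, sy$sd, 0, Inf)
      if (sy$scale == "panss_total") panss <- score
      if (sy$scale == "hamd17") hamd <- score
      if (sy$scale == "ymrs") ymrs <- score
    }

    sim_group <- if (dx == "HC") rep("HC", n) else
      paste0(dx, ifelse(!is.na(fh_any) & fh_any, "+", "-"))

    out[[dx]] <- data.frame(
      id = NA_character_, diagnosis = dx,
      fh_any = fh_any, fh_major = fh_major, fh_same = fh_same,
      age_years = age, gender = gender, education_years = edu,
      premorbid_iq = iq, handedness = handedness, vft_performance = perf,
      cpz_eq_mg_day = cpz, onset_age_years = onset,
      illness_duration_years = duration,
      panss_total = panss, hamd17 = hamd, ymrs = ymrs,
      sim_group = sim_group,
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    cohort <- generate_cohort_template()
  } else {
    cohort <- do.call(rbind, out)
    rownames(cohort) <- NULL
    cohort$id <- sprintf("S%03d", seq_len(nrow(cohort)))
  }
  cohort$diagnosis <- factor(cohort$diagnosis, levels = c("HC", "SCZ", "MDD", "BIP"))
  cohort$gender <- factor(cohort$gender, levels = c("male", "female"))
  cohort$handedness <- factor(cohort$handedness, levels = c("right", "left", "bilateral"))
  cohort
}

# zero-row cohort with the full column schema
generate_cohort_template <- function() {
  data.frame(id = character(), diagnosis = character(),
             fh_any = logical(), fh_major = logical(), fh_same = logical(),
             age_years = numeric(), gender = character(),
             education_years = numeric(), premorbid_iq = numeric(),
             handedness = character(), vft_performance = numeric(),
             cpz_eq_mg_day = numeric(), onset_age_years = numeric(),
             illness_duration_years = numeric(), panss_total = numeric(),
             hamd17 = numeric(), ymrs = numeric(), sim_group = character(),
             stringsAsFactors = FALSE)
}

#' Generate one subject's multi-channel recording
#'
#' Every channel carries the subject's hemodynamic response kernel
#' (plateau amplitude and onset latency each drawn once per subject from
#' the group's \code{Normal(amplitude_mean, amplitude_sd)} and
#' \code{Normal(latency_shift_s, latency_sd_s)}, latency truncated at
#' zero) plus i.i.d. Gaussian noise. Channels selected as
#' artifacts (probability \code{artifact_channel_rate}) additionally get a
#' large step discontinuity (\code{artifact_step_scale} × noise SD) and
#' three spikes at about twice that height; their indices are kept as
#' ground truth. Uses the session RNG.
#'
#' @param subject one cohort row (data.frame or list) with at least
#'   \code{id} and \code{sim_group}.
#' @param config a \code{sim_config}.
#' @return An object of class \code{nirs_recording}: a list with
#'   \code{subject_id}, \code{sampling_interval_s}, \code{channels}
#'   (matrix, channels × samples), \code{task_onset_s}, \code{task_offset_s},
#'   \code{end_s}, and ground truth \code{artifact_channels},
#'   \code{true_amplitude}, \code{true_latency_s}.
#' @export
generate_recording <- function(subject, config = simulation_config()) {
  label <- as.character(subject$sim_group)
  if (!label %in% names(config$amplitude_mean))
    stop("no amplitude configured for simulation group ", label, call. = FALSE)
  dt <- config$sampling_interval_s
  n_samp <- round((config$pre_s + config$task_s + config$post_s) / dt)
  t_s <- (seq_len(n_samp) - 1) * dt

  amplitude <- stats::rnorm(1, config$amplitude_mean[[label]], config$amplitude_sd)
  latency <- max(0, stats::rnorm(1, config$latency_shift_s[[label]],
                                 config$latency_sd_s))
  kernel <- response_kernel(t_s - config$pre_s, amplitude, latency,
                            task_s = config$task_s, rise_s = config$rise_s,
                            decay_tau_s = config$decay_tau_s)

  nc <- config$n_channels
  channels <- matrix(stats::rnorm(nc * n_samp, sd = config$noise_sd),
                     nrow = nc, ncol = n_samp)
  channels <- sweep(channels, 2, kernel, `+`)

  artifact_channels <- which(stats::runif(nc) < config$artifact_channel_rate)
  step <- config$artifact_step_scale * config$noise_sd
  for (ch in artifact_channels) {
    at <- sample.int(n_samp - 2, 1) + 1
    channels[ch, at:n_samp] <- channels[ch, at:n_samp] + sample(c(-1, 1), 1) * step
    spikes <- sample.int(n_samp, 3)
    channels[ch, spikes] <- channels[ch, spikes] +
      sample(c(-1, 1), 3, replace = TRUE) * 2 * step
  }

  structure(list(
    subject_id = as.character(subject$id),
    sampling_interval_s = dt,
    channels = channels,
    deoxy = NULL,
    task_onset_s = config$pre_s,
    task_offset_s = config$pre_s + config$task_s,
    end_s = config$pre_s + config$task_s + config$post_s,
    artifact_channels = artifact_channels,
    true_amplitude = amplitude,
    true_latency_s = latency
  ), class = "nirs_recording")
}

#' @export
print.nirs_recording <- function(x, ...) {
  cat(sprintf("NIRS recording %s: %d channels x %d samples (dt = %g s)\n",
              x$subject_id, nrow(x$channels), ncol(x$channels),
              x$sampling_interval_s))
  cat(sprintf("  task %g-%g s of %g s; %d artifact channel(s)\n",
              x$task_onset_s, x$task_offset_s, x$end_s,
              length(x$artifact_channels)))
  invisible(x)
}

#' Generate a full synthetic study (cohort plus recordings)
#'
#' Seeds the RNG from \code{config$seed} and draws the cohort and one
#' recording per subject, so identical configs give bit-identical studies.
#'
#' @param config a \code{sim_config}.
#' @return A list with \code{cohort} (data.frame), \code{recordings}
#'   (named list of \code{nirs_recording}) and \code{config}.
#' @export
generate_study <- function(config = simulation_config()) {
  set.seed(config$seed)
  cohort <- generate_cohort(config)
  recordings <- lapply(seq_len(nrow(cohort)),
                       function(i) generate_recording(cohort[i, ], config))
  names(recordings) <- cohort$id
  list(cohort = cohort, recordings = recordings, config = config)
}
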