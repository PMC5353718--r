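#' Simulation configuration for synthetic verbal-fluency cohorts
#'
#' Builds and validates the parameter set that drives cohort and recording
#' generation. Defaults reproduce the structure of the emulated study:
#' four diagnostic groups (schizophrenia, major depressive disorder,
#' bipolar disorder, healthy controls) of sizes 45/26/22/51; a 10 s
#' pre-task / 60 s task / 55 s post-task block design sampled at 0.1 s;
#' 52 measurement channels of which an 11-channel frontal cluster is
#' analysed; and group-dependent activation amplitude and response latency
#' with additive Gaussian channel noise and occasional artifact-corrupted
#' channels.
#'
#' Activation parameters are keyed by simulation group label: \code{"HC"}
#' for controls and \code{"<DX>+"} / \code{"<DX>-"} for patients with and
#' without a positive psychiatric family history. Amplitudes are in the
#' signal's arbitrary concentration-change units (mM·mm convention);
#' latencies in seconds added to the response onset. The default
#' amplitudes are solved numerically so that each subgroup's task-period
#' integral distribution (amplitude × kernel task-window area, which
#' shrinks with latency; variance from amplitude spread, latency jitter
#' and channel noise) sits at the emulated study's standardized gap versus
#' controls given the subgroup sizes; the default latency means and SD
#' place every group's centroid distribution near the 54-s classification
#' cutoff, with the psychosis-spectrum groups delayed relative to the
#' depression group and family-history-positive subgroups delayed by
#' about 0.6 SD relative to their negative counterparts. See the methods
#' vignette for the derivation.
#'
#' Family-history fractions are nested per subject: same-disorder implies
#' major-psychiatric implies any-psychiatric. Within each diagnosis,
#' \code{round(fraction * n)} subjects are flagged positive at each level.
#'
#' @param group_sizes named integer vector of subjects per diagnosis
#'   (names among SCZ, MDD, BIP, HC).
#' @param fh_any_fraction,fh_major_fraction,fh_same_fraction named numeric
#'   vectors in [0,1]: per-diagnosis fraction with a positive family history
#'   of (i) any psychiatric disorder, (ii) any major psychiatric disorder,
#'   (iii) the same disorder. Must be nested (same <= major <= any).
#' @param fh_unknown_rate probability that a patient's family history is
#'   recorded as unknown (all three indicators NA).
#' @param amplitude_mean named numeric vector of mean activation amplitudes
#'   per simulation group label.
#' @param amplitude_sd between-subject SD of the activation amplitude.
#' @param latency_shift_s named numeric vector of mean response-onset
#'   delays (s) per simulation group label.
#' @param latency_sd_s between-subject SD of the response latency (s);
#'   per-subject latencies are truncated at zero. This is the dominant
#'   source of within-group centroid variance.
#' @param noise_sd SD of the i.i.d. Gaussian channel noise per sample.
#' @param artifact_channel_rate probability that a channel is corrupted by
#'   a step-plus-spikes artifact.
#' @param artifact_step_scale artifact step height in multiples of
#'   \code{noise_sd}; spikes are generated at about twice this scale.
#' @param sampling_interval_s sampling interval in seconds per sample.
#' @param n_channels number of recorded channels (instrument default 52).
#' @param rise_s linear rise time of the response kernel (s).
#' @param decay_tau_s exponential decay time constant after task offset (s).
#' @param seed integer seed used by [generate_study()].
#'
#' @return An object of class \code{"sim_config"} (a named list).
#' @seealso [generate_cohort()], [generate_recording()], [generate_study()]
#' @export
#' @examples
#' cfg <- simulation_config()
#' sum(cfg$group_sizes)  # 144 subjects
simulation_config <- function(group_sizes = c(SCZ = 45L, MDD = 26L, BIP = 22L, HC = 51L),
                              fh_any_fraction = c(SCZ = 17 / 45, MDD = 10 / 26, BIP = 10 / 22, HC = 0),
                              fh_major_fraction = c(SCZ = 15 / 45, MDD = 3 / 26, BIP = 7 / 22, HC = 0),
                              fh_same_fraction = c(SCZ = 8 / 45, MDD = 2 / 26, BIP = 3 / 22, HC = 0),
                              fh_unknown_rate = 0,
                              amplitude_mean = c(HC = 2.593,
                                                 `SCZ+` = 2.159, `SCZ-` = 2.431,
                                                 `MDD+` = 1.927, `MDD-` = 2.175,
                                                 `BIP+` = 2.461, `BIP-` = 1.901),
                              amplitude_sd = 0.5,
                              latency_shift_s = c(HC = 12,
                                                  `SCZ+` = 17, `SCZ-` = 14,
                                                  `MDD+` = 13, `MDD-` = 13,
                                                  `BIP+` = 17, `BIP-` = 14),
                              latency_sd_s = 5,
                              noise_sd = 0.5,
                              artifact_channel_rate = 0.02,
                              artifact_step_scale = 12,
                              sampling_interval_s = 0.1,
                              n_channels = 52L,
                              rise_s = 15,
                              decay_tau_s = 15,
                              seed = 1L) {
  cfg <- list(
    group_sizes = group_sizes,
    fh_any_fraction = fh_any_fraction,
    fh_major_fraction = fh_major_fraction,
    fh_same_fraction = fh_same_fraction,
    fh_unknown_rate = fh_unknown_rate,
    amplitude_mean = amplitude_mean,
    amplitude_sd = amplitude_sd,
    latency_shift_s = latency_shift_s,
    latency_sd_s = latency_sd_s,
    noise_sd = noise_sd,
    artifact_channel_rate = artifact_channel_rate,
    artifact_step_scale = artifact_step_scale,
    sampling_interval_s = sampling_interval_s,
    n_channels = as.integer(n_channels),
    # task-block timing is part of the emulated design and not adjustable
    pre_s = 10, task_s = 60, post_s = 55,
    rise_s = rise_s,
    decay_tau_s = decay_tau_s,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(field, why) {
    stop(sprintf("invalid simulation config: field '%s' %s", field, why), call. = FALSE)
  }
  gs <- cfg$group_sizes
  if (is.null(names(gs)) || !all(names(gs) %in% c("SCZ", "MDD", "BIP", "HC")))
    stop_cfg("group_sizes", "must be named with diagnoses among SCZ, MDD, BIP, HC")
  if (any(gs < 0) || any(gs != round(gs)))
    stop_cfg("group_sizes", "must contain non-negative integer counts")
  for (f in c("fh_any_fraction", "fh_major_fraction", "fh_same_fraction")) {
    v <- cfg[[f]]
    if (!all(names(gs) %in% names(v)))
      stop_cfg(f, "must name every diagnosis in group_sizes")
    if (any(v < 0 | v > 1)) stop_cfg(f, "must lie in [0, 1]")
  }
  dx <- names(gs)
  if (any(cfg$fh_same_fraction[dx] > cfg$fh_major_fraction[dx] + 1e-12))
    stop_cfg("fh_same_fraction", "must not exceed fh_major_fraction (nested indicators)")
  if (any(cfg$fh_major_fraction[dx] > cfg$fh_any_fraction[dx] + 1e-12))
    stop_cfg("fh_major_fraction", "must not exceed fh_any_fraction (nested indicators)")
  for (f in c("fh_unknown_rate", "artifact_channel_rate")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop_cfg(f, "must lie in [0, 1]")
  }
  for (f in c("amplitude_sd", "noise_sd", "latency_sd_s")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] < 0)
      stop_cfg(f, "must be a single non-negative number")
  }
  for (f in c("sampling_interval_s", "rise_s", "decay_tau_s", "artifact_step_scale")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      stop_cfg(f, "must be a single positive number")
  }
  if (cfg$n_channels < 1L) stop_cfg("n_channels", "must be at least 1")
  labels <- sim_group_labels(names(gs))
  for (f in c("amplitude_mean", "latency_shift_s")) {
    missing <- setdiff(labels, names(cfg[[f]]))
    if (length(missing))
      stop_cfg(f, paste0("is missing group label(s): ", paste(missing, collapse = ", ")))
  }
  if (any(cfg$latency_shift_s < 0)) stop_cfg("latency_shift_s", "must be non-negative")
  invisible(cfg)
}

# All simulation group labels needed for a set of diagnoses.
sim_group_labels <- function(diagnoses) {
  dx <- setdiff(diagnoses, "HC")
  out <- c(paste0(rep(dx, each = 2), c("+", "-")))
  if ("HC" %in% diagnoses) out <- c("HC", out)
  out
}

#' Read or write a simulation configuration as YAML
#'
#' Scalar fields are stored as-is; named vectors as YAML maps. Unspecified
#' fields fall back to the [simulation_config()] defaults, and the result
#' is re-validated on load.
#'
#' @param path file path.
#' @param cfg a \code{sim_config} object.
#' @return \code{read_simulation_config()} returns a validated
#'   \code{sim_config}; \code{write_simulation_config()} returns
#'   \code{path} invisibly.
#' @export
read_simulation_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  defaults <- formals(simulation_config)
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  args <- lapply(raw, function(x) if (is.list(x)) unlist(x) else x)
  do.call(simulation_config, args)
}

#' @rdname read_simulation_config
#' @export
write_simulation_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  keep <- intersect(names(cfg), names(formals(simulation_config)))
  out <- lapply(cfg[keep], function(x) if (!is.null(names(x))) as.list(x) else x)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:", sum(x$group_sizes), "subjects (",
      paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes), collapse = ", "),
      ")\n")
  cat(sprintf("  blocks: %g s pre / %g s task / %g s post at %g s sampling, %d channels\n",
              x$pre_s, x$task_s, x$post_s, x$sampling_interval_s, x$n_channels))
  cat(sprintf("  noise_sd %g, amplitude_sd %g, artifact rate %g, seed %d\n",
              x$noise_sd, x$amplitude_sd, x$artifact_channel_rate, x$seed))
  invisible(x)
}
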