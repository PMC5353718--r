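# Shared fixtures and independent oracles for the test suite.

# Small four-group config for fast end-to-end runs.
small_config <- function(...) {
  simulation_config(group_sizes = c(SCZ = 8L, MDD = 6L, BIP = 6L, HC = 10L),
                    seed = 42L, ...)
}

# Two equal groups, flat-latency, reduced channel count: used for replicate
# effect-size calibration runs. Group SCZ gets `amp_scz`, HC `amp_hc`; the
# frontal cluster is remapped to channels 1..11 of a 12-channel montage.
twogroup_config <- function(n_per_group = 12L, amp_hc = 2, amp_scz = 1.65,
                            seed = 1L, ...) {
  simulation_config(
    group_sizes = c(SCZ = n_per_group, HC = n_per_group),
    fh_any_fraction = c(SCZ = 0, MDD = 0, BIP = 0, HC = 0),
    fh_major_fraction = c(SCZ = 0, MDD = 0, BIP = 0, HC = 0),
    fh_same_fraction = c(SCZ = 0, MDD = 0, BIP = 0, HC = 0),
    amplitude_mean = c(HC = amp_hc, `SCZ+` = amp_scz, `SCZ-` = amp_scz,
                       `MDD+` = 1, `MDD-` = 1, `BIP+` = 1, `BIP-` = 1),
    latency_shift_s = c(HC = 0, `SCZ+` = 0, `SCZ-` = 0,
                        `MDD+` = 0, `MDD-` = 0, `BIP+` = 0, `BIP-` = 0),
    latency_sd_s = 0,
    artifact_channel_rate = 0,
    n_channels = 12L,
    seed = seed,
    ...)
}

# Build a frontal_waveform directly from a signal sampled on the default
# 0.1 s grid over 0..125 s (task 10-70 s).
make_waveform <- function(signal, dt = 0.1, onset_s = 10, offset_s = 70) {
  structure(list(subject_id = "fixture", sampling_interval_s = dt,
                 signal = signal, n_valid_channels = 11L,
                 task_onset_index = round(onset_s / dt) + 1L,
                 task_offset_index = round(offset_s / dt) + 1L),
            class = "frontal_waveform")
}

# Sample a piecewise-linear function (knots kt, values kv) on the grid.
sample_pwl <- function(kt, kv, dt = 0.1, end_s = 125) {
  t <- seq(0, end_s - dt, by = dt)
  stats::approx(kt, kv, xout = t, rule = 2)$y
}

# Dense-grid brute-force task-window integral of a piecewise-linear signal.
oracle_integral <- function(kt, kv, from = 10, to = 70, n = 60001) {
  tt <- seq(from, to, length.out = n)
  vv <- stats::approx(kt, kv, xout = tt, rule = 2)$y
  h <- (to - from) / (n - 1)
  h * (sum(vv) - (vv[1] + vv[n]) / 2)
}

# Naive loop-based half-area centroid on the sampled signal, applying the
# same definition as the package (positive part, trapezoid segments,
# linear interpolation of cumulative area, earliest crossing) but through
# an explicit scalar accumulation rather than vectorised cumsum/which.
oracle_centroid <- function(signal, dt = 0.1, onset_s = 10) {
  idx <- (round(onset_s / dt) + 1L):length(signal)
  pos <- pmax(signal[idx], 0)
  total <- 0
  for (k in seq_len(length(pos) - 1L)) total <- total + dt * (pos[k] + pos[k + 1]) / 2
  if (total <= 0) return(NA_real_)
  half <- total / 2
  acc <- 0
  for (k in seq_len(length(pos) - 1L)) {
    seg <- dt * (pos[k] + pos[k + 1]) / 2
    if (acc + seg >= half) {
      frac <- if (seg > 0) (half - acc) / seg else 0
      return((k - 1 + frac) * dt)
    }
    acc <- acc + seg
  }
  (length(pos) - 1) * dt
}

# Analytic SD of the extracted task-window integral under the generator:
# between-subject amplitude and latency spread times kernel area, plus
# channel noise propagated through the m-channel average, trapezoid
# integration and the pre/post (or pre-only) baseline correction. The
# latency term assumes the mean latency leaves a full ramp inside the task
# window (area linear in latency with slope -amplitude).
analytic_integral_sd <- function(config, m = 11, latency = 0, amp_mean = 0,
                                 baseline_mode = "prepost",
                                 pre_baseline_s = 10, post_baseline_s = 5) {
  dt <- config$sampling_interval_s
  area <- kernel_task_area(1, latency, config$task_s, config$rise_s,
                           config$decay_tau_s)
  amp_var <- (config$amplitude_sd * area)^2 +
    (amp_mean^2 + config$amplitude_sd^2) * config$latency_sd_s^2
  sig2 <- config$noise_sd^2 / m          # per-sample variance of the average
  n_task <- config$task_s / dt           # trapezoid weight sum of squares ~ n
  var_raw <- sig2 * dt^2 * n_task
  n_pre <- pre_baseline_s / dt
  n_post <- post_baseline_s / dt
  if (baseline_mode == "pre") {
    var_corr <- config$task_s^2 * sig2 / n_pre
  } else {
    # anchor times: centres of the pre window and of the final post window
    t_pre <- (1 + n_pre) / 2
    n_samp <- (config$pre_s + config$task_s + config$post_s) / dt
    t_post <- (n_samp - n_post + 1 + n_samp) / 2
    onset_idx <- config$pre_s / dt + 1
    t_task_mid <- (onset_idx + onset_idx + n_task) / 2
    r <- (t_task_mid - t_pre) / (t_post - t_pre)
    var_corr <- config$task_s^2 * sig2 * ((1 - r)^2 / n_pre + r^2 / n_post)
  }
  sqrt(amp_var + var_raw + var_corr)
}

# Expectation inflation factor of the pooled-SD Cohen's d estimator with
# residual degrees of freedom nu: E[d_hat] = c(nu) * delta.
d_bias_factor <- function(nu) {
  sqrt(nu / 2) * exp(lgamma((nu - 1) / 2) - lgamma(nu / 2))
}
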