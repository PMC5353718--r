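test_that("bad-channel detection separates clean, dead and corrupted channels", {
  cfg <- small_config(artifact_channel_rate = 0)
  st <- generate_study(cfg)
  rec <- st$recordings[[1]]
  expect_identical(detect_bad_channels(rec), integer(0))

  # dead channel: zero variance
  rec_dead <- rec
  rec_dead$channels[26, ] <- 3.2
  expect_identical(detect_bad_channels(rec_dead), 26L)

  # step discontinuity with a clear margin over the noise floor
  rec_step <- rec
  half <- seq(600, ncol(rec_step$channels))
  rec_step$channels[37, half] <- rec_step$channels[37, half] + 20 * cfg$noise_sd
  expect_identical(detect_bad_channels(rec_step), 37L)

  expect_error(detect_bad_channels(rec, cluster = integer(0)), "at least one")
  expect_error(detect_bad_channels(rec, cluster = c(1L, 99L)), "channel range")
})

test_that("generator artifacts are recovered from ground truth", {
  cfg <- small_config(artifact_channel_rate = 0.5)
  st <- generate_study(cfg)
  hits <- misses <- 0L
  for (rec in st$recordings) {
    found <- detect_bad_channels(rec, cluster = 1:52)
    truth <- sort(as.integer(rec$artifact_channels))
    hits <- hits + length(intersect(found, truth))
    misses <- misses + length(setdiff(truth, found)) + length(setdiff(found, truth))
  }
  expect_gt(hits, 0L)
  expect_identical(misses, 0L)
})

test_that("baseline correction removes offset and linear drift exactly", {
  n <- 1250
  pre <- 1:100
  post <- 1201:1250
  expect_equal(baseline_correct(rep(0, n), pre, post), rep(0, n))
  drift <- 0.7 + 0.003 * seq_len(n)
  expect_equal(baseline_correct(drift, pre, post), rep(0, n), tolerance = 1e-10)

  # compactly supported activation + drift: recovered when windows are
  # activation-free
  bump <- sample_pwl(c(0, 10, 40, 70, 100, 125), c(0, 0, 1.5, 1.5, 0, 0))
  expect_equal(baseline_correct(bump + drift, pre, post), bump, tolerance = 1e-6)
  # pre-only mode subtracts the pre-task mean
  expect_equal(baseline_correct(bump + 2, pre, mode = "pre"), bump, tolerance = 1e-10)

  expect_error(baseline_correct(rep(0, n), pre_window = 5L, post_window = post),
               "at least 2 samples")
  expect_error(baseline_correct(rep(0, n), pre, post_window = 1251:1260),
               "outside the signal")
})

test_that("frontal averaging reduces noise and tracks valid-channel counts", {
  cfg <- small_config(artifact_channel_rate = 0, noise_sd = 0)
  st <- generate_study(cfg)
  rec <- st$recordings[[1]]
  # identical channels: cluster mean equals any single corrected channel
  w <- cluster_frontal(rec)
  one <- baseline_correct(rec$channels[25, ], 1:100, 1201:1250)
  expect_equal(w$signal, one)
  expect_equal(w$n_valid_channels, 11L)

  # i.i.d. noise averages down by sqrt(11)
  noise_rec <- rec
  noise_rec$channels <- matrix(stats::rnorm(52 * 1250), nrow = 52)
  wn <- cluster_frontal(noise_rec)
  expect_equal(stats::sd(wn$signal), 1 / sqrt(11), tolerance = 0.1)

  # six of eleven channels bad leaves five valid and fails QC downstream
  w5 <- cluster_frontal(rec, bad = c(25:28, 36:37))
  expect_equal(w5$n_valid_channels, 5L)
  # all channels bad: QC-failure waveform, not an error
  w0 <- cluster_frontal(rec, bad = frontal_channels())
  expect_equal(w0$n_valid_channels, 0L)
  expect_true(all(is.na(w0$signal)))
})

test_that("integral and centroid agree with brute-force oracles on canonical shapes", {
  # unit-height rectangle spanning the task window
  rect <- sample_pwl(c(0, 9.999, 10, 70, 70.001, 125), c(0, 0, 1, 1, 0, 0))
  rect[(101:701)] <- 1
  w <- make_waveform(rect)
  expect_equal(compute_integral(w), 60)

  # symmetric triangle peaking mid-task
  tri <- sample_pwl(c(0, 10, 40, 70, 125), c(0, 0, 1, 0, 0))
  wt <- make_waveform(tri)
  expect_equal(compute_integral(wt), 30)
  expect_equal(compute_centroid(wt), 30)

  # all-zero signal
  expect_equal(compute_integral(make_waveform(rep(0, 1250))), 0)
  expect_true(is.na(compute_centroid(make_waveform(rep(0, 1250)))))
  # negative-only signal: integral signed, centroid undefined
  wneg <- make_waveform(-tri)
  expect_equal(compute_integral(wneg), -30)
  expect_true(is.na(compute_centroid(wneg)))

  # late activation spilling into the post-task window
  late <- sample_pwl(c(0, 49.9, 50, 110, 110.1, 125), c(0, 0, 1, 1, 0, 0))
  expect_equal(compute_centroid(make_waveform(late)), 70, tolerance = 1e-9)
})

test_that("features are scale- and shift-equivariant", {
  set.seed(11)
  bump <- sample_pwl(c(0, 20, 35, 55, 80, 125), c(0, 0, 1.2, 0.8, 0, 0))
  w <- make_waveform(bump)
  w3 <- make_waveform(3 * bump)
  expect_equal(compute_integral(w3), 3 * compute_integral(w))
  expect_equal(compute_centroid(w3), compute_centroid(w))
  # delay by 5 s (50 samples): centroid moves by exactly 5 s
  shifted <- c(rep(0, 50), bump[1:1200])
  expect_equal(compute_centroid(make_waveform(shifted)),
               compute_centroid(w) + 5, tolerance = 1e-9)
})

test_that("integral and centroid match dense/naive oracles on random signals", {
  set.seed(99)
  for (i in 1:100) {
    n_knots <- sample(4:9, 1)
    kt <- sort(c(0, 125, sample(seq(0.5, 124.5, by = 0.1), n_knots)))
    kv <- stats::rnorm(length(kt), sd = 2)
    sig <- sample_pwl(kt, kv)
    w <- make_waveform(sig)
    ref_int <- oracle_integral(kt, kv)
    expect_lt(abs(compute_integral(w) - ref_int), 1e-6 * max(1, abs(ref_int)))
    cen <- compute_centroid(w)
    ref <- oracle_centroid(sig)
    if (is.na(ref)) expect_true(is.na(cen))
    else expect_lt(abs(cen - ref), 1e-6 * max(1, abs(ref)))
  }
})

test_that("extraction applies the minimum-channel exclusion rule", {
  cfg <- small_config(artifact_channel_rate = 0)
  st <- generate_study(cfg)
  rec <- st$recordings[[5]]
  row <- extract_features(rec)
  expect_true(row$qc_pass)
  expect_true(is.finite(row$integral_value) && is.finite(row$centroid_value_s))

  corrupt <- function(rec, channels) {
    for (ch in channels) {
      spikes <- c(200, 600, 900)
      rec$channels[ch, spikes] <- rec$channels[ch, spikes] + 40 * cfg$noise_sd
    }
    rec
  }
  # seven corrupted frontal channels -> fewer than 6 usable -> excluded
  row7 <- extract_features(corrupt(rec, c(25:28, 36:38)))
  expect_false(row7$qc_pass)
  expect_equal(row7$n_valid_channels, 4L)
  expect_equal(row7$exclusion_reason, "insufficient_channels")
  expect_true(is.na(row7$integral_value))

  # five corrupted -> six usable -> still analysed
  row5 <- extract_features(corrupt(rec, c(25:28, 36)))
  expect_true(row5$qc_pass)
  expect_equal(row5$n_valid_channels, 6L)
})

test_that("noise-free extraction recovers amplitude x kernel area", {
  A <- 1.4
  cfg <- twogroup_config(n_per_group = 1L, amp_hc = A, amp_scz = A,
                         noise_sd = 0, amplitude_sd = 0)
  st <- generate_study(cfg)
  rec <- st$recordings[[1]]
  area <- kernel_task_area(A, 0, cfg$task_s, cfg$rise_s, cfg$decay_tau_s)

  fc_pre <- feature_config(jump_k = Inf, baseline_mode = "pre")
  row <- extract_features(rec, cluster = 1:11, config = fc_pre)
  expect_equal(row$integral_value, area, tolerance = 1e-9)

  # pre/post baseline: the decay tail has not fully returned to zero, so the
  # fitted line tilts the integral by a small, analytically known amount
  fc_pp <- feature_config(jump_k = Inf, baseline_mode = "prepost")
  row_pp <- extract_features(rec, cluster = 1:11, config = fc_pp)
  expect_equal(row_pp$integral_value, area, tolerance = 0.02)
  expect_lt(row_pp$integral_value, area)  # tail bias is downward
})

test_that("excluding a channel is equivalent to recomputing the mean without it", {
  cfg <- small_config()
  st <- generate_study(cfg)
  rec <- st$recordings[[2]]
  cl <- frontal_channels()
  w_all <- cluster_frontal(rec, cl)
  w_drop <- cluster_frontal(rec, cl, bad = 27L)
  manual <- vapply(setdiff(cl, 27L), function(ch)
    baseline_correct(rec$channels[ch, ], 1:100, 1201:1250), numeric(1250))
  expect_equal(w_drop$signal, rowMeans(manual))
  # and the dropped-channel mean accounts exactly for the difference
  ch27 <- baseline_correct(rec$channels[27, ], 1:100, 1201:1250)
  expect_equal(w_all$signal, (rowMeans(manual) * 10 + ch27) / 11)
})
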