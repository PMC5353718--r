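#!/usr/bin/env Rscript
# Stage 2: frontal waveform features from the on-disk recordings.
#
# Re-reads the fixture set written by 01_simulate.R, screens the
# 11-channel frontal cluster for artifact-corrupted or dead channels,
# baseline-corrects, averages the cluster, and computes the task-period
# integral and half-area centroid per subject. Subjects with fewer than
# 6 usable frontal channels are excluded.

library(nirsvft)

fx <- read_fixture_set("scratch/fixtures")
feats <- extract_features_cohort(fx$recordings)
write.csv(feats, "results/features.csv", row.names = FALSE, na = "")
excl <- feats[!feats$qc_pass, c("subject_id", "n_valid_channels", "exclusion_reason")]
write.csv(excl, "results/exclusions.csv", row.names = FALSE, na = "")

message(sum(feats$qc_pass), " of ", nrow(feats), " subjects pass QC (",
        nrow(excl), " excluded)")
by_dx <- merge(feats, fx$cohort[, c("id", "diagnosis")],
               by.x = "subject_id", by.y = "id")
for (dx in levels(by_dx$diagnosis)) {
  sub <- by_dx[by_dx$diagnosis == dx & by_dx$qc_pass, ]
  message(sprintf("  %s: integral %6.1f +/- %5.1f, centroid %5.1f +/- %4.1f s",
                  dx, mean(sub$integral_value), sd(sub$integral_value),
                  mean(sub$centroid_value_s), sd(sub$centroid_value_s)))
}
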