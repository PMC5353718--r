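#!/usr/bin/env Rscript
# Stage 4: individual-level threshold classification.
#
# Applies the fixed cutoffs (integral 73: patient-range vs control-range;
# centroid 54 s: psychosis-spectrum vs depression-like timing) per subject
# and summarises counts and percentages per diagnostic group.

library(nirsvft)

fx <- read_fixture_set("scratch/fixtures")
feats <- read.csv("results/features.csv", na.strings = "")

cls <- classify_subjects(feats)
write.csv(cls, "results/classification.csv", row.names = FALSE, na = "")
summ <- summarize_classification(feats, fx$cohort)
write.csv(summ, "results/classification_summary.csv", row.names = FALSE, na = "")

for (i in seq_len(nrow(summ))) {
  message(sprintf("  %s (n=%d): %4.1f%% patient-range, %4.1f%% psychosis-timing",
                  summ$group[i], summ$n[i], summ$pct_patient[i],
                  summ$pct_psychosis[i]))
}
if (any(cls$tie_integral | cls$tie_centroid))
  message(sum(cls$tie_integral | cls$tie_centroid),
          " subject(s) sat exactly on a threshold (classified as case)")
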