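#!/usr/bin/env Rscript
# Stage 5: assemble a human-readable markdown report from the stage outputs.

library(nirsvft)

dem <- read.csv("results/demographics_tests.csv", na.strings = "")
models <- jsonlite::read_json("results/ancova_models.json", simplifyVector = FALSE)
contrasts <- read.csv("results/posthoc_contrasts.csv")
summ <- read.csv("results/classification_summary.csv", na.strings = "")

md <- c("# Synthetic frontal NIRS verbal-fluency analysis", "",
        "## Demographic comparisons", "",
        "| Variable | Test | Statistic | df | p |",
        "|---|---|---|---|---|",
        sprintf("| %s | %s | %.2f | %s | %.3g |", dem$variable, dem$test,
                dem$statistic, ifelse(is.na(dem$df), "-", dem$df), dem$p),
        "", "## Covariate-adjusted group models", "",
        "| Model | F | df | p | n |", "|---|---|---|---|---|")
for (nm in names(models)) {
  m <- models[[nm]]
  md <- c(md, sprintf("| %s | %.2f | %d, %d | %.3g | %d |", nm, m$F,
                      m$df_num, m$df_den, m$p, m$n_used))
}
md <- c(md, "", "## LSD contrasts (adjusted means, raw-pooled Cohen's d)", "",
        "| Model | Pair | Adj. diff | p | d |", "|---|---|---|---|---|",
        sprintf("| %s | %s vs %s | %.1f | %.3g | %.2f |", contrasts$model,
                contrasts$group_a, contrasts$group_b,
                contrasts$adjusted_mean_diff, contrasts$lsd_p,
                contrasts$cohens_d),
        "", "## Threshold classification", "",
        "| Group | n | % patient-range | % psychosis-timing |", "|---|---|---|---|",
        sprintf("| %s | %d | %.1f | %.1f |", summ$group, summ$n,
                summ$pct_patient, summ$pct_psychosis))

writeLines(md, "results/report.md")
message("report written to results/report.md (", length(md), " lines)")
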