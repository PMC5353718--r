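#!/usr/bin/env Rscript
# Stage 3: covariate-adjusted group comparisons.
#
# Fits the diagnostic-status and family-history ANCOVA models (age,
# gender and task performance as covariates; type-III sums of squares)
# on integral and centroid, follows significant omnibus effects with
# Fisher's LSD contrasts, attaches pooled-SD Cohen's d, and screens
# feature-clinical Spearman correlations.

library(nirsvft)

fx <- read_fixture_set("scratch/fixtures")
feats <- read.csv("results/features.csv", na.strings = "")
cohort <- fx$cohort

models <- list()
contrasts <- list()
for (dep in c("integral_value", "centroid_value_s")) {
  # four diagnostic groups
  fit <- ancova(feats, cohort, dependent = dep, grouping = "diagnosis")
  print(fit)
  models[[paste0(dep, ".diagnosis")]] <-
    fit[c("dependent", "factor_levels", "F", "df_num", "df_den", "p", "n_used")]
  lsd <- lsd_posthoc(fit, pairs = list(c("SCZ", "HC"), c("MDD", "HC"), c("BIP", "HC")))
  lsd$model <- paste0(dep, ".diagnosis")
  contrasts[[length(contrasts) + 1L]] <- lsd

  # controls vs pooled patients split by major-psychiatric family history
  fit_fh <- ancova(feats, cohort, dependent = dep,
                   grouping = fh_grouping(cohort, level = "major"))
  print(fit_fh)
  models[[paste0(dep, ".fh_pooled")]] <-
    fit_fh[c("dependent", "factor_levels", "F", "df_num", "df_den", "p", "n_used")]
  lsd_fh <- lsd_posthoc(fit_fh)
  lsd_fh$model <- paste0(dep, ".fh_pooled")
  contrasts[[length(contrasts) + 1L]] <- lsd_fh

  # per-diagnosis family-history models (any psychiatric disorder)
  for (dx in c("SCZ", "MDD", "BIP")) {
    fit_dx <- suppressMessages(
      ancova(feats, cohort, dependent = dep,
             grouping = fh_grouping(cohort, diagnoses = dx, level = "any")))
    models[[paste0(dep, ".fh_", dx)]] <-
      fit_dx[c("dependent", "factor_levels", "F", "df_num", "df_den", "p", "n_used")]
  }
}

jsonlite::write_json(models, "results/ancova_models.json",
                     auto_unbox = TRUE, digits = NA)
all_contrasts <- do.call(rbind, contrasts)
write.csv(all_contrasts, "results/posthoc_contrasts.csv", row.names = FALSE)

rho <- spearman_correlations(
  feats, cohort,
  variables = c("vft_performance", "cpz_eq_mg_day", "onset_age_years",
                "illness_duration_years", "panss_total", "hamd17", "ymrs"))
write.csv(rho, "results/spearman_correlations.csv", row.names = FALSE, na = "")

sig <- all_contrasts[all_contrasts$lsd_p < 0.05, ]
message(nrow(sig), " of ", nrow(all_contrasts),
        " LSD contrasts significant at p < 0.05; largest |d| = ",
        sprintf("%.2f", max(abs(all_contrasts$cohens_d))))
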