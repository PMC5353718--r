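# Direct feature/subject tables (no recordings) for model-level tests.
fake_tables <- function(groups, n_per_group, effect = 0, seed = 1) {
  set.seed(seed)
  g <- rep(groups, n_per_group)
  n <- length(g)
  shift <- effect * (as.integer(factor(g, levels = groups)) - 1)
  subjects <- data.frame(
    id = sprintf("X%03d", seq_len(n)),
    group = g,
    age_years = stats::rnorm(n, 38, 10),
    gender = sample(c("male", "female"), n, replace = TRUE),
    vft_performance = round(stats::rnorm(n, 15, 5)),
    stringsAsFactors = FALSE
  )
  features <- data.frame(
    subject_id = subjects$id,
    integral_value = stats::rnorm(n, 80, 25) + shift,
    centroid_value_s = stats::rnorm(n, 45, 8),
    n_valid_channels = 11L, qc_pass = TRUE,
    exclusion_reason = NA_character_,
    stringsAsFactors = FALSE
  )
  list(features = features, subjects = subjects)
}

test_that("ANCOVA degrees of freedom follow the design on random layouts", {
  set.seed(2)
  for (i in 1:6) {
    k <- sample(2:5, 1)
    ns <- sample(8:20, k, replace = TRUE)
    covs <- sample(c("age_years", "gender", "vft_performance"), sample(1:3, 1))
    tb <- fake_tables(LETTERS[1:k], ns, seed = i)
    fit <- ancova(tb$features, tb$subjects, grouping = "group", covariates = covs)
    expect_equal(fit$df_num, k - 1L)
    expect_equal(fit$df_den, sum(ns) - k - length(covs))
    expect_gte(fit$p, 0); expect_lte(fit$p, 1)
  }
})

test_that("ANCOVA rejects degenerate designs and logs listwise drops", {
  tb <- fake_tables(c("A", "B"), c(10, 1))
  expect_error(ancova(tb$features, tb$subjects, grouping = "group"),
               "degenerate")
  tb2 <- fake_tables(c("A", "B"), c(12, 12))
  tb2$subjects$age_years[3] <- NA
  expect_message(fit <- ancova(tb2$features, tb2$subjects, grouping = "group"),
                 "dropped 1")
  expect_equal(fit$n_used, 23L)
  expect_equal(fit$df_den, 23L - 2L - 3L)
})

test_that("LSD contrasts reduce to the omnibus test for two groups", {
  tb <- fake_tables(c("A", "B"), c(14, 11), effect = 12)
  fit <- ancova(tb$features, tb$subjects, grouping = "group")
  lsd <- lsd_posthoc(fit)
  expect_equal(nrow(lsd), 1L)
  expect_equal(lsd$lsd_p, fit$p, tolerance = 1e-12)
  expect_equal(lsd$t_value^2, fit$F, tolerance = 1e-10)
  expect_error(lsd_posthoc(fit, pairs = list(c("A", "Z"))), "unknown group")
})

test_that("identical groups give null contrasts", {
  tb <- fake_tables(c("A", "B"), c(12, 12), seed = 3)
  # make group B an exact copy of group A on all modelled variables
  tb$features$integral_value[13:24] <- tb$features$integral_value[1:12]
  tb$subjects[13:24, c("age_years", "gender", "vft_performance")] <-
    tb$subjects[1:12, c("age_years", "gender", "vft_performance")]
  fit <- ancova(tb$features, tb$subjects, grouping = "group")
  lsd <- lsd_posthoc(fit)
  expect_equal(lsd$adjusted_mean_diff, 0, tolerance = 1e-10)
  expect_gt(lsd$lsd_p, 0.999)
})

test_that("LSD adjusted means and p-values agree with emmeans", {
  tb <- fake_tables(c("A", "B", "C"), c(15, 10, 12), effect = 15, seed = 4)
  fit <- ancova(tb$features, tb$subjects, grouping = "group")
  lsd <- lsd_posthoc(fit)
  em <- emmeans::emmeans(fit$model, ".group")
  ref <- as.data.frame(emmeans::contrast(em, "pairwise", adjust = "none"))
  # emmeans orders pairs the same way (A-B, A-C, B-C)
  expect_equal(lsd$adjusted_mean_diff, ref$estimate, tolerance = 1e-8)
  expect_equal(lsd$lsd_p, ref$p.value, tolerance = 1e-8)
  expect_equal(lsd$se, ref$SE, tolerance = 1e-8)
})

test_that("Cohen's d matches hand values, antisymmetry and the t identity", {
  expect_equal(cohens_d(c(0, 1, 2), c(1, 2, 3)), -1)
  expect_equal(cohens_d(c(5, 6, 7, 8), c(5, 6, 7, 8)), 0)
  set.seed(8)
  x <- stats::rnorm(20); y <- stats::rnorm(15, 0.5)
  expect_equal(cohens_d(x, y), -cohens_d(y, x))
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(cohens_d(x, y),
               unname(tt$statistic) * sqrt(1 / 20 + 1 / 15), tolerance = 1e-12)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled standard deviation")
  expect_error(cohens_d(1, c(1, 2)), "at least 2")
})

test_that("Spearman correlations match a brute-force rank computation", {
  tb <- fake_tables("A", 8, seed = 5)
  tb$features$integral_value <- c(3.1, 5.2, 1.0, 9.9, 7.3, 2.2, 8.8, 4.4)
  tb$subjects$age_years <- c(31, 44, 22, 58, 47, 29, 51, 40)
  out <- spearman_correlations(tb$features, tb$subjects, "age_years",
                               feature_cols = "integral_value")
  manual <- stats::cor(rank(tb$features$integral_value), rank(tb$subjects$age_years))
  expect_equal(out$rho, manual, tolerance = 1e-12)
  expect_equal(out$n, 8L)

  # monotone and anti-monotone limits
  tb$subjects$age_years <- rank(tb$features$integral_value) + 20
  up <- spearman_correlations(tb$features, tb$subjects, "age_years",
                              feature_cols = "integral_value")
  expect_equal(up$rho, 1)
  tb$subjects$age_years <- -tb$features$integral_value
  down <- spearman_correlations(tb$features, tb$subjects, "age_years",
                                feature_cols = "integral_value")
  expect_equal(down$rho, -1)

  # degenerate variable flagged, not an error
  tb$subjects$age_years <- rep(40, 8)
  flat <- spearman_correlations(tb$features, tb$subjects, "age_years",
                                feature_cols = "integral_value")
  expect_true(is.na(flat$rho))
  expect_match(flat$note, "all-tied")
})

test_that("demographic table picks the right test per variable type", {
  set.seed(9)
  co <- generate_cohort(simulation_config())
  dem <- demographic_table(co)
  tests <- dem$tests
  age_row <- tests[tests$variable == "age_years", ]
  expect_equal(age_row$test, "Kruskal-Wallis")
  expect_equal(age_row$df, 3)
  gender_row <- tests[tests$variable == "gender", ]
  expect_equal(gender_row$test, "chi-squared")
  expect_equal(gender_row$df, 3)
  # medication exists only in patients: compared across the 3 patient groups
  cpz_row <- tests[tests$variable == "cpz_eq_mg_day", ]
  expect_equal(cpz_row$df, 2)
  expect_true(all(c("HC", "SCZ") %in% names(dem$group_summary$age_years)))

  # two-group comparison switches to Mann-Whitney U
  two <- demographic_table(co[co$diagnosis %in% c("HC", "SCZ"), ],
                           grouping = "diagnosis")
  expect_equal(two$tests[two$tests$variable == "age_years", "test"],
               "Mann-Whitney U")
})

test_that("chi-squared on perfectly separated 2x2 counts equals its closed form", {
  subjects <- data.frame(id = sprintf("Y%02d", 1:20),
                         group = rep(c("A", "B"), each = 10),
                         gender = rep(c("male", "female"), each = 10),
                         stringsAsFactors = FALSE)
  dem <- demographic_table(subjects, grouping = "group",
                           continuous = character(), categorical = "gender")
  expect_equal(dem$tests$statistic, 20)
  expect_equal(dem$tests$df, 1)
})

test_that("family-history grouping is nested, level-aware and NA-safe", {
  cfg <- simulation_config(fh_unknown_rate = 0.2, seed = 31L)
  set.seed(31)
  co <- generate_cohort(cfg)
  g_any <- fh_grouping(co, level = "any")
  g_major <- fh_grouping(co, level = "major")
  expect_true(all(g_any[co$diagnosis == "HC"] == "HC"))
  # unknown family history propagates to NA grouping
  unk <- !is.na(co$diagnosis) & co$diagnosis != "HC" & is.na(co$fh_any)
  expect_true(any(unk))
  expect_true(all(is.na(g_any[unk])))
  # major-positive is a subset of any-positive
  expect_true(all(which(g_major == "FH+") %in% which(g_any == "FH+")))
  # restricting diagnoses drops the others
  g_scz <- fh_grouping(co, diagnoses = "SCZ", level = "any")
  expect_true(all(is.na(g_scz[co$diagnosis %in% c("MDD", "BIP")])))
})
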