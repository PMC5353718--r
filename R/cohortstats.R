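#' Cohen's d with pooled standard deviation
#'
#' \eqn{d = (\bar{x} - \bar{y}) / s_p} with
#' \eqn{s_p^2 = ((n_1 - 1) s_1^2 + (n_2 - 1) s_2^2) / (n_1 + n_2 - 2)},
#' computed from raw group values (not covariate-adjusted means).
#'
#' @param x,y numeric samples, each with at least 2 observations.
#' @return The standardized mean difference (x minus y).
#' @export
#' @examples
#' cohens_d(c(0, 1, 2), c(1, 2, 3))  # -1
cohens_d <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each sample needs at least 2 observations",
                             call. = FALSE)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2))
  if (sp == 0) stop("pooled standard deviation is zero; effect size undefined",
                    call. = FALSE)
  (mean(x) - mean(y)) / sp
}

# Join qc-passing feature rows to subjects and drop rows with missing
# dependent/group/covariate values (listwise), reporting the count.
ancova_data <- function(features, subjects, dependent, grouping, covariates) {
  if (is.character(grouping) && length(grouping) == 1L) {
    if (!grouping %in% names(subjects))
      stop("grouping column '", grouping, "' not found in subjects", call. = FALSE)
    group_vec <- subjects[[grouping]]
  } else {
    if (length(grouping) != nrow(subjects))
      stop("grouping vector must have one entry per subject", call. = FALSE)
    group_vec <- grouping
  }
  subj <- subjects
  subj$.group <- factor(group_vec)
  keep <- c("id", ".group", covariates)
  missing_cols <- setdiff(covariates, names(subj))
  if (length(missing_cols))
    stop("covariate(s) not found in subjects: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  dat <- merge(features[isTRUE_vec(features$qc_pass), , drop = FALSE],
               subj[, keep], by.x = "subject_id", by.y = "id")
  if (!dependent %in% names(dat))
    stop("dependent variable '", dependent, "' not found in features", call. = FALSE)
  dat$.y <- dat[[dependent]]
  # 1-df indicator coding for two-level factor covariates (e.g. gender)
  for (cv in covariates) {
    v <- dat[[cv]]
    if (is.factor(v) || is.character(v)) {
      v <- factor(v)
      if (nlevels(droplevels(v)) > 2)
        stop("covariate '", cv, "' has more than 2 levels; recode it numerically",
             call. = FALSE)
      dat[[cv]] <- as.numeric(v == levels(v)[2])
    }
  }
  n_before <- nrow(dat)
  dat <- dat[stats::complete.cases(dat[, c(".y", ".group", covariates)]), ]
  n_dropped <- n_before - nrow(dat)
  if (n_dropped > 0)
    message("ancova: dropped ", n_dropped, " row(s) with missing values")
  dat$.group <- droplevels(dat$.group)
  list(data = dat, n_dropped = n_dropped)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Covariate-adjusted group comparison (ANCOVA)
#'
#' Ordinary least-squares ANCOVA with a single group factor and continuous
#' (or 1-df indicator) covariates, type-III sums of squares for the
#' omnibus group effect - the convention of the emulated study's software.
#' Only quality-control-passing feature rows enter; rows with missing
#' covariates are dropped listwise with a logged count.
#'
#' @param features feature table from [extract_features_cohort()].
#' @param subjects cohort table from [generate_cohort()] (or any table with
#'   an \code{id} column and the covariates).
#' @param dependent feature column name, typically \code{"integral_value"}
#'   or \code{"centroid_value_s"}.
#' @param grouping a column name in \code{subjects} (e.g.
#'   \code{"diagnosis"}) or a factor of length \code{nrow(subjects)} (NA
#'   drops the subject); see [fh_grouping()].
#' @param covariates covariate column names; default age, gender and task
#'   performance.
#' @return An object of class \code{ancova_result}: list with
#'   \code{dependent}, \code{factor_levels}, \code{F}, \code{df_num},
#'   \code{df_den}, \code{p}, \code{covariates}, \code{n_used},
#'   \code{n_dropped}, the fitted \code{model} and the analysis
#'   \code{data}.
#' @export
ancova <- function(features, subjects, dependent = "integral_value",
                   grouping = "diagnosis",
                   covariates = c("age_years", "gender", "vft_performance")) {
  prep <- ancova_data(features, subjects, dependent, grouping, covariates)
  dat <- prep$data
  counts <- table(dat$.group)
  if (length(counts) < 2)
    stop("degenerate design: need at least 2 groups with data", call. = FALSE)
  if (any(counts < 2))
    stop("degenerate design: group(s) with fewer than 2 subjects: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)

  fml <- stats::reformulate(c(".group", covariates), response = ".y")
  model <- stats::lm(fml, data = dat,
                     contrasts = list(.group = "contr.sum"))
  aov3 <- car::Anova(model, type = 3)
  row <- which(rownames(aov3) == ".group")
  res <- which(rownames(aov3) == "Residuals")

  structure(list(
    dependent = dependent,
    factor_levels = levels(dat$.group),
    F = aov3[row, "F value"],
    df_num = as.integer(aov3[row, "Df"]),
    df_den = as.integer(aov3[res, "Df"]),
    p = aov3[row, "Pr(>F)"],
    covariates = covariates,
    n_used = nrow(dat),
    n_dropped = prep$n_dropped,
    model = model,
    data = dat
  ), class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("ANCOVA on %s across %s (covariates: %s)\n", x$dependent,
              paste(x$factor_levels, collapse = "/"),
              paste(x$covariates, collapse = ", ")))
  cat(sprintf("  F(%d, %d) = %.2f, p = %.3g  [n = %d, dropped %d]\n",
              x$df_num, x$df_den, x$F, x$p, x$n_used, x$n_dropped))
  invisible(x)
}

#' Fisher's LSD post hoc contrasts with Cohen's d
#'
#' Unadjusted pairwise t-tests on covariate-adjusted group means (evaluated
#' at the covariate means of the analysis sample), using the omnibus
#' model's residual variance and degrees of freedom; no multiplicity
#' correction, per the LSD procedure. Cohen's d is computed from the raw
#' group values of the dependent variable, not from adjusted means.
#'
#' @param fit an \code{ancova_result}.
#' @param pairs optional list of 2-vectors of group labels; default all
#'   pairs.
#' @return data.frame with one row per pair: \code{group_a, group_b,
#'   adjusted_mean_diff} (a minus b), \code{se, df, t_value, lsd_p,
#'   cohens_d}.
#' @export
lsd_posthoc <- function(fit, pairs = NULL) {
  stopifnot(inherits(fit, "ancova_result"))
  lev <- fit$factor_levels
  if (is.null(pairs)) {
    cmb <- utils::combn(lev, 2)
    pairs <- lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
  }
  dat <- fit$data
  cov_means <- lapply(fit$covariates, function(cv) mean(dat[[cv]]))
  names(cov_means) <- fit$covariates
  trms <- stats::delete.response(stats::terms(fit$model))
  beta <- stats::coef(fit$model)
  V <- stats::vcov(fit$model)
  df_res <- stats::df.residual(fit$model)

  row_for <- function(g) {
    nd <- data.frame(.group = factor(g, levels = lev), cov_means,
                     check.names = FALSE)
    stats::model.matrix(trms, nd, contrasts.arg = fit$model$contrasts)
  }

  out <- lapply(pairs, function(pr) {
    if (!all(pr %in% lev))
      stop("unknown group level(s): ",
           paste(setdiff(pr, lev), collapse = ", "), call. = FALSE)
    cd <- row_for(pr[1]) - row_for(pr[2])
    est <- drop(cd %*% beta)
    se <- sqrt(drop(cd %*% V %*% t(cd)))
    tval <- est / se
    p <- 2 * stats::pt(-abs(tval), df_res)
    d <- cohens_d(dat$.y[dat$.group == pr[1]], dat$.y[dat$.group == pr[2]])
    data.frame(group_a = pr[1], group_b = pr[2],
               adjusted_mean_diff = est, se = se, df = df_res,
               t_value = tval, lsd_p = p, cohens_d = d,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Family-history grouping factor
#'
#' Builds the three-level grouping used in the family-history models:
#' healthy controls versus patients (of the requested diagnoses) with and
#' without a positive family history at the chosen nesting level. Subjects
#' of other diagnoses, and patients with unknown family history, are NA
#' and therefore dropped by [ancova()].
#'
#' @param subjects cohort table.
#' @param diagnoses patient diagnoses to include (default all three).
#' @param level family-history nesting level: \code{"any"} psychiatric
#'   disorder, \code{"major"} psychiatric disorder, or \code{"same"}
#'   disorder as the proband.
#' @return Factor with levels \code{HC}, \code{FH+}, \code{FH-}.
#' @export
fh_grouping <- function(subjects, diagnoses = c("SCZ", "MDD", "BIP"),
                        level = c("any", "major", "same")) {
  level <- match.arg(level)
  flag <- subjects[[paste0("fh_", level)]]
  out <- rep(NA_character_, nrow(subjects))
  out[subjects$diagnosis == "HC"] <- "HC"
  pat <- subjects$diagnosis %in% diagnoses
  out[pat & isTRUE_vec(flag)] <- "FH+"
  out[pat & !is.na(flag) & !flag] <- "FH-"
  factor(out, levels = c("HC", "FH+", "FH-"))
}

#' Spearman correlations between features and clinical variables
#'
#' Tie-corrected rank correlations on pairwise-complete observations with
#' two-sided p-values (normal approximation under ties).
#'
#' @param features feature table (qc-passing rows are used).
#' @param subjects cohort table.
#' @param variables subject column names to correlate against.
#' @param feature_cols feature columns (default integral and centroid).
#' @return data.frame: \code{feature, variable, n, rho, p, note} (note
#'   flags undefined correlations from all-tied variables or n < 3).
#' @export
spearman_correlations <- function(features, subjects, variables,
                                  feature_cols = c("integral_value",
                                                   "centroid_value_s")) {
  dat <- merge(features[isTRUE_vec(features$qc_pass), , drop = FALSE],
               subjects, by.x = "subject_id", by.y = "id")
  grid <- expand.grid(feature = feature_cols, variable = variables,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    x <- dat[[grid$feature[i]]]
    y <- dat[[grid$variable[i]]]
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    if (n < 3)
      return(data.frame(grid[i, ], n = n, rho = NA_real_, p = NA_real_,
                        note = "fewer than 3 complete pairs"))
    if (length(unique(x[ok])) < 2 || length(unique(y[ok])) < 2)
      return(data.frame(grid[i, ], n = n, rho = NA_real_, p = NA_real_,
                        note = "all-tied variable"))
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman",
                                           exact = FALSE))
    data.frame(grid[i, ], n = n, rho = unname(ct$estimate), p = ct$p.value,
               note = NA_character_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group demographic comparison table
#'
#' Mirrors the usual clinical Table 1: continuous variables compared with
#' the Kruskal-Wallis test (Mann-Whitney U for two groups), categorical
#' variables with Pearson's chi-squared test (no continuity correction),
#' and a per-variable normality screen - Lilliefors-corrected
#' Kolmogorov-Smirnov by default (parameters estimated from the data), or
#' the plain one-sample KS test against the fitted normal when
#' \code{lilliefors = FALSE}.
#'
#' @param subjects cohort table.
#' @param grouping column name or factor (as in [ancova()]).
#' @param continuous,categorical variable names to compare.
#' @param lilliefors use the parameter-estimated (Lilliefors) null for the
#'   normality screen.
#' @return List with \code{tests} (data.frame: variable, type, test,
#'   statistic, df, p, normality_p, normal) and \code{group_summary}
#'   (per-group mean ± SD strings or category counts).
#' @export
demographic_table <- function(subjects, grouping = "diagnosis",
                              continuous = c("age_years", "education_years",
                                             "premorbid_iq", "vft_performance",
                                             "cpz_eq_mg_day", "onset_age_years",
                                             "illness_duration_years"),
                              categorical = c("gender", "handedness"),
                              lilliefors = TRUE) {
  g <- if (is.character(grouping) && length(grouping) == 1L)
    subjects[[grouping]] else grouping
  g <- factor(g)
  rows <- list()
  summ <- list()
  for (v in intersect(continuous, names(subjects))) {
    x <- subjects[[v]]
    ok <- !is.na(x) & !is.na(g)
    gl <- droplevels(g[ok])
    if (!sum(ok) || nlevels(gl) < 2) {
      message("demographic_table: skipping '", v, "' (insufficient data)")
      next
    }
    if (nlevels(gl) == 2) {
      tst <- stats::wilcox.test(x[ok] ~ gl)
      rows[[v]] <- data.frame(variable = v, type = "continuous",
                              test = "Mann-Whitney U",
                              statistic = unname(tst$statistic), df = NA_real_,
                              p = tst$p.value)
    } else {
      tst <- stats::kruskal.test(x[ok], gl)
      rows[[v]] <- data.frame(variable = v, type = "continuous",
                              test = "Kruskal-Wallis",
                              statistic = unname(tst$statistic),
                              df = unname(tst$parameter), p = tst$p.value)
    }
    xx <- x[ok]
    ks_p <- if (length(unique(xx)) < 5) NA_real_
      else if (lilliefors) nortest::lillie.test(xx)$p.value
      else stats::ks.test(xx, "pnorm", mean(xx), stats::sd(xx))$p.value
    rows[[v]]$normality_p <- ks_p
    rows[[v]]$normal <- !is.na(ks_p) & ks_p >= 0.05
    summ[[v]] <- tapply(x, g, function(z) {
      z <- z[!is.na(z)]
      if (!length(z)) "-" else sprintf("%.1f ± %.1f", mean(z), stats::sd(z))
    })
  }
  for (v in intersect(categorical, names(subjects))) {
    x <- subjects[[v]]
    ok <- !is.na(x) & !is.na(g)
    tab <- table(droplevels(factor(x[ok])), droplevels(g[ok]))
    if (nrow(tab) < 2 || ncol(tab) < 2) {
      message("demographic_table: skipping '", v, "' (insufficient data)")
      next
    }
    tst <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    rows[[v]] <- data.frame(variable = v, type = "categorical",
                            test = "chi-squared",
                            statistic = unname(tst$statistic),
                            df = unname(tst$parameter), p = tst$p.value,
                            normality_p = NA_real_, normal = NA)
    summ[[v]] <- apply(table(g, factor(x)), 1, function(cnt)
      paste(sprintf("%s:%d", names(cnt), cnt), collapse = " "))
  }
  tests <- do.call(rbind, rows)
  rownames(tests) <- NULL
  list(tests = tests, group_summary = summ)
}
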