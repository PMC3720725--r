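# The statistical battery applied to cohort tables: normality gate,
# rank-sum comparisons with Bonferroni correction, correlation, contingency
# testing, and the two assay helpers (comparative-Ct fold change, reporter
# repression).

new_test_result <- function(test_name, statistic, p_value,
                            adjusted_p = NA_real_, alpha_cutoff = 0.05,
                            extra = list()) {
  decision <- if (min(adjusted_p, p_value, na.rm = TRUE) < alpha_cutoff)
    "reject" else "fail_to_reject"
  structure(c(list(test_name = test_name, statistic = statistic,
                   p_value = p_value, adjusted_p = adjusted_p,
                   alpha_cutoff = alpha_cutoff, decision = decision),
              extra),
            class = "lq_test_result")
}

#' @export
print.lq_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, p = %.4g", x$test_name, x$statistic,
              x$p_value))
  if (!is.na(x$adjusted_p)) cat(sprintf(" (adjusted %.4g)", x$adjusted_p))
  cat(sprintf(" -> %s at alpha %.3g\n", x$decision, x$alpha_cutoff))
  invisible(x)
}

#' Normality and variance-equivalence gate
#'
#' Runs a Shapiro-Wilk test per cohort at \code{alpha} and a Levene-type
#' variance-equivalence test (Brown-Forsythe, median-centred) across
#' cohorts; the gate recommends nonparametric group comparison when any
#' cohort departs from normality or the variances are unequal. The Levene
#' procedure stands in for an unnamed variance-equivalence test; it is the
#' conventional choice.
#'
#' @param cohorts named list of numeric vectors (each n >= 3).
#' @param alpha significance level (default 0.05).
#' @return list with per-cohort \code{shapiro} results, the \code{levene}
#'   result, and \code{recommend_nonparametric}.
#' @export
normality_gate <- function(cohorts, alpha = 0.05) {
  if (!is.list(cohorts) || length(cohorts) == 0L)
    stop("'cohorts' must be a non-empty list of numeric vectors",
         call. = FALSE)
  nm <- names(cohorts) %||% paste0("cohort", seq_along(cohorts))
  shap <- lapply(seq_along(cohorts), function(i) {
    v <- cohorts[[i]]
    if (length(v) < 3L)
      stop(sprintf("cohort '%s' has n < 3", nm[i]), call. = FALSE)
    if (stats::sd(v) == 0)
      return(new_test_result("shapiro_wilk", NA_real_, 0,
                             alpha_cutoff = alpha,
                             extra = list(cohort = nm[i],
                                          note = "degenerate constant sample")))
    sw <- stats::shapiro.test(v)
    new_test_result("shapiro_wilk", unname(sw$statistic), sw$p.value,
                    alpha_cutoff = alpha, extra = list(cohort = nm[i]))
  })
  names(shap) <- nm
  lev <- NULL
  if (length(cohorts) >= 2L) {
    vals <- unlist(cohorts, use.names = FALSE)
    grp <- factor(rep(nm, lengths(cohorts)))
    lv <- car::leveneTest(vals ~ grp, center = stats::median)
    lev <- new_test_result("levene_variance_equivalence",
                           lv[1, "F value"], lv[1, "Pr(>F)"],
                           alpha_cutoff = alpha,
                           extra = list(note = "Brown-Forsythe (median-centred) stand-in"))
  }
  reject_norm <- any(vapply(shap, function(s) s$decision == "reject",
                            TRUE))
  reject_var <- !is.null(lev) && lev$decision == "reject"
  list(shapiro = shap, levene = lev,
       recommend_nonparametric = reject_norm || reject_var)
}

#' Wilcoxon rank-sum comparisons against a control cohort
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test of each test cohort
#' against the control, with a Bonferroni-corrected cutoff
#' \code{alpha / m} (for the conventional seven contrasts at alpha 0.05
#' this is 0.05/7, reported to three decimals as 0.007). P-values are exact
#' (full enumeration) for combined n <= 10 without ties, and use the normal
#' approximation with tie correction otherwise.
#'
#' @param control numeric vector, the control cohort.
#' @param tests named list of numeric test cohorts.
#' @param m number of comparisons for the Bonferroni correction (default
#'   7; set to \code{length(tests)} to correct within the call).
#' @param alpha family-wise level (default 0.05).
#' @return named list of test results; each carries the per-comparison
#'   p-value, the Bonferroni-adjusted p (\code{min(1, m p)}) and the
#'   decision at the \code{alpha / m} cutoff. Output metadata records the
#'   cutoff explicitly since rounded reports of it are ambiguous.
#' @export
wilcoxon_vs_control <- function(control, tests, m = 7L, alpha = 0.05) {
  if (length(control) < 3L)
    stop("control cohort must have n >= 3", call. = FALSE)
  if (!is.list(tests) || length(tests) == 0L)
    stop("'tests' must be a non-empty named list", call. = FALSE)
  nm <- names(tests) %||% paste0("test", seq_along(tests))
  cutoff <- alpha / m
  out <- lapply(seq_along(tests), function(i) {
    y <- tests[[i]]
    if (length(y) < 3L)
      stop(sprintf("cohort '%s' has n < 3", nm[i]), call. = FALSE)
    exact <- (length(control) + length(y)) <= 10L &&
      !any(duplicated(c(control, y)))
    wt <- suppressWarnings(stats::wilcox.test(
      y, control, alternative = "two.sided", exact = exact,
      correct = !exact))
    new_test_result("wilcoxon_rank_sum", unname(wt$statistic), wt$p.value,
                    adjusted_p = min(1, m * wt$p.value),
                    alpha_cutoff = cutoff,
                    extra = list(label = nm[i], m = m, exact = exact,
                                 cutoff_note = sprintf(
                                   "Bonferroni cutoff alpha/m = %.3f",
                                   cutoff)))
  })
  names(out) <- nm
  out
}

#' Correlation between normalized intensity and surface factor
#'
#' Pearson correlation with a two-sided test, used to ask whether the
#' amount of targeted construct at the array predicts the degree of
#' unfolding (it should not, if unfolding is expression-independent).
#'
#' @param cohort data.frame with \code{normalized_intensity} and
#'   \code{surface_factor} columns, or a list/data.frame of two numeric
#'   vectors.
#' @return test result with the correlation in \code{$r}.
#' @export
pearson_intensity_vs_shape <- function(cohort) {
  x <- cohort[["normalized_intensity"]]
  y <- cohort[["surface_factor"]]
  if (is.null(x) || is.null(y))
    stop("cohort must provide 'normalized_intensity' and 'surface_factor'",
         call. = FALSE)
  if (length(x) < 3L) stop("n >= 3 required", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("values must be finite", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the variables", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  new_test_result("pearson_correlation", unname(ct$statistic), ct$p.value,
                  extra = list(r = unname(ct$estimate), n = length(x)))
}

#' Chi-square test of independence on a 2x2 table
#'
#' Pearson chi-square with one degree of freedom, without continuity
#' correction by default (matching conventional 2x2 reporting); Yates
#' correction available by flag. Used e.g. to test whether array
#' decondensation is independent of cell-cycle stage (condensed/decondensed
#' x S-phase/non-S-phase).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param yates apply the continuity correction.
#' @return test result; when the null is not rejected the interpretation
#'   field reads "independent".
#' @export
chi_square_independence <- function(table, yates = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    stop("'table' must be 2x2", call. = FALSE)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(table) == 0) stop("total count must be > 0", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("a zero marginal makes the test undefined", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(table, correct = yates))
  new_test_result("chi_square_independence", unname(ct$statistic),
                  ct$p.value,
                  extra = list(
                    df = unname(ct$parameter), yates = yates,
                    interpretation = if (ct$p.value >= 0.05)
                      "independent" else "associated"))
}

#' Comparative-Ct (delta-delta-Ct) fold change
#'
#' Relative quantification of gene expression from qPCR cycle thresholds:
#' \code{dCt = mean(target) - mean(reference)} per sample,
#' \code{ddCt = dCt_sample - dCt_calibrator}, fold change
#' \code{2^(-ddCt)}. Replicate standard deviations are propagated in
#' quadrature onto \code{ddCt} and (via the log-derivative) onto the fold
#' change.
#'
#' @param target_ct,reference_ct replicate Ct values for the sample.
#' @param calibrator_target_ct,calibrator_reference_ct replicate Ct values
#'   for the calibrator sample.
#' @return list with \code{ddct}, \code{fold_change}, \code{ddct_sd},
#'   \code{fold_sd}.
#' @export
ddct_fold_change <- function(target_ct, reference_ct,
                             calibrator_target_ct,
                             calibrator_reference_ct) {
  sets <- list(target_ct, reference_ct, calibrator_target_ct,
               calibrator_reference_ct)
  if (any(lengths(sets) == 0L))
    stop("replicate sets must be non-empty", call. = FALSE)
  if (any(!vapply(sets, function(s) all(is.finite(s)), TRUE)))
    stop("Ct values must be finite", call. = FALSE)
  se2 <- function(x) if (length(x) > 1) stats::var(x) / length(x) else 0
  dct_s <- mean(target_ct) - mean(reference_ct)
  dct_c <- mean(calibrator_target_ct) - mean(calibrator_reference_ct)
  ddct <- dct_s - dct_c
  ddct_sd <- sqrt(sum(vapply(sets, se2, 0)))
  fold <- 2^(-ddct)
  list(ddct = ddct, fold_change = fold, ddct_sd = ddct_sd,
       fold_sd = log(2) * fold * ddct_sd)
}

#' Reporter repression relative to an internal reference
#'
#' Luciferase activities are first normalized to the co-transfected
#' internal reference (e.g. beta-galactosidase), then repression is
#' \code{100 * (1 - activity_sample / activity_control)} percent. Negative
#' values indicate activation.
#'
#' @param sample_luc,sample_ref sample luciferase and reference signals.
#' @param control_luc,control_ref control signals.
#' @return percent repression.
#' @export
reporter_repression <- function(sample_luc, sample_ref, control_luc,
                                control_ref) {
  if (sample_ref <= 0 || control_ref <= 0)
    stop("reference signals must be > 0", call. = FALSE)
  act_s <- sample_luc / sample_ref
  act_c <- control_luc / control_ref
  if (act_c == 0) stop("control activity is zero", call. = FALSE)
  100 * (1 - act_s / act_c)
}

#' Percent difference in mean intensity between two populations
#'
#' \code{100 * (mean(a) - mean(b)) / mean(b)}, with a seeded bootstrap
#' confidence interval (percentile method). Used e.g. to compare the
#' expression level of a transfected construct with the endogenous protein
#' level in non-transfected cells.
#'
#' @param group_a_means,group_b_means per-cell mean intensities.
#' @param n_boot bootstrap resamples (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed RNG seed for the bootstrap.
#' @return list with \code{percent_difference}, \code{ci} (length 2),
#'   \code{n_boot}, \code{seed}.
#' @export
population_intensity_ratio <- function(group_a_means, group_b_means,
                                       n_boot = 1000L, conf = 0.95,
                                       seed = 1L) {
  if (length(group_a_means) == 0L || length(group_b_means) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  if (mean(group_b_means) == 0)
    stop("reference group mean is zero", call. = FALSE)
  est <- 100 * (mean(group_a_means) - mean(group_b_means)) /
    mean(group_b_means)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      a <- sample(group_a_means, replace = TRUE)
      b <- sample(group_b_means, replace = TRUE)
      100 * (mean(a) - mean(b)) / mean(b)
    }, 0)
  })
  a2 <- (1 - conf) / 2
  list(percent_difference = est,
       ci = unname(stats::quantile(boot, c(a2, 1 - a2))),
       n_boot = n_boot, seed = seed)
}

#' Box-plot summary statistics per cohort
#'
#' Median, quartiles, whiskers and outliers (Tukey convention via
#' \code{boxplot.stats}) plus min/max and n, one row per cohort -- the
#' numbers behind the usual cohort box plots.
#'
#' @param cohorts named list of numeric vectors.
#' @return data.frame with one row per cohort.
#' @export
cohort_box_stats <- function(cohorts) {
  nm <- names(cohorts) %||% paste0("cohort", seq_along(cohorts))
  do.call(rbind, lapply(seq_along(cohorts), function(i) {
    v <- cohorts[[i]]
    bs <- grDevices::boxplot.stats(v)
    data.frame(cohort = nm[i], n = length(v),
               min = min(v), q1 = stats::quantile(v, 0.25, names = FALSE),
               median = stats::median(v),
               q3 = stats::quantile(v, 0.75, names = FALSE), max = max(v),
               whisker_low = bs$stats[1], whisker_high = bs$stats[5],
               n_outliers = length(bs$out), stringsAsFactors = FALSE)
  }))
}
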