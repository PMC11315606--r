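summarise_group <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) stop("each group needs at least 2 observations")
  list(n = length(x), m = mean(x), s = stats::sd(x))
}

resolve_summaries <- function(n1, m1, s1, n2, m2, s2, x, y) {
  if (!is.null(x)) {
    g1 <- summarise_group(x); g2 <- summarise_group(y)
  } else {
    g1 <- list(n = n1, m = m1, s = s1); g2 <- list(n = n2, m = m2, s = s2)
    if (g1$n < 2 || g2$n < 2) stop("each group needs n >= 2")
  }
  list(g1 = g1, g2 = g2)
}

pooled_sd <- function(g1, g2) {
  sqrt(((g1$n - 1) * g1$s^2 + (g2$n - 1) * g2$s^2) / (g1$n + g2$n - 2))
}

#' Pooled-variance two-sample t-test
#'
#' Accepts either raw vectors (`x`, `y`) or summary statistics (n, mean, SD
#' per group), so printed group summaries can be re-analysed directly. Uses
#' the pooled (equal-variance) standard error with `df = n1 + n2 - 2`; a
#' Welch variant is available via `var_equal = FALSE` (raw-vector input
#' only).
#'
#' @param n1,m1,s1,n2,m2,s2 group sizes, means and SDs (summary interface).
#' @param x,y raw observation vectors (alternative interface).
#' @param var_equal pool the variances (default TRUE).
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
pooled_t <- function(n1 = NULL, m1 = NULL, s1 = NULL,
                     n2 = NULL, m2 = NULL, s2 = NULL,
                     x = NULL, y = NULL, var_equal = TRUE) {
  if (!var_equal) {
    if (is.null(x)) stop("the Welch variant requires raw vectors")
    tt <- stats::t.test(x, y, var.equal = FALSE)
    return(list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value))
  }
  g <- resolve_summaries(n1, m1, s1, n2, m2, s2, x, y)
  sp <- pooled_sd(g$g1, g$g2)
  se <- sp * sqrt(1 / g$g1$n + 1 / g$g2$n)
  if (se == 0) {
    if (g$g1$m == g$g2$m)
      return(list(t = 0, df = g$g1$n + g$g2$n - 2, p = 1))
    stop("zero pooled variance with unequal means")
  }
  t <- (g$g1$m - g$g2$m) / se
  df <- g$g1$n + g$g2$n - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Cohen's d with pooled SD
#'
#' `d = (m1 - m2) / s_pooled`; carries the sign of the mean difference.
#'
#' @inheritParams pooled_t
#' @return numeric effect size.
#' @export
cohens_d <- function(n1 = NULL, m1 = NULL, s1 = NULL,
                     n2 = NULL, m2 = NULL, s2 = NULL,
                     x = NULL, y = NULL) {
  g <- resolve_summaries(n1, m1, s1, n2, m2, s2, x, y)
  sp <- pooled_sd(g$g1, g$g2)
  if (sp == 0) stop("zero pooled SD")
  (g$g1$m - g$g2$m) / sp
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values. In the group-comparison layer the family is the
#' four arbitration measures (preference and switching in each goal
#' condition) within one patient-control pair.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Pearson correlation with two-sided p-value
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return list with `r`, `df`, `p`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), df = unname(ct$parameter), p = ct$p.value)
}

#' Covariate-adjusted group test (ANOVA as a linear model)
#'
#' Fits `measure ~ covariate + group` and reports the partial F-test for the
#' group term after adjusting for the covariate (e.g. sex coded 0/1), the
#' linear-model equivalent of an ANOVA with a covariate.
#'
#' @param measure numeric outcome vector.
#' @param group group membership (2 levels; factor or coercible).
#' @param covariate numeric covariate (e.g. sex indicator).
#' @return list with `F`, `df1`, `df2`, `p` for the group term.
#' @export
lm_with_covariate <- function(measure, group, covariate) {
  group <- factor(group)
  if (nlevels(group) != 2) stop("group must have exactly 2 levels")
  full <- lm(measure ~ covariate + group)
  reduced <- lm(measure ~ covariate)
  an <- stats::anova(reduced, full)
  list(F = an$F[2], df1 = an$Df[2], df2 = an$Res.Df[2], p = an$`Pr(>F)`[2])
}

#' Patient-vs-control comparison of the arbitration measures
#'
#' For one patient-control pair, runs a pooled two-sample t-test on each of
#' the four headline measures (system preference and system switching in the
#' specific and flexible conditions), adjusts the four p-values with
#' Benjamini-Hochberg FDR, and reports Cohen's d. Group 1 is the patient
#' group, so positive t and d mean patient > control.
#'
#' @param metrics data.frame from [cohort_metrics()] covering both groups.
#' @param groups data.frame with columns `subject` and `group`.
#' @param patient,control the two group labels to compare.
#' @param measures measures to test (default the four headline measures; the
#'   FDR family is whatever is supplied here).
#' @return data.frame with one row per measure: group means/SDs/ns, `t`,
#'   `df`, `p_raw`, `p_fdr`, `cohens_d`.
#' @export
compare_groups <- function(metrics, groups, patient, control,
                           measures = c("preference_specific",
                                        "preference_flexible",
                                        "switching_specific",
                                        "switching_flexible")) {
  m <- merge(metrics, groups, by = "subject")
  rows <- lapply(measures, function(ms) {
    x <- m[[ms]][m$group == patient]
    y <- m[[ms]][m$group == control]
    tt <- pooled_t(x = x, y = y)
    data.frame(measure = ms,
               n1 = length(x), mean1 = mean(x), sd1 = stats::sd(x),
               n2 = length(y), mean2 = mean(y), sd2 = stats::sd(y),
               t = tt$t, df = tt$df, p_raw = tt$p,
               cohens_d = cohens_d(x = x, y = y))
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_fdr(out$p_raw)
  out[, c("measure", "n1", "mean1", "sd1", "n2", "mean2", "sd2",
          "t", "df", "p_raw", "p_fdr", "cohens_d")]
}
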