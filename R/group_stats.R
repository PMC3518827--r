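# Validation statistics: descriptive summaries of factor scores and
# two-group comparisons (one-way ANOVA, Levene's test for equality of
# variances, Kruskal-Wallis). ANOVA and Kruskal-Wallis come from
# stats, Levene from car; this module fixes the conventions (centering
# default, standardized-moment definitions) used throughout.

#' Descriptive summary of a score vector
#'
#' Count, mean, median, sample (n-1) standard deviation, minimum,
#' maximum, range, and standardized skewness/kurtosis. The standardized
#' moments are the adjusted Fisher-Pearson sample skewness `G1` divided
#' by `sqrt(6/n)` and the adjusted excess kurtosis `G2` divided by
#' `sqrt(24/n)` — the large-sample z-score convention of the major
#' desktop statistics packages, under which |z| > 2 flags significant
#' departure from normality.
#'
#' @param values Numeric vector, length >= 2.
#' @return One-row data frame with columns `count`, `mean`, `median`,
#'   `sd`, `min`, `max`, `range`, `std_skewness`, `std_kurtosis` (the
#'   last two `NA` when n is too small for the adjusted moments).
#' @export
#' @examples
#' describe(am_cases()$f1)
describe <- function(values) {
  x <- as.numeric(values)
  if (length(x) < 2L || any(!is.finite(x))) {
    stop("describe() needs at least 2 finite values", call. = FALSE)
  }
  n <- length(x)
  m <- mean(x)
  s <- stats::sd(x)
  z <- (x - m) / s
  g1 <- if (n >= 3L && s > 0)
    n / ((n - 1) * (n - 2)) * sum(z^3) else NA_real_
  g2 <- if (n >= 4L && s > 0)
    n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * sum(z^4) -
      3 * (n - 1)^2 / ((n - 2) * (n - 3)) else NA_real_
  data.frame(count = n, mean = m, median = stats::median(x), sd = s,
             min = min(x), max = max(x), range = max(x) - min(x),
             std_skewness = g1 / sqrt(6 / n),
             std_kurtosis = g2 / sqrt(24 / n))
}

#' Descriptive summary table of factor scores
#'
#' One [describe()] row per factor, optionally split by outcome group
#' (mirroring the published overall and by-outcome summary tables).
#'
#' @param scored An `am_scored` data frame.
#' @param by_outcome Split by the `outcome` column.
#' @return Data frame with a `factor` column (and `group` when split).
#' @export
describe_scores <- function(scored, by_outcome = FALSE) {
  fcols <- grep("^f[0-9]+$", names(scored), value = TRUE)
  if (!length(fcols)) stop("no factor-score columns", call. = FALSE)
  if (!by_outcome) {
    out <- do.call(rbind, lapply(fcols, function(fc)
      cbind(factor = fc, describe(scored[[fc]]))))
    return(out)
  }
  if (!"outcome" %in% names(scored)) {
    stop("no outcome column to split by", call. = FALSE)
  }
  rows <- list()
  for (fc in fcols) for (g in c("death", "recovery")) {
    rows[[paste(fc, g)]] <- cbind(factor = fc, group = g,
                                  describe(scored[[fc]][scored$outcome == g]))
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

.check_groups <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (any(!is.finite(c(group_a, group_b)))) {
    stop("non-finite values in groups", call. = FALSE)
  }
}

#' One-way ANOVA F test for two groups
#'
#' Classical equal-variance one-way ANOVA with df (1, n-2); for two
#' groups the F statistic equals the squared pooled-variance t
#' statistic.
#'
#' @param group_a,group_b Numeric vectors (each >= 2 values).
#' @return List with `f`, `p`, `df1`, `df2`.
#' @export
oneway_f <- function(group_a, group_b) {
  .check_groups(group_a, group_b)
  y <- c(group_a, group_b)
  g <- factor(rep(c("a", "b"), c(length(group_a), length(group_b))))
  ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(f = unname(ft$statistic), p = ft$p.value,
       df1 = unname(ft$parameter[1]), df2 = unname(ft$parameter[2]))
}

#' Levene's test for equality of variances (two groups)
#'
#' ANOVA on absolute deviations from the group center. The default
#' center is the median (Brown-Forsythe variant), which reproduces the
#' published validation statistics of the derivation study;
#' mean-centering (the classic Levene test) is available as an option.
#'
#' @param group_a,group_b Numeric vectors (each >= 2 values).
#' @param center `"median"` (default) or `"mean"`.
#' @return List with `stat`, `p`, `center`.
#' @export
levene <- function(group_a, group_b, center = c("median", "mean")) {
  center <- match.arg(center)
  .check_groups(group_a, group_b)
  y <- c(group_a, group_b)
  g <- factor(rep(c("a", "b"), c(length(group_a), length(group_b))))
  lt <- car::leveneTest(y, g, center = if (center == "median")
    stats::median else mean)
  list(stat = lt[1, "F value"], p = lt[1, "Pr(>F)"], center = center)
}

#' Kruskal-Wallis rank test for two groups
#'
#' Rank-based H statistic (average ranks for ties, standard tie
#' correction), p-value from chi-square with 1 df.
#'
#' @param group_a,group_b Numeric vectors; combined length >= 3.
#' @return List with `h`, `p`.
#' @export
kruskal_wallis <- function(group_a, group_b) {
  .check_groups(group_a, group_b)
  kt <- stats::kruskal.test(list(group_a, group_b))
  list(h = unname(kt$statistic), p = kt$p.value)
}

#' Two-group comparison of a factor score
#'
#' Runs ANOVA, Levene (both centerings) and Kruskal-Wallis for a score
#' split by outcome, and recommends which location test to trust:
#' ANOVA when Levene's p >= 0.05, Kruskal-Wallis otherwise.
#'
#' @param values Numeric score vector.
#' @param outcome Character vector of `"recovery"` / `"death"` labels.
#' @param center Levene centering used for the recommendation.
#' @return List with `anova_f`, `anova_p`, `levene_stat`, `levene_p`,
#'   `levene_center`, `kw_stat`, `kw_p`, `recommended`.
#' @export
compare_groups <- function(values, outcome, center = "median") {
  stopifnot(length(values) == length(outcome))
  a <- values[outcome == "death"]
  b <- values[outcome == "recovery"]
  an <- oneway_f(a, b)
  lv <- levene(a, b, center = center)
  kw <- kruskal_wallis(a, b)
  list(anova_f = an$f, anova_p = an$p,
       levene_stat = lv$stat, levene_p = lv$p, levene_center = center,
       kw_stat = kw$h, kw_p = kw$p,
       recommended = if (lv$p >= 0.05) "anova" else "kruskal_wallis")
}
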