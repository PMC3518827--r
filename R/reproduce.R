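# Recomputes every headline statistic of the derivation study from the
# embedded fixtures and compares it with the published value. Each row
# carries an absolute tolerance: half the printed precision for
# display-rounded values, 0.5% of the published value for statistics
# whose inputs the study printed at 5-6 significant digits.

#' Reproduce the published results from the embedded fixtures
#'
#' Recomputes, from the embedded 44-case score table and the published
#' constants: the eigenvalue bookkeeping (sum and cumulative percent at
#' three factors), all eight communalities from the weight matrix,
#' per-factor and overall sensitivity/specificity, the factor-1-only
#' classification agreement, the death rate, descriptive ranges,
#' subgroup means, and the ANOVA / Levene / Kruskal-Wallis statistics
#' per factor.
#'
#' @return An `am_reproduction` data frame with columns `quantity`,
#'   `published`, `recomputed`, `tolerance`, `class` (`"exact"` for
#'   counts and display-rounded percentages, `"rounded"` for statistics
#'   limited by the printed precision of their inputs) and `match`.
#' @export
#' @examples
#' rep <- reproduce_report()
#' all(rep$match)
reproduce_report <- function() {
  rows <- list()
  add <- function(quantity, published, recomputed, tolerance, class) {
    rows[[length(rows) + 1L]] <<- data.frame(
      quantity = quantity, published = published,
      recomputed = recomputed, tolerance = tolerance, class = class)
  }

  ev <- am_eigenvalues()
  smry <- extraction_summary(ev$eigenvalue, p = 8L)
  add("eigenvalue sum", 8, sum(ev$eigenvalue), 1e-5, "exact")
  add("cumulative percent at 3 factors", 69.053,
      smry$cumulative_percent[3], 0.001, "exact")
  add("factors retained (eigenvalue > 1)", 3,
      attr(smry, "n_retained"), 0, "exact")

  W <- am_weights()
  pub_h2 <- am_published_communalities()
  h2 <- communalities(W)
  for (i in seq_len(nrow(h2))) {
    add(paste("communality", h2$parameter[i]), pub_h2$communality[i],
        h2$communality[i], 5e-6, "exact")
  }

  cases <- am_cases()
  scale <- am_scale()
  pf <- per_factor_power(cases, scale)
  pub_pf <- list(c(87, 79), c(87, 50), c(73, 71))
  for (j in 1:3) {
    add(sprintf("SNC factor %d", j), pub_pf[[j]][1], pf$snc[j], 0.5, "exact")
    add(sprintf("SPC factor %d", j), pub_pf[[j]][2], pf$spc[j], 0.5, "exact")
  }
  overall <- diagnostic_power(classify_cases(cases, scale))
  add("SNC overall (majority)", 90, overall$snc, 0.5, "exact")
  add("SPC overall (majority)", 64, overall$spc, 0.5, "exact")

  f1cls <- classify_cases(cases, scale, rule = "f1_only")
  add("factor-1 rule: agreement with published classification", 44,
      sum(f1cls$classification == cases$classification), 0, "exact")
  add("factor-1 rule: misclassified cases", 7,
      sum(f1cls$classification %in% c("FP", "FN")), 0, "exact")

  add("death rate [%]", 31.82, 100 * mean(cases$outcome == "death"),
      0.005, "exact")

  pub_range <- c(14.13, 7.12, 7.01)
  pub_death_mean <- c(-2.52, 0.89, 1.11)
  pub_rec_mean <- c(1.17, -0.41, -0.52)
  pub_anova <- c(21.78, 8.45, 14.18)
  pub_levene <- c(4.0978, 8.9967, 0.0001)
  pub_kw <- c(11.9168, 4.9168, NA)
  for (j in 1:3) {
    s <- cases[[paste0("f", j)]]
    d <- describe(s)
    add(sprintf("range factor %d", j), pub_range[j], d$range, 0.005,
        "rounded")
    add(sprintf("mean factor %d, death group", j), pub_death_mean[j],
        mean(s[cases$outcome == "death"]), 0.005, "rounded")
    add(sprintf("mean factor %d, recovery group", j), pub_rec_mean[j],
        mean(s[cases$outcome == "recovery"]), 0.005, "rounded")
    cg <- compare_groups(s, cases$outcome)
    add(sprintf("ANOVA F factor %d", j), pub_anova[j], cg$anova_f,
        max(0.005 * pub_anova[j], 0.005), "rounded")
    add(sprintf("Levene (median) factor %d", j), pub_levene[j],
        cg$levene_stat, max(0.005 * pub_levene[j], 5e-5), "rounded")
    if (!is.na(pub_kw[j])) {
      add(sprintf("Kruskal-Wallis H factor %d", j), pub_kw[j], cg$kw_stat,
          0.005 * pub_kw[j], "rounded")
    }
  }

  out <- do.call(rbind, rows)
  out$match <- abs(out$recomputed - out$published) <= out$tolerance
  class(out) <- c("am_reproduction", "data.frame")
  out
}

#' @export
print.am_reproduction <- function(x, ...) {
  df <- as.data.frame(x)
  df$published <- signif(df$published, 6)
  df$recomputed <- signif(df$recomputed, 6)
  df$match <- ifelse(df$match, "ok", "MISMATCH")
  print.data.frame(df[c("quantity", "published", "recomputed", "match")],
                   row.names = FALSE, right = FALSE)
  cat(sprintf("\n%d/%d checks matched\n", sum(x$match), nrow(x)))
  invisible(x)
}
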