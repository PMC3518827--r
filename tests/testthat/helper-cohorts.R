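# Programmatic fixtures shared across test files.

# A plausible random cohort with independent-ish parameters.
random_cohort <- function(n, seed = 1, outcome = FALSE) {
  set.seed(seed)
  df <- data.frame(
    age = runif(n, 20, 80),
    coex_diseases = stats::rpois(n, 2),
    hgb = pmax(1, stats::rnorm(n, 12, 2)),
    wbc_pre = stats::rlnorm(n, log(12), 0.3),
    crp_pre = abs(stats::rnorm(n, 150, 50)),
    pct_pre = abs(stats::rnorm(n, 2, 1)),
    proteins = pmax(30, stats::rnorm(n, 60, 6)),
    albumins = NA_real_)
  df$albumins <- pmax(5, pmin(df$proteins - 1, stats::rnorm(n, 32, 3)))
  if (outcome) df$outcome <- sample(c("recovery", "death"), n, TRUE)
  as_am_cohort(df)
}

# One hypothetical patient sitting exactly at the published means,
# optionally shifted by `delta` SDs on selected parameters.
patient_at_means <- function(delta = c()) {
  ref <- am_reference()
  x <- ref$means
  for (p in names(delta)) x[[p]] <- x[[p]] + delta[[p]] * ref$sds[[p]]
  as_am_cohort(as.data.frame(as.list(x)))
}

# Scored-case data frame from raw score triples.
scored_from <- function(f1, f2, f3, outcome = NULL) {
  df <- data.frame(id = as.character(seq_along(f1)),
                   f1 = f1, f2 = f2, f3 = f3)
  if (!is.null(outcome)) df <- cbind(df[1], outcome = outcome, df[-1])
  class(df) <- c("am_scored", "data.frame")
  df
}

# plain varimax criterion, independent of the implementation
raw_varimax_criterion <- function(L) {
  p <- nrow(L)
  sum(apply(L, 2, function(col) sum(col^4) - sum(col^2)^2 / p))
}
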