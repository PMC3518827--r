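test_that("correlation matrix is a unit-diagonal Pearson matrix", {
  coh <- random_cohort(50, seed = 3)
  r <- correlation_matrix(coh)
  expect_identical(dim(r), c(8L, 8L))
  expect_equal(diag(r), setNames(rep(1, 8), am_parameters()))
  expect_equal(r, t(r))

  # two perfectly dependent columns -> off-diagonal exactly 1
  df <- as.data.frame(coh)
  df$albumins <- df$proteins / 2
  r2 <- correlation_matrix(as_am_cohort(df))
  expect_equal(r2["albumins", "proteins"], 1)

  df$age <- 50
  expect_error(correlation_matrix(as_am_cohort(df)), "age")
})

test_that("independent columns have near-zero sample correlations", {
  coh <- random_cohort(10000, seed = 11)
  r <- correlation_matrix(coh)
  offdiag <- r[upper.tri(r)]
  # albumins is truncated against proteins in the helper; exclude it
  keep <- upper.tri(r) & !(rownames(r) == "albumins")[row(r)] &
    !(colnames(r) == "albumins")[col(r)]
  expect_lt(max(abs(r[keep])), 0.05)
})

test_that("2x2 extraction matches the closed-form eigenvalues 1 +/- r", {
  for (r in c(-0.8, 0.3, 0.65)) {
    m <- matrix(c(1, r, r, 1), 2)
    ex <- extract_factors(m)
    expect_equal(ex$eigenvalues, c(1 + abs(r), 1 - abs(r)), tolerance = 1e-12)
  }
})

test_that("p=3 eigenvalues match characteristic-polynomial roots", {
  set.seed(5)
  x <- matrix(rnorm(300), 100, 3)
  x[, 2] <- x[, 2] + 0.5 * x[, 1]
  m <- cor(x)
  ex <- extract_factors(m)
  # det(m - lambda I) = -lambda^3 + tr lambda^2 - c2 lambda + det
  c2 <- (m[1,1]*m[2,2] - m[1,2]*m[2,1]) +
    (m[1,1]*m[3,3] - m[1,3]*m[3,1]) + (m[2,2]*m[3,3] - m[2,3]*m[3,2])
  roots <- sort(Re(polyroot(c(-det(m), c2, -sum(diag(m)), 1))),
                decreasing = TRUE)
  expect_equal(ex$eigenvalues, roots, tolerance = 1e-9)
})

test_that("identity correlation matrix retains nothing under strict Kaiser", {
  ex <- extract_factors(diag(3))
  expect_equal(ex$n_retained, 0)
  expect_null(ex$loadings)
})

test_that("all-component loadings reconstruct the correlation matrix", {
  coh <- random_cohort(60, seed = 9)
  m <- correlation_matrix(coh)
  e <- eigen(m, symmetric = TRUE)
  recon <- Reduce(`+`, lapply(seq_len(8), function(j)
    e$values[j] * tcrossprod(e$vectors[, j])))
  expect_lt(max(abs(recon - m)), 1e-8)
})

test_that("extraction summary reproduces the published bookkeeping", {
  ev <- am_eigenvalues()
  smry <- extraction_summary(ev$eigenvalue, p = 8)
  expect_equal(sum(ev$eigenvalue), 8, tolerance = 1e-6)
  expect_equal(smry$cumulative_percent[3], 69.053, tolerance = 1e-5)
  expect_equal(attr(smry, "n_retained"), 3)
  expect_equal(smry$percent_variance, ev$percent_variance, tolerance = 1e-4)
  expect_equal(smry$cumulative_percent[8], 100, tolerance = 1e-4)
})

test_that("non-symmetric input is a contract error", {
  m <- diag(3); m[1, 2] <- 0.5
  expect_error(extract_factors(m), "symmetric")
})

test_that("communalities are row sums of squares, published rows included", {
  w <- am_weights()
  h2 <- communalities(w)
  expect_equal(h2$communality[h2$parameter == "albumins"], 0.862124,
               tolerance = 5e-6)
  expect_equal(h2$communality[h2$parameter == "hgb"], 0.589401,
               tolerance = 5e-6)
  expect_equal(h2$communality + h2$specific_variance, rep(1, 8))
  z <- communalities(matrix(0, 2, 3))
  expect_equal(z$communality, c(0, 0))
  expect_equal(z$specific_variance, c(1, 1))
})

test_that("scoring standardizes against the reference", {
  sc0 <- factor_scores(patient_at_means())
  expect_equal(unlist(sc0[c("f1", "f2", "f3")], use.names = FALSE),
               c(0, 0, 0), tolerance = 1e-12)
  sc1 <- factor_scores(patient_at_means(c(albumins = 1)))
  expect_equal(unlist(sc1[c("f1", "f2", "f3")], use.names = FALSE),
               unname(am_weights()["albumins", ]), tolerance = 1e-12)
})

test_that("self-referenced scores are mean-centered", {
  coh <- random_cohort(200, seed = 13)
  x <- as.matrix(as.data.frame(coh)[am_parameters()])
  ref <- new_am_reference(colMeans(x), apply(x, 2, sd))
  sc <- factor_scores(coh, ref, am_weights())
  expect_equal(mean(sc$f1), 0, tolerance = 1e-12)
  expect_equal(mean(sc$f2), 0, tolerance = 1e-12)
  expect_equal(mean(sc$f3), 0, tolerance = 1e-12)
})

test_that("regression scoring equals the solve() oracle", {
  coh <- random_cohort(100, seed = 17)
  x <- as.matrix(as.data.frame(coh)[am_parameters()])
  ref <- new_am_reference(colMeans(x), apply(x, 2, sd))
  r <- correlation_matrix(coh)
  w <- am_weights()
  sc <- factor_scores(coh, ref, w, method = "regression", corr = r)
  z <- scale(x)
  oracle <- z %*% solve(r) %*% w
  expect_equal(sc$f1, unname(oracle[, 1]), tolerance = 1e-10)
  expect_error(factor_scores(coh, ref, w, method = "regression"),
               "correlation")
  expect_error(factor_scores(coh, ref, w[1:5, ]), "row per parameter")
})
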