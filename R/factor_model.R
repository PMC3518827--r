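# Exploratory factor analysis by principal components on the
# correlation matrix: the machinery that derives scales like the
# published one. Extraction keeps components with eigenvalue > 1
# (Kaiser criterion, strict); rotation is varimax with Kaiser row
# normalization, implemented as pairwise Jacobi sweeps.

#' Pearson correlation matrix of a cohort
#'
#' @param cohort An `am_cohort`.
#' @return Symmetric 8 x 8 correlation matrix with unit diagonal,
#'   parameters in canonical order.
#' @export
correlation_matrix <- function(cohort) {
  stopifnot(inherits(cohort, "am_cohort"))
  x <- .param_matrix(cohort)
  if (nrow(x) < 3L) stop("need at least 3 patients for correlations",
                         call. = FALSE)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant parameter(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(x)
  diag(r) <- 1
  r
}

#' Eigenvalue summary with Kaiser retention
#'
#' Turns a descending eigenvalue vector into the extraction summary:
#' percent of variance (`eigenvalue / p * 100`), its running cumulative
#' percentage, and the number of factors retained under the strict
#' Kaiser rule (eigenvalue > 1; a value of exactly 1 is not retained).
#'
#' @param eigenvalues Non-increasing, non-negative numeric vector.
#' @param p Number of variables (defaults to `length(eigenvalues)`).
#' @return Data frame with columns `component`, `eigenvalue`,
#'   `percent_variance`, `cumulative_percent`, plus attribute
#'   `n_retained`.
#' @export
extraction_summary <- function(eigenvalues, p = length(eigenvalues)) {
  stopifnot(is.numeric(eigenvalues), !is.unsorted(rev(eigenvalues)))
  pct <- eigenvalues / p * 100
  out <- data.frame(component = seq_along(eigenvalues),
                    eigenvalue = eigenvalues,
                    percent_variance = pct,
                    cumulative_percent = cumsum(pct))
  attr(out, "n_retained") <- sum(eigenvalues > 1)
  out
}

#' Principal-component factor extraction
#'
#' Eigendecomposition of a correlation matrix with initial
#' communalities fixed at 1 (principal components method). Unrotated
#' loading column j is `eigenvector_j * sqrt(eigenvalue_j)`; columns
#' with eigenvalue > 1 are retained (strict Kaiser criterion).
#'
#' @param corr Symmetric positive semi-definite correlation matrix.
#' @param tol Symmetry tolerance.
#' @return List of class `am_extraction` with elements `summary` (see
#'   [extraction_summary()]), `eigenvalues`, `loadings` (p x k
#'   unrotated retained loadings, attribute `rotated = FALSE`) and
#'   `n_retained`.
#' @export
extract_factors <- function(corr, tol = 1e-8) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  if (max(abs(corr - t(corr))) > tol) {
    stop("correlation matrix is not symmetric", call. = FALSE)
  }
  e <- eigen((corr + t(corr)) / 2, symmetric = TRUE)
  if (min(e$values) < -tol * nrow(corr)) {
    stop("correlation matrix is not positive semi-definite", call. = FALSE)
  }
  vals <- pmax(e$values, 0)
  smry <- extraction_summary(vals, p = nrow(corr))
  k <- attr(smry, "n_retained")
  L <- NULL
  if (k > 0L) {
    L <- e$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(vals[seq_len(k)]), k)
    dimnames(L) <- list(rownames(corr), paste0("F", seq_len(k)))
    L <- .orient_loadings(L, reorder = FALSE)
    attr(L, "rotated") <- FALSE
  }
  structure(list(summary = smry, eigenvalues = vals,
                 loadings = L, n_retained = k),
            class = "am_extraction")
}

#' @export
print.am_extraction <- function(x, ...) {
  cat("Principal-component extraction:", x$n_retained,
      "factor(s) retained (eigenvalue > 1)\n")
  print(x$summary, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Varimax rotation by pairwise Jacobi sweeps
#'
#' Orthogonal rotation maximizing the varimax criterion (the sum over
#' factors of the variance of squared loadings). With
#' `kaiser_normalize = TRUE` (default) rows are scaled to unit
#' communality before rotating and rescaled afterwards, so every
#' variable contributes equally to the criterion. Row communalities are
#' preserved exactly; after convergence, columns are ordered by
#' explained variance (descending sum of squares) and signed so that
#' each column's largest-magnitude loading is positive.
#'
#' @param loadings p x k numeric loading matrix (k >= 1; k = 1 is
#'   returned unchanged).
#' @param kaiser_normalize Scale rows to unit length during rotation.
#' @param tol Convergence tolerance on the criterion gain per sweep.
#' @param max_sweeps Sweep limit; exceeding it without convergence is
#'   an error reporting the last gain.
#' @return Rotated loading matrix with attributes `rotated = TRUE`,
#'   `rotation` (the k x k orthogonal matrix, before column
#'   reordering/signing) and `sweeps`.
#' @export
varimax_rotate <- function(loadings, kaiser_normalize = TRUE,
                           tol = 1e-10, max_sweeps = 1000L) {
  L <- as.matrix(loadings)
  p <- nrow(L); k <- ncol(L)
  if (k < 2L) return(loadings)
  h <- sqrt(rowSums(L^2))
  A <- if (kaiser_normalize) L / ifelse(h > 0, h, 1) else L
  rot <- diag(k)
  crit_old <- .varimax_criterion(A)
  crit_new <- crit_old
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    if (sweeps > max_sweeps) {
      stop(sprintf(
        "varimax did not converge in %d sweeps (last criterion gain %.3e)",
        max_sweeps, crit_new - crit_old), call. = FALSE)
    }
    for (j in seq_len(k - 1L)) {
      for (l in seq((j + 1L), k)) {
        x <- A[, j]; y <- A[, l]
        u <- x^2 - y^2
        v <- 2 * x * y
        num <- sum(2 * u * v) - 2 * sum(u) * sum(v) / p
        den <- sum(u^2 - v^2) - (sum(u)^2 - sum(v)^2) / p
        phi <- atan2(num, den) / 4
        if (abs(phi) > 1e-15) {
          cs <- cos(phi); sn <- sin(phi)
          A[, j] <- cs * x + sn * y
          A[, l] <- -sn * x + cs * y
          g <- rot[, j]
          rot[, j] <- cs * g + sn * rot[, l]
          rot[, l] <- -sn * g + cs * rot[, l]
        }
      }
    }
    crit_new <- .varimax_criterion(A)
    if (crit_new - crit_old < tol) break
    crit_old <- crit_new
  }
  out <- if (kaiser_normalize) A * ifelse(h > 0, h, 1) else A
  dimnames(out) <- dimnames(L)
  out <- .orient_loadings(out, reorder = TRUE)
  attr(out, "rotated") <- TRUE
  attr(out, "rotation") <- rot
  attr(out, "sweeps") <- sweeps
  out
}

# raw varimax criterion: sum over columns of the variance of squared
# loadings (times p; monotone-equivalent form)
.varimax_criterion <- function(L) {
  p <- nrow(L)
  sum(apply(L, 2L, function(col) sum(col^4) - sum(col^2)^2 / p))
}

# deterministic orientation: optionally order columns by explained
# variance, then flip signs so the largest-|loading| entry is positive
.orient_loadings <- function(L, reorder = TRUE) {
  if (reorder) {
    ord <- order(colSums(L^2), decreasing = TRUE)
    L <- L[, ord, drop = FALSE]
    colnames(L) <- paste0("F", seq_len(ncol(L)))
  }
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  L
}

#' Communalities and specific variances
#'
#' Row sums of squared loadings (the proportion of each variable's
#' variance attributable to the retained factors) and their complement.
#'
#' @param loadings p x k loading matrix.
#' @return Data frame with columns `parameter`, `communality`,
#'   `specific_variance` (summing to 1 by construction).
#' @export
communalities <- function(loadings) {
  L <- as.matrix(loadings)
  h2 <- rowSums(L^2)
  data.frame(parameter = rownames(L) %||% paste0("v", seq_along(h2)),
             communality = h2,
             specific_variance = 1 - h2,
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Factor scores for a cohort
#'
#' Standardizes each parameter with the reference (`z = (x - mean) /
#' sd`) and combines the standardized values into factor scores. With
#' `method = "loading_weights"` (default, the published scale's rule)
#' the weight-matrix entries multiply the z-values directly:
#' `score_j = sum_i weights[i, j] * z_i`. With `method = "regression"`
#' the score coefficients are `solve(corr) %*% weights` (the standard
#' regression/Thurstone estimator), requiring the correlation matrix.
#'
#' @param cohort An `am_cohort`.
#' @param ref An `am_reference` (means and sds).
#' @param weights p x k weight matrix in canonical parameter order.
#' @param method `"loading_weights"` or `"regression"`.
#' @param corr Correlation matrix (required for `"regression"`).
#' @return An `am_scored` data frame: `id`, `outcome` (if present in
#'   the cohort) and score columns `f1 ... fk`.
#' @export
factor_scores <- function(cohort, ref = am_reference(),
                          weights = am_weights(),
                          method = c("loading_weights", "regression"),
                          corr = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(cohort, "am_cohort"), inherits(ref, "am_reference"))
  W <- as.matrix(weights)
  if (nrow(W) != length(am_parameters())) {
    stop("weight matrix must have one row per parameter (",
         length(am_parameters()), ")", call. = FALSE)
  }
  x <- .param_matrix(cohort)
  z <- sweep(sweep(x, 2L, ref$means, "-"), 2L, ref$sds, "/")
  coef <- switch(method,
    loading_weights = W,
    regression = {
      if (is.null(corr)) {
        stop("regression scoring needs the correlation matrix", call. = FALSE)
      }
      solve(corr, W)
    })
  s <- z %*% coef
  out <- data.frame(id = cohort$id, stringsAsFactors = FALSE)
  if ("outcome" %in% names(cohort)) out$outcome <- cohort$outcome
  for (j in seq_len(ncol(s))) out[[paste0("f", j)]] <- as.numeric(s[, j])
  attr(out, "method") <- method
  class(out) <- c("am_scored", "data.frame")
  out
}
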