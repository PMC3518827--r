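# Embedded constants of the published 44-patient acute mediastinitis
# derivation study, shipped as plain-text tables under inst/extdata.
# Integrity is checked at every load (cheap; the tables are tiny).

.fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "amprog", mustWork = FALSE)
  if (!nzchar(p)) stop("fixture not found: ", file, call. = FALSE)
  p
}

#' Published standardization reference
#'
#' Means and sample standard deviations of the eight admission
#' parameters in the 44-patient derivation cohort, used to standardize
#' raw values before factor scoring (`z = (x - mean) / sd`).
#'
#' @return An `am_reference`: list with named numeric vectors `means`
#'   and `sds` in canonical parameter order.
#' @export
#' @examples
#' am_reference()$means[["age"]]
am_reference <- function() {
  df <- utils::read.csv(.fixture_path("standardization.csv"),
                        comment.char = "#")
  stopifnot(identical(df$parameter, am_parameters()),
            all(df$sd > 0), all(is.finite(df$mean)))
  new_am_reference(stats::setNames(df$mean, df$parameter),
                   stats::setNames(df$sd, df$parameter))
}

#' Construct a standardization reference
#'
#' @param means,sds Numeric vectors of length 8 in canonical parameter
#'   order; `sds` strictly positive.
#' @return An `am_reference` list.
#' @export
new_am_reference <- function(means, sds) {
  pars <- am_parameters()
  means <- stats::setNames(as.numeric(means), pars)
  sds <- stats::setNames(as.numeric(sds), pars)
  if (length(means) != 8L || length(sds) != 8L) {
    stop("reference needs 8 means and 8 sds", call. = FALSE)
  }
  if (any(!is.finite(means)) || any(!is.finite(sds)) || any(sds <= 0)) {
    stop("reference sds must be finite and strictly positive", call. = FALSE)
  }
  structure(list(means = means, sds = sds), class = "am_reference")
}

#' Published factor weight matrix
#'
#' The varimax-rotated 8 x 3 weight matrix of the published recovery
#' scale (rows: parameters in canonical order; columns: proteinic
#' status, inflammatory status, general risk). These entries are used
#' verbatim as score weights on standardized parameters.
#'
#' @return Numeric matrix with parameter rownames and colnames
#'   `F1`, `F2`, `F3`.
#' @export
am_weights <- function() {
  df <- utils::read.csv(.fixture_path("factor_weights.csv"),
                        comment.char = "#")
  stopifnot(identical(df$parameter, am_parameters()))
  w <- as.matrix(df[c("F1", "F2", "F3")])
  rownames(w) <- df$parameter
  stopifnot(all(abs(w) <= 1), all(rowSums(w^2) <= 1))
  w
}

#' Published communalities
#'
#' The printed communality and specific-variance values for the eight
#' parameters (kept alongside the weights for reproduction checks).
#'
#' @return Data frame with columns `parameter`, `communality`,
#'   `specific_variance`.
#' @export
am_published_communalities <- function() {
  df <- utils::read.csv(.fixture_path("factor_weights.csv"),
                        comment.char = "#")
  df[c("parameter", "communality", "specific_variance")]
}

#' Published eigenvalue table
#'
#' The eight eigenvalues of the principal-component extraction on the
#' derivation cohort's correlation matrix, with the printed percent of
#' variance and cumulative percentage.
#'
#' @return Data frame with columns `component`, `eigenvalue`,
#'   `percent_variance`, `cumulative_percent`.
#' @export
am_eigenvalues <- function() {
  df <- utils::read.csv(.fixture_path("eigenvalues.csv"),
                        comment.char = "#")
  stopifnot(nrow(df) == 8L, !is.unsorted(rev(df$eigenvalue)))
  df
}

#' Published scored cases
#'
#' The 44 cases of the derivation cohort with observed outcome, the
#' three factor scores and the published classification label (which
#' follows the factor-1-only rule). Integrity is verified at load:
#' 30 recoveries and 14 deaths.
#'
#' @return An `am_scored` data frame with columns `id`, `outcome`,
#'   `f1`, `f2`, `f3`, `classification`.
#' @export
#' @examples
#' cases <- am_cases()
#' table(cases$outcome)
am_cases <- function() {
  df <- utils::read.csv(.fixture_path("scored_cases.csv"),
                        comment.char = "#", stringsAsFactors = FALSE)
  df$id <- as.character(df$id)
  stopifnot(nrow(df) == 44L,
            sum(df$outcome == "recovery") == 30L,
            sum(df$outcome == "death") == 14L,
            all(df$classification %in% c("TP", "TN", "FP", "FN")))
  class(df) <- c("am_scored", "data.frame")
  df
}
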