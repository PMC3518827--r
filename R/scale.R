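# The recovery-prediction scale: per-factor thresholds, vote
# combination, confusion classification and diagnostic power.
#
# Vote semantics: a factor votes "recovery" by a strict inequality on
# its recovery side; a score exactly at the cutoff votes non-recovery
# (conservative toward predicting death). The positive test outcome is
# "recovery": TP = recovered and predicted recovery, TN = died and
# predicted death, FP = died but predicted recovery, FN = recovered
# but predicted death. SNC = 100*TP/(TP+FN), SPC = 100*TN/(TN+FP).

.combinations <- c("majority", "f1_only", "unanimous")

#' Construct a scale definition
#'
#' @param ref An `am_reference` (standardization constants).
#' @param weights p x k factor weight matrix.
#' @param thresholds Data frame with columns `cutoff` (numeric) and
#'   `recovery_side` (`"above"` or `"below"`), one row per factor.
#' @param combination Vote combination rule: `"majority"` (recovery iff
#'   at least 2 of 3 factors vote recovery), `"f1_only"`, or
#'   `"unanimous"`.
#' @param factor_names Optional factor labels.
#' @return An `am_scale` list.
#' @export
new_am_scale <- function(ref, weights, thresholds,
                         combination = "majority", factor_names = NULL) {
  stopifnot(inherits(ref, "am_reference"))
  W <- as.matrix(weights)
  combination <- match.arg(combination, .combinations)
  if (!is.data.frame(thresholds) ||
      !all(c("cutoff", "recovery_side") %in% names(thresholds))) {
    stop("thresholds must be a data frame with cutoff and recovery_side",
         call. = FALSE)
  }
  if (nrow(thresholds) != ncol(W)) {
    stop("need one threshold per weight column", call. = FALSE)
  }
  if (!all(thresholds$recovery_side %in% c("above", "below"))) {
    stop("recovery_side must be 'above' or 'below'", call. = FALSE)
  }
  if (is.null(factor_names)) factor_names <- colnames(W) %||%
    paste0("F", seq_len(ncol(W)))
  structure(list(ref = ref, weights = W,
                 thresholds = as.data.frame(thresholds),
                 combination = combination,
                 factor_names = factor_names),
            class = "am_scale")
}

#' The published acute mediastinitis recovery scale
#'
#' The fixed scale of the derivation study: published means and SDs,
#' the varimax-rotated weight matrix, and the three recovery
#' thresholds — proteinic status above -1.4, inflammatory status below
#' 1.0, general risk below 0.4 — combined by 2-of-3 majority vote.
#'
#' @return An `am_scale`.
#' @export
#' @examples
#' sc <- am_scale()
#' sc$thresholds
am_scale <- function() {
  read_scale(.fixture_path("published_scale.yaml"))
}

#' Read / write a scale definition (YAML)
#'
#' A scale file stores the parameter order, factor names, means, SDs,
#' weight columns, thresholds and the combination rule.
#'
#' @param path File path.
#' @return [read_scale()]: an `am_scale`. [write_scale()]: `path`,
#'   invisibly.
#' @export
read_scale <- function(path) {
  if (!file.exists(path)) stop("scale file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  pars <- unlist(y$parameters)
  if (!identical(pars, am_parameters())) {
    stop("scale file parameter order differs from the canonical order",
         call. = FALSE)
  }
  W <- sapply(y$weights, unlist)
  rownames(W) <- pars
  thr <- do.call(rbind, lapply(y$thresholds, function(t)
    data.frame(cutoff = t$cutoff, recovery_side = t$recovery_side)))
  sc <- new_am_scale(new_am_reference(unlist(y$means), unlist(y$sds)),
                     W, thr, y$combination %||% "majority",
                     unlist(y$factor_names))
  sc$name <- y$name
  sc$provenance <- y$provenance
  sc
}

#' @rdname read_scale
#' @param scale An `am_scale`.
#' @export
write_scale <- function(scale, path) {
  stopifnot(inherits(scale, "am_scale"))
  y <- list(
    name = scale$name %||% "derived scale",
    parameters = am_parameters(),
    factor_names = scale$factor_names,
    means = unname(scale$ref$means),
    sds = unname(scale$ref$sds),
    weights = stats::setNames(
      lapply(seq_len(ncol(scale$weights)),
             function(j) unname(scale$weights[, j])),
      colnames(scale$weights) %||% paste0("F", seq_len(ncol(scale$weights)))),
    thresholds = lapply(seq_len(nrow(scale$thresholds)), function(i)
      list(cutoff = scale$thresholds$cutoff[i],
           recovery_side = scale$thresholds$recovery_side[i])),
    combination = scale$combination,
    provenance = scale$provenance %||% "derived by amprog"
  )
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

#' @export
print.am_scale <- function(x, ...) {
  cat(x$name %||% "Recovery prediction scale", "\n")
  cat(sprintf("  %d factors over %d parameters; combination rule: %s\n",
              ncol(x$weights), nrow(x$weights), x$combination))
  for (j in seq_len(nrow(x$thresholds))) {
    cat(sprintf("  %-20s recovery vote iff score %s %g\n",
                x$factor_names[j],
                if (x$thresholds$recovery_side[j] == "above") ">" else "<",
                x$thresholds$cutoff[j]))
  }
  invisible(x)
}

# logical vote matrix (TRUE = recovery vote), one column per factor
.vote_matrix <- function(scored, scale) {
  k <- nrow(scale$thresholds)
  fcols <- paste0("f", seq_len(k))
  if (!all(fcols %in% names(scored))) {
    stop("scored cases lack score columns ",
         paste(setdiff(fcols, names(scored)), collapse = ", "),
         call. = FALSE)
  }
  s <- as.matrix(as.data.frame(scored)[fcols])
  if (any(!is.finite(s))) stop("non-finite factor scores", call. = FALSE)
  v <- matrix(NA, nrow(s), k)
  for (j in seq_len(k)) {
    v[, j] <- if (scale$thresholds$recovery_side[j] == "above")
      s[, j] > scale$thresholds$cutoff[j]
    else
      s[, j] < scale$thresholds$cutoff[j]
  }
  colnames(v) <- paste0("vote", seq_len(k))
  v
}

.combine_votes <- function(votes, rule) {
  rule <- match.arg(rule, .combinations)
  rec <- switch(rule,
    majority = rowSums(votes) * 2 > ncol(votes),
    f1_only = votes[, 1L],
    unanimous = rowSums(votes) == ncol(votes))
  ifelse(rec, "recovery", "death")
}

#' Predict recovery from factor scores
#'
#' Applies the per-factor thresholds (strict inequality; equality at a
#' cutoff votes non-recovery) and combines the votes by the scale's
#' rule or an override.
#'
#' @param scored An `am_scored` data frame (columns `f1 ... fk`).
#' @param scale An `am_scale` (default: the published scale).
#' @param rule Optional combination-rule override (`"majority"`,
#'   `"f1_only"`, `"unanimous"`).
#' @return `scored` with added logical columns `vote1 ... votek` (TRUE
#'   = recovery vote) and a `predicted` column.
#' @export
#' @examples
#' predict_recovery(am_cases())[1:3, ]
predict_recovery <- function(scored, scale = am_scale(), rule = NULL) {
  stopifnot(inherits(scale, "am_scale"))
  v <- .vote_matrix(scored, scale)
  out <- as.data.frame(scored)
  out[colnames(v)] <- as.data.frame(v)
  out$predicted <- .combine_votes(v, rule %||% scale$combination)
  class(out) <- c("am_scored", "data.frame")
  out
}

#' Classify predictions against observed outcomes
#'
#' Labels every case TP/TN/FP/FN (positive = predicted recovery) and
#' aggregates the confusion counts.
#'
#' @inheritParams predict_recovery
#' @return An `am_scored` data frame with `votes`, `predicted` and
#'   `classification` columns and an `"confusion"` attribute; retrieve
#'   the counts with [confusion_counts()].
#' @export
classify_cases <- function(scored, scale = am_scale(), rule = NULL) {
  if (!"outcome" %in% names(scored) || any(is.na(scored$outcome))) {
    missing_ids <- if ("outcome" %in% names(scored))
      scored$id[is.na(scored$outcome)] else scored$id
    stop("cases without observed outcome: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  out <- predict_recovery(scored, scale, rule)
  out$classification <- .classify(out$outcome, out$predicted)
  attr(out, "confusion") <- .count_confusion(out$classification)
  out
}

.classify <- function(observed, predicted) {
  ifelse(predicted == "recovery",
         ifelse(observed == "recovery", "TP", "FP"),
         ifelse(observed == "death", "TN", "FN"))
}

.count_confusion <- function(cls) {
  structure(list(tp = sum(cls == "TP"), tn = sum(cls == "TN"),
                 fp = sum(cls == "FP"), fn = sum(cls == "FN")),
            class = "am_confusion")
}

#' Confusion counts of a classified cohort
#'
#' @param x An `am_scored` returned by [classify_cases()], or a
#'   character vector of TP/TN/FP/FN labels.
#' @return An `am_confusion` list with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(x) {
  if (inherits(x, "am_confusion")) return(x)
  cls <- if (is.data.frame(x)) {
    cc <- attr(x, "confusion")
    if (!is.null(cc)) return(cc)
    x$classification
  } else x
  if (is.null(cls) || !all(cls %in% c("TP", "TN", "FP", "FN"))) {
    stop("no valid classification labels", call. = FALSE)
  }
  .count_confusion(cls)
}

#' @export
print.am_confusion <- function(x, ...) {
  cat(sprintf("TP=%d TN=%d FP=%d FN=%d (n=%d)\n",
              x$tp, x$tn, x$fp, x$fn, x$tp + x$tn + x$fp + x$fn))
  invisible(x)
}

#' Sensitivity and specificity
#'
#' `snc = 100 * tp / (tp + fn)`; `spc = 100 * tn / (tn + fp)`, both on
#' the percent scale at full precision (round only for display). An
#' undefined coefficient (zero denominator) is `NA`, never 0.
#'
#' @param counts An `am_confusion` (see [confusion_counts()]).
#' @return An `am_power` list with `snc` and `spc`.
#' @export
#' @examples
#' diagnostic_power(confusion_counts(classify_cases(am_cases())))
diagnostic_power <- function(counts) {
  counts <- confusion_counts(counts)
  snc <- if (counts$tp + counts$fn > 0)
    100 * counts$tp / (counts$tp + counts$fn) else NA_real_
  spc <- if (counts$tn + counts$fp > 0)
    100 * counts$tn / (counts$tn + counts$fp) else NA_real_
  structure(list(snc = snc, spc = spc, counts = counts),
            class = "am_power")
}

#' @export
print.am_power <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.0f%%", v)
  cat(sprintf("SNC = %s, SPC = %s\n", fmt(x$snc), fmt(x$spc)))
  invisible(x)
}

#' Per-factor diagnostic power
#'
#' Treats each single factor's vote as the prediction and reports
#' sensitivity/specificity per factor.
#'
#' @inheritParams classify_cases
#' @return Data frame with one row per factor: `factor`, `tp`, `fn`,
#'   `tn`, `fp`, `snc`, `spc`.
#' @export
per_factor_power <- function(scored, scale = am_scale()) {
  if (!"outcome" %in% names(scored) || any(is.na(scored$outcome))) {
    stop("per-factor power needs observed outcomes for every case",
         call. = FALSE)
  }
  v <- .vote_matrix(scored, scale)
  out <- lapply(seq_len(ncol(v)), function(j) {
    pred <- ifelse(v[, j], "recovery", "death")
    cc <- .count_confusion(.classify(scored$outcome, pred))
    pw <- diagnostic_power(cc)
    data.frame(factor = scale$factor_names[j],
               tp = cc$tp, fn = cc$fn, tn = cc$tn, fp = cc$fp,
               snc = pw$snc, spc = pw$spc)
  })
  do.call(rbind, out)
}

#' Derive per-factor recovery thresholds
#'
#' With `method = "youden"`, searches the midpoints of adjacent sorted
#' observed scores per factor and picks the cutoff maximizing the
#' Youden index `SNC/100 + SPC/100 - 1`; the recovery side is the side
#' of the recovery-group mean. Ties are broken toward the lowest
#' cutoff. With `method = "fixed"` the supplied cutoffs pass through.
#' Threshold derivation is an explicit extension of the published
#' scale, whose cutoffs were chosen by inspection of density traces;
#' derived thresholds are flagged as such.
#'
#' @param scored An `am_scored` with outcomes for every case.
#' @param method `"youden"` or `"fixed"`.
#' @param cutoffs Numeric vector of cutoffs (for `"fixed"`).
#' @param sides Character vector of recovery sides (for `"fixed"`).
#' @return Data frame with columns `cutoff`, `recovery_side`, `youden`
#'   and attribute `method`.
#' @export
derive_thresholds <- function(scored, method = c("youden", "fixed"),
                              cutoffs = NULL, sides = NULL) {
  method <- match.arg(method)
  fcols <- grep("^f[0-9]+$", names(scored), value = TRUE)
  if (method == "fixed") {
    stopifnot(length(cutoffs) == length(fcols),
              length(sides) == length(fcols))
    out <- data.frame(cutoff = cutoffs, recovery_side = sides,
                      youden = NA_real_)
    attr(out, "method") <- "fixed"
    return(out)
  }
  if (!"outcome" %in% names(scored) ||
      length(unique(scored$outcome)) < 2L) {
    stop("threshold derivation needs both outcome classes", call. = FALSE)
  }
  rec <- scored$outcome == "recovery"
  rows <- lapply(fcols, function(fc) {
    s <- scored[[fc]]
    side <- if (mean(s[rec]) > mean(s[!rec])) "above" else "below"
    u <- sort(unique(s))
    mids <- (u[-1] + u[-length(u)]) / 2
    j <- vapply(mids, function(ct) {
      vote <- if (side == "above") s > ct else s < ct
      snc <- sum(vote & rec) / sum(rec)
      spc <- sum(!vote & !rec) / sum(!rec)
      snc + spc - 1
    }, numeric(1))
    best <- which(j == max(j))[1L]
    data.frame(cutoff = mids[best], recovery_side = side,
               youden = max(j))
  })
  out <- do.call(rbind, rows)
  attr(out, "method") <- "youden"
  out
}

#' Derive a full scale from a cohort
#'
#' End-to-end derivation: estimate the standardization reference (mean,
#' n-1 SD) from the cohort, correlate, extract principal-component
#' factors (strict Kaiser retention), varimax-rotate, score with the
#' rotated loadings as weights, and pick per-factor thresholds. Refused
#' when the cohort is not larger than the parameter count (singular
#' correlation matrix); scoring with an externally supplied scale has
#' no such restriction.
#'
#' @param cohort An `am_cohort`; outcomes required for
#'   `threshold_method = "youden"`.
#' @param threshold_method Passed to [derive_thresholds()].
#' @param combination Vote combination rule for the derived scale.
#' @param ... Passed to [varimax_rotate()].
#' @return An `am_scale` with attributes `extraction` and `scores`.
#' @export
derive_scale <- function(cohort, threshold_method = "youden",
                         combination = "majority", ...) {
  stopifnot(inherits(cohort, "am_cohort"))
  p <- length(am_parameters())
  if (nrow(cohort) <= p) {
    stop("scale derivation needs more patients than parameters (n > ",
         p, ")", call. = FALSE)
  }
  x <- .param_matrix(cohort)
  ref <- new_am_reference(colMeans(x), apply(x, 2L, stats::sd))
  R <- correlation_matrix(cohort)
  ex <- extract_factors(R)
  if (ex$n_retained < 1L) {
    stop("no factor reached the Kaiser criterion (eigenvalue > 1)",
         call. = FALSE)
  }
  L <- if (ex$n_retained >= 2L) varimax_rotate(ex$loadings, ...) else
    ex$loadings
  scores <- factor_scores(cohort, ref, L)
  thr <- if (threshold_method == "youden" && "outcome" %in% names(cohort))
    derive_thresholds(scores, "youden")
  else
    data.frame(cutoff = rep(0, ex$n_retained),
               recovery_side = rep("above", ex$n_retained),
               youden = NA_real_)
  sc <- new_am_scale(ref, L, thr[c("cutoff", "recovery_side")],
                     combination)
  sc$name <- sprintf("derived scale (n = %d, %d factors)",
                     nrow(cohort), ex$n_retained)
  attr(sc, "extraction") <- ex
  attr(sc, "scores") <- scores
  sc
}
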