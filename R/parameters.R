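#' Canonical admission-parameter order
#'
#' The eight admission parameters of the acute mediastinitis recovery
#' scale, in the fixed order shared by every standardization reference,
#' weight matrix and cohort in this package: hemoglobin, serum total
#' protein, number of coexisting diseases, preoperative white blood
#' cell count, age, serum albumin, preoperative C-reactive protein and
#' preoperative procalcitonin. All matrix rows and reference vectors
#' follow this order; reordering anywhere is a bug.
#'
#' @return Character vector of the eight parameter names.
#' @export
#' @examples
#' am_parameters()
am_parameters <- function() {
  c("hgb", "proteins", "coex_diseases", "wbc_pre",
    "age", "albumins", "crp_pre", "pct_pre")
}

# Human-readable labels, units conventional for the printed magnitudes
# (the scoring is unit-agnostic after standardization).
.param_labels <- c(
  hgb           = "hemoglobin [g/dL]",
  proteins      = "serum total protein [g/L]",
  coex_diseases = "number of coexisting diseases",
  wbc_pre       = "preoperative WBC [10^3/uL]",
  age           = "age [years]",
  albumins      = "serum albumin [g/L]",
  crp_pre       = "preoperative CRP [mg/L]",
  pct_pre       = "preoperative procalcitonin [ng/mL]"
)

# Case-insensitive header aliases accepted on CSV input.
.param_aliases <- list(
  hgb           = c("hgb", "hemoglobin", "haemoglobin"),
  proteins      = c("proteins", "protein", "total_protein", "serum_protein"),
  coex_diseases = c("coex_diseases", "coex_diseas", "coex_disease",
                    "comorbidities", "n_comorbidities"),
  wbc_pre       = c("wbc_pre", "wbc", "leukocytes", "white_blood_cells"),
  age           = c("age"),
  albumins      = c("albumins", "albumin"),
  crp_pre       = c("crp_pre", "crp", "c_reactive_protein"),
  pct_pre       = c("pct_pre", "pct", "procalcitonin")
)

.outcome_levels <- c("recovery", "death")

# strictly-positive parameters; crp_pre and pct_pre may be zero
.positive_params <- c("hgb", "proteins", "wbc_pre", "age", "albumins")

#' Assemble and validate a patient cohort
#'
#' Builds an `am_cohort` (a validated data frame) from per-patient
#' admission parameters. Checks that all eight parameters are present,
#' numeric and finite, that ids are unique, and that outcome labels (if
#' any) are `"recovery"` or `"death"` (case-insensitive). A record with
#' albumin above total protein is physiologically implausible and
#' raises a warning, not an error.
#'
#' @param x Data frame with the columns of [am_parameters()], an
#'   optional `id` column (defaults to the row number) and an optional
#'   `outcome` column.
#' @return An `am_cohort` data frame with columns `id`, the eight
#'   parameters in canonical order and (if supplied) `outcome`.
#' @export
as_am_cohort <- function(x) {
  stopifnot(is.data.frame(x))
  pars <- am_parameters()
  missing_cols <- setdiff(pars, names(x))
  if (length(missing_cols)) {
    stop("cohort is missing parameter column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  id <- if ("id" %in% names(x)) as.character(x$id) else as.character(seq_len(nrow(x)))
  if (anyDuplicated(id)) {
    stop("cohort ids are not unique: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  out <- data.frame(id = id, stringsAsFactors = FALSE)
  for (p in pars) {
    v <- x[[p]]
    if (!is.numeric(v)) {
      stop("parameter '", p, "' is not numeric", call. = FALSE)
    }
    out[[p]] <- as.numeric(v)
  }
  bad <- !stats::complete.cases(out[pars]) |
    !apply(as.matrix(out[pars]), 1L, function(r) all(is.finite(r)))
  if (any(bad)) {
    stop("non-finite or missing parameter values in row(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  for (p in .positive_params) {
    if (any(out[[p]] <= 0)) {
      stop("parameter '", p, "' must be strictly positive", call. = FALSE)
    }
  }
  if (any(out$crp_pre < 0) || any(out$pct_pre < 0)) {
    stop("crp_pre and pct_pre must be non-negative", call. = FALSE)
  }
  # a count in real data, but non-negative reals are accepted so that
  # hypothetical patients (e.g. "at the cohort means") can be scored
  if (any(out$coex_diseases < 0)) {
    stop("coex_diseases must be non-negative", call. = FALSE)
  }
  if (any(out$albumins > out$proteins)) {
    warning("albumin exceeds total protein in row(s): ",
            paste(which(out$albumins > out$proteins), collapse = ", "),
            call. = FALSE)
  }
  if ("outcome" %in% names(x)) {
    oc <- tolower(trimws(as.character(x$outcome)))
    oc[oc == ""] <- NA_character_
    bad_oc <- !is.na(oc) & !oc %in% .outcome_levels
    if (any(bad_oc)) {
      stop("invalid outcome label(s): ",
           paste(unique(oc[bad_oc]), collapse = ", "),
           " (expected 'recovery' or 'death')", call. = FALSE)
    }
    out$outcome <- oc
  }
  class(out) <- c("am_cohort", "data.frame")
  out
}

#' @export
print.am_cohort <- function(x, ...) {
  n_out <- if ("outcome" %in% names(x)) sum(!is.na(x$outcome)) else 0L
  cat(sprintf("Acute mediastinitis cohort: %d patients (%d with observed outcome)\n",
              nrow(x), n_out))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("... and", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

# parameter matrix in canonical order, patients in rows
.param_matrix <- function(cohort) {
  m <- as.matrix(as.data.frame(cohort)[am_parameters()])
  rownames(m) <- cohort$id
  m
}
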