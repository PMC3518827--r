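#' Read a patient cohort from CSV
#'
#' Reads a one-row-per-patient CSV with a header naming the eight
#' admission parameters (case-insensitive; common aliases such as
#' `hemoglobin`, `crp`, `coex_diseas` are accepted) plus optional `id`
#' and `outcome` columns. Decimal separator is the dot. Rows with any
#' missing or non-numeric parameter value are rejected with a per-row
#' warning; a missing parameter column is a format error.
#'
#' @param path Path to a CSV file.
#' @param sep Field separator (default `","`).
#' @return An [as_am_cohort()]-validated `am_cohort`.
#' @export
read_cohort <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                    comment.char = "#", check.names = FALSE,
                    colClasses = "character"),
    error = function(e) stop("empty or unreadable cohort file: ", path,
                             " (", conditionMessage(e), ")", call. = FALSE))
  if (nrow(raw) == 0L || ncol(raw) == 0L) {
    stop("empty cohort file: ", path, call. = FALSE)
  }
  names(raw) <- tolower(trimws(names(raw)))
  canon <- names(raw)
  for (p in names(.param_aliases)) {
    canon[canon %in% .param_aliases[[p]]] <- p
  }
  canon[canon %in% c("id", "case", "case_id", "patient")] <- "id"
  canon[canon %in% c("outcome", "observed_outcome")] <- "outcome"
  names(raw) <- canon
  pars <- am_parameters()
  missing_cols <- setdiff(pars, names(raw))
  if (length(missing_cols)) {
    stop("cohort CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num <- raw[pars]
  num[] <- lapply(num, function(v) suppressWarnings(as.numeric(v)))
  bad <- !stats::complete.cases(num)
  if (any(bad)) {
    warning("rejected ", sum(bad), " row(s) with missing/non-numeric ",
            "parameters (rows ", paste(which(bad), collapse = ", "), ")",
            call. = FALSE)
  }
  keep <- raw[!bad, , drop = FALSE]
  num <- num[!bad, , drop = FALSE]
  if (nrow(keep) == 0L) {
    stop("no valid rows in cohort file: ", path, call. = FALSE)
  }
  df <- num
  if ("id" %in% names(keep)) df$id <- keep$id
  if ("outcome" %in% names(keep)) df$outcome <- keep$outcome
  as_am_cohort(df)
}

#' Write a cohort to CSV
#'
#' @param cohort An `am_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "am_cohort"))
  .write_csv(as.data.frame(cohort), path)
}

#' Write scored cases to CSV
#'
#' Writes one row per scored case: id, observed outcome (if any),
#' factor scores at full precision, per-factor votes, prediction and
#' classification when present. The file round-trips losslessly through
#' [read_scored()].
#'
#' @param scored An `am_scored` data frame (see [factor_scores()],
#'   [classify_cases()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scored <- function(scored, path) {
  stopifnot(is.data.frame(scored))
  if (nrow(scored) == 0L) stop("no cases to write", call. = FALSE)
  .write_csv(as.data.frame(scored), path)
}

#' Read scored cases from CSV
#'
#' @param path Path to a CSV written by [write_scored()] (or any CSV
#'   with columns `id`, `f1`, `f2`, ... and optionally `outcome`,
#'   `classification`).
#' @return An `am_scored` data frame.
#' @export
read_scored <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  names(df) <- tolower(names(df))
  fcols <- grep("^f[0-9]+$", names(df), value = TRUE)
  if (!length(fcols) || !"id" %in% names(df)) {
    stop("not a scored-case file (need id and f1, f2, ... columns): ",
         path, call. = FALSE)
  }
  df$id <- as.character(df$id)
  if ("outcome" %in% names(df)) df$outcome <- tolower(df$outcome)
  class(df) <- c("am_scored", "data.frame")
  df
}

.write_csv <- function(df, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) {
    stop("cannot write ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  invisible(path)
}
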