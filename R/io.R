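# CSV input/output. Readers validate hard and name the offending row;
# writers keep full precision and add the one-decimal display column the
# field conventionally reports NNCOC with.

#' Read a cohort table from CSV
#'
#' Reads a comma-separated file with a header and returns either a scored
#' cohort (when `risk_col` is given) or a covariate design plus outcome
#' vector (when `covariate_cols` is given). The outcome column is coerced
#' strictly to 0/1; any other value, any missing value, or a risk outside
#' \[0, 1\] is an error naming the offending data row.
#'
#' @param path Path to a CSV file with a header row.
#' @param outcome_col Name of the binary outcome column.
#' @param risk_col Name of a precomputed absolute-risk column, or `NULL`.
#' @param covariate_cols Character vector of covariate column names, or
#'   `NULL`. Exactly one of `risk_col`/`covariate_cols` must be given.
#' @return With `risk_col`: a [scored_cohort()]. With `covariate_cols`: a
#'   list with `design` (data frame) and `outcomes`.
#' @export
read_cohort_table <- function(path, outcome_col, risk_col = NULL,
                              covariate_cols = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.null(risk_col) == is.null(covariate_cols)) {
    stop("give exactly one of `risk_col` or `covariate_cols`", call. = FALSE)
  }
  tab <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c(outcome_col, risk_col, covariate_cols)
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop(sprintf("missing column(s) in %s: %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }

  y_raw <- tab[[outcome_col]]
  bad <- which(is.na(y_raw) | !(y_raw %in% c(0, 1, "0", "1")))
  if (length(bad)) {
    stop(sprintf("non-binary or missing outcome '%s' at row %d",
                 as.character(y_raw[bad[1L]]), bad[1L]), call. = FALSE)
  }
  y <- as.integer(as.character(y_raw))

  if (!is.null(risk_col)) {
    r <- suppressWarnings(as.numeric(tab[[risk_col]]))
    bad <- which(is.na(r) | r < 0 | r > 1)
    if (length(bad)) {
      stop(sprintf("invalid risk value '%s' at row %d (must be in [0, 1])",
                   as.character(tab[[risk_col]][bad[1L]]), bad[1L]), call. = FALSE)
    }
    return(scored_cohort(r, y))
  }

  design <- tab[, covariate_cols, drop = FALSE]
  for (cc in covariate_cols) {
    v <- suppressWarnings(as.numeric(design[[cc]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("missing or non-numeric covariate '%s' at row %d", cc, bad[1L]),
           call. = FALSE)
    }
    design[[cc]] <- v
  }
  list(design = design, outcomes = y)
}

#' Write a CU curve as a CSV table
#'
#' One row per threshold point with columns `threshold`, `n_flagged`,
#' `true_positives`, `sensitivity`, `specificity`, `ppv`, `nncoc` at full
#' precision, plus `nncoc_display` rounded to one decimal (the conventional
#' reporting style, e.g. "2.3").
#'
#' @param curve A `cu_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_table <- function(curve, path) {
  stopifnot(inherits(curve, "cu_curve"))
  tab <- curve$points
  tab$nncoc_display <- sprintf("%.1f", round(tab$nncoc, 1))
  utils::write.csv(format(tab, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a CU-curve table written by [write_curve_table()]
#'
#' Reconstructs a `cu_curve` object (points plus the 100%-sensitivity
#' summary) from the serialized table. Cohort totals are recovered from the
#' terminal point, which flags the whole cohort.
#'
#' @param path Path to a curve CSV.
#' @return A `cu_curve`.
#' @export
read_curve_table <- function(path) {
  tab <- utils::read.csv(path, header = TRUE)
  tab$nncoc_display <- NULL
  n_patients <- tab$n_flagged[nrow(tab)]
  n_cases <- tab$true_positives[nrow(tab)]
  curve <- structure(
    list(points = tab, n_patients = n_patients, n_cases = n_cases,
         n_controls = n_patients - n_cases),
    class = "cu_curve"
  )
  curve$full_sensitivity <- full_sensitivity_summary(curve)
  curve
}

#' Write a generated cohort as CSV
#'
#' Serialises the output of [generate_logistic_cohort()] (covariates,
#' outcome, true risk) for demos and fixtures.
#'
#' @param cohort List as returned by [generate_logistic_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  tab <- cohort$design
  tab$outcome <- cohort$outcomes
  tab$true_risk <- cohort$true_risks
  utils::write.csv(format(tab, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
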