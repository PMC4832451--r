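#' Number needed to capture one case (NNCOC)
#'
#' The NNCOC at a classification threshold is the number of patients flagged
#' positive (true positives plus false positives) divided by the number of
#' true positives — the reciprocal of the positive predictive value. It is
#' the number of patients who must be acted on (biopsied, catheterised,
#' screened) per true case found.
#'
#' @param n_flagged Number of patients at or above the threshold (TP + FP).
#' @param true_positives Number of cases among them; must be at least 1.
#' @return The exact ratio `n_flagged / true_positives`, at full precision.
#'   Display rounding (one decimal, as conventionally reported) is left to
#'   the output layer.
#' @examples
#' nncoc(35, 15) # 2.33...
#' nncoc(30, 15) # 2
#' @export
nncoc <- function(n_flagged, true_positives) {
  if (any(true_positives < 1)) {
    stop("NNCOC is undefined when no true positives are captured", call. = FALSE)
  }
  if (any(n_flagged < true_positives)) {
    stop("`n_flagged` must be at least `true_positives`", call. = FALSE)
  }
  n_flagged / true_positives
}

#' Build a clinical utility (CU) curve
#'
#' Sweeps every distinct risk value in the cohort as a threshold
#' (classification rule: risk >= threshold is positive) and records, per
#' threshold, the flagged count, true positives, sensitivity, specificity,
#' PPV and NNCOC. The curve is the locus of (NNCOC, sensitivity) points in
#' descending threshold order; it re-parameterises the ROC curve's operating
#' points on an axis clinicians can act on directly.
#'
#' Thresholds above the top-ranked case capture no true positives; those
#' points (NNCOC undefined/infinite) are omitted. Patients sharing a risk
#' value cross the threshold together, so the curve is indexed by distinct
#' risk values, never by patient rank. NNCOC is *not* monotone in the
#' threshold — the characteristic zigzag is preserved, never smoothed or
#' sorted away.
#'
#' @param cohort A [scored_cohort()] (or anything coercible: a data frame
#'   with `risk` and `outcome` columns).
#' @param strict If `TRUE` (default), require at least one case and one
#'   non-case. `strict = FALSE` permits a cohort with no non-cases
#'   (specificity is then `NA`); a cohort with no cases is always an error.
#'
#' @return An object of class `cu_curve`: a list with
#'   \describe{
#'     \item{points}{data frame with columns `threshold`, `n_flagged`,
#'       `true_positives`, `sensitivity`, `specificity`, `ppv`, `nncoc`,
#'       ordered by strictly decreasing threshold.}
#'     \item{full_sensitivity}{the 100%-sensitivity summary, see
#'       [full_sensitivity_summary()].}
#'     \item{n_patients, n_cases}{cohort totals.}
#'   }
#' @seealso [full_sensitivity_summary()], [threshold_for_sensitivity()],
#'   [roc_curve()]
#' @examples
#' set.seed(1)
#' coh <- scored_cohort(runif(20), rbinom(20, 1, 0.4))
#' curve <- build_cu_curve(coh)
#' curve$full_sensitivity
#' @export
build_cu_curve <- function(cohort, strict = TRUE) {
  if (!inherits(cohort, "scored_cohort")) {
    cohort <- scored_cohort(cohort$risk, cohort$outcome)
  }
  check_two_classes(cohort, strict = strict)

  risk <- cohort$risk
  outcome <- cohort$outcome
  n <- length(risk)
  n_cases <- sum(outcome == 1)
  n_controls <- n - n_cases

  # descending distinct thresholds; cumulative counts over patients sorted
  # by decreasing risk give flagged/TP at each threshold
  ord <- order(risk, decreasing = TRUE)
  r_sorted <- risk[ord]
  y_sorted <- outcome[ord]
  cum_flagged <- seq_len(n)
  cum_tp <- cumsum(y_sorted)
  # last index of each tie block = counts with rule risk >= threshold
  is_block_end <- c(r_sorted[-n] != r_sorted[-1], TRUE)
  thr <- r_sorted[is_block_end]
  n_flagged <- cum_flagged[is_block_end]
  tp <- cum_tp[is_block_end]

  keep <- tp >= 1L
  thr <- thr[keep]; n_flagged <- n_flagged[keep]; tp <- tp[keep]

  fp <- n_flagged - tp
  sens <- tp / n_cases
  spec <- if (n_controls > 0) (n_controls - fp) / n_controls else NA_real_
  ppv <- tp / n_flagged

  points <- data.frame(
    threshold = thr,
    n_flagged = n_flagged,
    true_positives = tp,
    sensitivity = sens,
    specificity = spec,
    ppv = ppv,
    nncoc = n_flagged / tp
  )

  curve <- structure(
    list(points = points, n_patients = n, n_cases = n_cases,
         n_controls = n_controls),
    class = "cu_curve"
  )
  curve$full_sensitivity <- full_sensitivity_summary(curve)
  curve
}

#' The 100%-sensitivity summary of a CU curve
#'
#' Finds the *highest* threshold at which every case is captured — the point
#' where the CU curve first reaches 100% sensitivity — and reports the
#' flagged count, the NNCOC there, and the rule-out: patients whose risk
#' falls below that threshold are all non-cases and can be classified as
#' free of disease. The horizontal segment of the CU curve at 100%
#' sensitivity has exactly this length.
#'
#' @param curve A `cu_curve` from [build_cu_curve()].
#' @return A list of class `full_sensitivity_summary` with elements
#'   `threshold`, `n_flagged`, `nncoc`, `n_ruled_out`, `rule_out_fraction`.
#' @export
full_sensitivity_summary <- function(curve) {
  stopifnot(inherits(curve, "cu_curve"))
  pts <- curve$points
  hit <- which(pts$sensitivity >= 1)
  i <- hit[1L] # points are threshold-descending; first hit = highest threshold
  n_ruled_out <- curve$n_patients - pts$n_flagged[i]
  structure(
    list(threshold = pts$threshold[i],
         n_flagged = pts$n_flagged[i],
         nncoc = pts$nncoc[i],
         n_ruled_out = n_ruled_out,
         rule_out_fraction = n_ruled_out / curve$n_patients),
    class = "full_sensitivity_summary"
  )
}

#' Operating point achieving a target sensitivity
#'
#' Returns the CU-curve point with the highest threshold whose sensitivity
#' meets or exceeds `target` — the most conservative rule that still
#' captures the requested fraction of cases.
#'
#' @param curve A `cu_curve`.
#' @param target Sensitivity target in (0, 1]. Always attainable: the
#'   terminal point (whole cohort flagged) has sensitivity 1.
#' @return A one-row data frame (a `CUPoint`): columns as in
#'   `curve$points`.
#' @export
threshold_for_sensitivity <- function(curve, target) {
  stopifnot(inherits(curve, "cu_curve"))
  if (length(target) != 1L || !is.finite(target) || target <= 0 || target > 1) {
    stop("`target` must be a single sensitivity in (0, 1]", call. = FALSE)
  }
  pts <- curve$points
  i <- which(pts$sensitivity >= target)[1L]
  pts[i, , drop = FALSE]
}

#' Bootstrap confidence band for NNCOC at fixed sensitivity targets
#'
#' Patient-level resampling with replacement; within each resample the CU
#' curve is rebuilt and the NNCOC read off at each sensitivity target via
#' [threshold_for_sensitivity()]. Percentile intervals are returned. Off the
#' main path by design: the point estimates carry no bands unless asked for.
#'
#' @param cohort A [scored_cohort()].
#' @param sens_targets Sensitivity targets in (0, 1].
#' @param reps Bootstrap replicates (default 2000).
#' @param seed Integer seed; required, so results are reproducible.
#' @param conf Confidence level (default 0.95).
#' @return Data frame: `target`, `nncoc` (point estimate), `ci_low`,
#'   `ci_high`.
#' @export
nncoc_bootstrap_band <- function(cohort, sens_targets = c(0.80, 0.85, 0.90, 0.95, 1.00),
                                 reps = 2000, seed, conf = 0.95) {
  if (missing(seed)) stop("`seed` is required for reproducibility", call. = FALSE)
  if (!inherits(cohort, "scored_cohort")) {
    cohort <- scored_cohort(cohort$risk, cohort$outcome)
  }
  check_two_classes(cohort)
  base_curve <- build_cu_curve(cohort)
  point <- vapply(sens_targets, function(t)
    threshold_for_sensitivity(base_curve, t)$nncoc, numeric(1))
  n <- nrow(cohort)
  boot <- withr::with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      idx <- resample_with_both_classes(cohort$outcome, n)
      bc <- build_cu_curve(scored_cohort(cohort$risk[idx], cohort$outcome[idx]))
      vapply(sens_targets, function(t)
        threshold_for_sensitivity(bc, t)$nncoc, numeric(1))
    }, numeric(length(sens_targets)))
  })
  boot <- matrix(boot, nrow = length(sens_targets))
  alpha <- (1 - conf) / 2
  data.frame(
    target = sens_targets,
    nncoc = point,
    ci_low = apply(boot, 1, stats::quantile, probs = alpha),
    ci_high = apply(boot, 1, stats::quantile, probs = 1 - alpha)
  )
}

# internal: draw a bootstrap index vector guaranteed to contain both
# outcome classes; redraws up to 100 times then errors
resample_with_both_classes <- function(outcomes, n) {
  for (attempt in 1:100) {
    idx <- sample.int(n, n, replace = TRUE)
    y <- outcomes[idx]
    if (any(y == 1) && any(y == 0)) return(idx)
  }
  stop("bootstrap resample lacked both outcome classes after 100 redraws",
       call. = FALSE)
}

#' @export
print.cu_curve <- function(x, ...) {
  fs <- x$full_sensitivity
  cat(sprintf("CU curve: %d patients, %d cases, %d threshold points\n",
              x$n_patients, x$n_cases, nrow(x$points)))
  cat(sprintf("100%% sensitivity first reached at threshold %.4g: %d flagged, NNCOC %.1f, %d ruled out\n",
              fs$threshold, fs$n_flagged, fs$nncoc, fs$n_ruled_out))
  invisible(x)
}

#' @export
print.full_sensitivity_summary <- function(x, ...) {
  cat(sprintf(
    "100%% sensitivity at threshold %.4g: %d flagged (NNCOC %.1f), %d ruled out (%.1f%% of cohort)\n",
    x$threshold, x$n_flagged, x$nncoc, x$n_ruled_out, 100 * x$rule_out_fraction))
  invisible(x)
}
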