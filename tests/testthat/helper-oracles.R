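# Independent oracles and fixture builders. Everything here recomputes
# quantities by direct enumeration, deliberately ignoring the package's
# own code paths.

# Cohort with distinct descending risks in which case ranks are chosen so
# the lowest-ranked case sits exactly at `lowest_case_rank` (counting from
# the highest risk). Remaining cases are scattered among the higher ranks.
rank_cohort <- function(n, n_cases, lowest_case_rank, seed = 1) {
  stopifnot(n_cases <= lowest_case_rank, lowest_case_rank <= n)
  risks <- seq(0.99, 0.01, length.out = n) # strictly decreasing, inside (0,1)
  outcomes <- integer(n)
  outcomes[lowest_case_rank] <- 1L
  extra <- withr::with_seed(seed,
    sample(seq_len(lowest_case_rank - 1L), n_cases - 1L))
  outcomes[extra] <- 1L
  scored_cohort(risks, outcomes)
}

# Random cohort with heavy ties (risks on a coarse grid).
random_tied_cohort <- function(n, seed, prevalence = 0.4, grid = 20) {
  withr::with_seed(seed, {
    risks <- round(runif(n) * grid) / grid
    outcomes <- rbinom(n, 1, prevalence)
    if (all(outcomes == 1)) outcomes[1] <- 0L
    if (all(outcomes == 0)) outcomes[1] <- 1L
    scored_cohort(risks, outcomes)
  })
}

# Brute-force threshold sweep: for each distinct risk value, count
# flagged / TP / FP by direct comparison, build the metric table.
oracle_cu_points <- function(risks, outcomes) {
  thr <- sort(unique(risks), decreasing = TRUE)
  n_cases <- sum(outcomes == 1)
  n_controls <- sum(outcomes == 0)
  rows <- lapply(thr, function(t) {
    flagged <- risks >= t
    tp <- sum(flagged & outcomes == 1)
    if (tp == 0) return(NULL)
    fp <- sum(flagged & outcomes == 0)
    data.frame(threshold = t, n_flagged = sum(flagged), true_positives = tp,
               sensitivity = tp / n_cases,
               specificity = if (n_controls) (n_controls - fp) / n_controls else NA,
               ppv = tp / sum(flagged), nncoc = sum(flagged) / tp)
  })
  do.call(rbind, rows)
}

# Exhaustive Mann-Whitney pair counting: concordant 1, tie 1/2.
oracle_auc <- function(risks, outcomes) {
  x <- risks[outcomes == 1]
  y <- risks[outcomes == 0]
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Minimal flagged set containing all cases, by searching all thresholds.
oracle_full_sensitivity <- function(risks, outcomes) {
  thr <- sort(unique(risks), decreasing = TRUE)
  for (t in thr) {
    flagged <- risks >= t
    if (sum(flagged & outcomes == 1) == sum(outcomes == 1)) {
      return(list(threshold = t, n_flagged = sum(flagged),
                  n_ruled_out = sum(!flagged)))
    }
  }
}
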