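test_that("nncoc is the exact flagged-to-case ratio and rejects zero cases", {
  expect_equal(nncoc(35, 15), 35 / 15)
  expect_equal(round(nncoc(35, 15), 1), 2.3)
  expect_equal(nncoc(30, 15), 2)
  expect_equal(round(nncoc(199, 114), 1), 1.7)
  expect_equal(nncoc(80, 25), 3.2)
  for (k in c(1, 5, 40)) expect_equal(nncoc(k, k), 1)
  expect_error(nncoc(10, 0), "undefined")
  expect_error(nncoc(3, 5), "at least")
})

test_that("perfect separation reaches 100% sensitivity at NNCOC 1", {
  coh <- scored_cohort(c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1), c(1, 1, 1, 0, 0, 0))
  curve <- build_cu_curve(coh)
  i <- which(curve$points$sensitivity >= 1)[1]
  expect_equal(curve$points$nncoc[i], 1)
  expect_equal(curve$full_sensitivity$nncoc, 1)
  expect_equal(curve$full_sensitivity$n_ruled_out, 3)
})

test_that("a 37-patient cohort with the lowest case at rank 30 gives NNCOC 2 and 7 ruled out", {
  coh <- rank_cohort(37, 15, lowest_case_rank = 30, seed = 4)
  fs <- build_cu_curve(coh)$full_sensitivity
  expect_equal(fs$n_flagged, 30)
  expect_equal(fs$nncoc, 2)
  expect_equal(fs$n_ruled_out, 7)
  # every ruled-out patient is a non-case by construction of the summary
  expect_true(all(coh$outcome[coh$risk < fs$threshold] == 0))
})

test_that("every curve point matches brute-force threshold enumeration, ties included", {
  for (seed in 1:8) {
    coh <- random_tied_cohort(20, seed = seed)
    got <- build_cu_curve(coh)$points
    want <- oracle_cu_points(coh$risk, coh$outcome)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("curve invariants hold on random cohorts", {
  for (seed in 1:8) {
    coh <- random_tied_cohort(40, seed = 100 + seed)
    curve <- build_cu_curve(coh)
    pts <- curve$points
    # nncoc * ppv = 1 exactly, thresholds strictly decreasing
    expect_lt(max(abs(pts$nncoc * pts$ppv - 1)), 1e-12)
    expect_true(all(diff(pts$threshold) < 0))
    # sensitivity non-decreasing; terminal point flags everyone
    expect_true(all(diff(pts$sensitivity) >= 0))
    last <- nrow(pts)
    expect_equal(pts$sensitivity[last], 1)
    expect_equal(pts$nncoc[last], curve$n_patients / curve$n_cases)
    expect_equal(pts$n_flagged[last], curve$n_patients)
  }
})

test_that("the curve is tie-coherent under strictly monotone risk transforms", {
  coh <- random_tied_cohort(50, seed = 77)
  base <- build_cu_curve(coh)$points
  trans <- build_cu_curve(scored_cohort(coh$risk^3, coh$outcome))$points
  expect_equal(trans$threshold, base$threshold^3, tolerance = 1e-12)
  for (col in c("n_flagged", "true_positives", "sensitivity", "specificity",
                "ppv", "nncoc")) {
    expect_equal(trans[[col]], base[[col]])
  }
})

test_that("zigzag in NNCOC is preserved, not monotonized", {
  # case, non-case, case pattern down the ranking forces NNCOC to rise then fall
  coh <- scored_cohort(c(0.9, 0.8, 0.7, 0.6, 0.2), c(1, 0, 0, 1, 0))
  nn <- build_cu_curve(coh)$points$nncoc
  expect_equal(nn, c(1, 2, 3, 2, 5 / 2))
  expect_false(all(diff(nn) >= 0) || all(diff(nn) <= 0))
})

test_that("full-sensitivity summary agrees with enumeration over all thresholds", {
  for (seed in 1:6) {
    coh <- random_tied_cohort(30, seed = 200 + seed)
    fs <- build_cu_curve(coh)$full_sensitivity
    want <- oracle_full_sensitivity(coh$risk, coh$outcome)
    expect_equal(fs$threshold, want$threshold)
    expect_equal(fs$n_flagged, want$n_flagged)
    expect_equal(fs$n_ruled_out, want$n_ruled_out)
    expect_equal(fs$rule_out_fraction, want$n_ruled_out / nrow(coh))
  }
})

test_that("threshold_for_sensitivity picks the highest qualifying threshold", {
  # risks 0.9 .. 0.0, cases at ranks 1, 2, 4
  risks <- seq(0.9, 0.0, by = -0.1)
  outcomes <- integer(10); outcomes[c(1, 2, 4)] <- 1L
  curve <- build_cu_curve(scored_cohort(risks, outcomes))
  # a two-thirds target is met by the second case at threshold 0.8
  expect_equal(threshold_for_sensitivity(curve, 2 / 3)$threshold, 0.8)
  # 0.67 exceeds 2/3, so the exact >= rule must fall through to the third case
  expect_equal(threshold_for_sensitivity(curve, 0.67)$threshold, 0.6)
  # target 1.0 coincides with the full-sensitivity point
  fs <- curve$full_sensitivity
  pt1 <- threshold_for_sensitivity(curve, 1.0)
  expect_equal(pt1$threshold, fs$threshold)
  expect_equal(pt1$nncoc, fs$nncoc)
  expect_error(threshold_for_sensitivity(curve, 0), "in \\(0, 1\\]")
  expect_error(threshold_for_sensitivity(curve, 1.5), "in \\(0, 1\\]")
})

test_that("single-class cohorts follow the strictness contract", {
  all_cases <- scored_cohort(c(0.9, 0.5, 0.2), c(1, 1, 1))
  expect_error(build_cu_curve(all_cases), "no non-cases")
  curve <- build_cu_curve(all_cases, strict = FALSE)
  expect_equal(curve$full_sensitivity$n_ruled_out, 0)
  expect_equal(curve$full_sensitivity$nncoc, 1)
  expect_error(build_cu_curve(scored_cohort(c(0.1, 0.2), c(0, 0))), "no cases")
})

test_that("bootstrap NNCOC bands cover the point estimate and are seed-stable", {
  coh <- generate_binormal_cohort(40, 60, mean_case = 1.2, seed = 9)
  b1 <- nncoc_bootstrap_band(coh, sens_targets = c(0.8, 1.0), reps = 200, seed = 21)
  b2 <- nncoc_bootstrap_band(coh, sens_targets = c(0.8, 1.0), reps = 200, seed = 21)
  expect_identical(b1, b2)
  expect_true(all(b1$ci_low <= b1$nncoc + 1e-12))
  expect_true(all(b1$ci_high >= b1$nncoc - 1e-12))
  expect_error(nncoc_bootstrap_band(coh, reps = 100), "seed")
})
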