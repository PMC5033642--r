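test_that("subject simulation hits the requested SNR and is reproducible", {
  cs <- cohortSpec(nSubjects = 1, seed = 3)
  d <- smallDesign()
  gt <- tdcsdcm:::drawGroundTruth(cs)[[1]]
  s1 <- simulateSubject(gt, d, cs, seed = 5)
  s2 <- simulateSubject(gt, d, cs, seed = 5)
  expect_identical(s1$series, s2$series)
  expect_identical(s1$trials, s2$trials)
  expect_equal(dim(s1$series$anodal), c(120, 2))
  # realized noise SD within 20% of the target (signal SD / SNR)
  resid <- unlist(s1$series) - unlist(lapply(names(s1$series), function(cc)
    simulateBold(gt$params, hemodynamicParams(2), d,
                 s1$events[[cc]]$onset, cc)))
  expect_lt(abs(sd(resid) / s1$noiseSd - 1), 0.2)
  expect_true(all(s1$trials$rt_ms > 0))
})

test_that("zero driving input gives flat sessions for a subject", {
  cs <- cohortSpec(nSubjects = 1, seed = 4, cMean = 0.1, cSD = 0)
  gt <- tdcsdcm:::drawGroundTruth(cs)[[1]]
  gt$params@C[] <- 0
  s <- simulateSubject(gt, smallDesign(), cs, seed = 1)
  # no signal -> signal SD 0 -> noise SD 0 -> exactly flat
  expect_equal(max(abs(unlist(s$series))), 0)
  expect_equal(s$noiseSd, 0)
})

test_that("a default cohort has 10 subjects, 20 sessions and a full ledger", {
  cs <- cohortSpec(seed = 7)
  d <- smallDesign()
  cohort <- simulateCohort(cs, d)
  expect_length(cohort$subjects, 10)
  expect_equal(sum(lengths(lapply(cohort$subjects, `[[`, "series"))), 20)
  expect_length(cohort$groundTruth, 10)
  expect_equal(dim(cohort$effectiveArray), c(10, 4, 2))
  expect_equal(nrow(cohort$trials), 10 * 2 * d@nTrials)
  # ledger effective values satisfy the connectivity invariants
  for (gt in cohort$groundTruth) {
    expect_true(validObject(gt$params))
    expect_lt(max(diag(gt$effective$anodal)), 0)
  }
})

test_that("cohort regeneration from the master seed is bit-identical", {
  cs <- cohortSpec(nSubjects = 2, seed = 11)
  d <- smallDesign()
  c1 <- simulateCohort(cs, d)
  c2 <- simulateCohort(cs, d)
  expect_identical(c1$subjects[[1]]$series, c2$subjects[[1]]$series)
  expect_identical(c1$trials, c2$trials)
  expect_identical(c1$effectiveArray, c2$effectiveArray)
})

test_that("planted condition effects appear in the ledger means", {
  # backward-connection difference within 3 SEs of the configured value
  cs <- cohortSpec(nSubjects = 60, seed = 13)
  gts <- tdcsdcm:::drawGroundTruth(cs)
  dback <- vapply(gts, function(g)
    g$effective$anodal[2, 1] - g$effective$sham[2, 1], numeric(1))
  target <- -0.67 - (-0.26)
  se <- sd(dback) / sqrt(length(dback))
  expect_lt(abs(mean(dback) - target), 3 * se + 0.03)
  # self-connection effect: anodal less negative
  dself <- vapply(gts, function(g)
    g$effective$anodal[2, 2] - g$effective$sham[2, 2], numeric(1))
  expect_gt(mean(dself), 0)
  expect_lt(abs(mean(dself) - 0.17), 3 * sd(dself) / sqrt(length(dself)) + 0.02)
})

test_that("planted RT facilitation tracks the forward-connection change", {
  cs <- cohortSpec(nSubjects = 200, seed = 17)
  gts <- tdcsdcm:::drawGroundTruth(cs)
  d <- vapply(gts, function(g) g$forwardDelta, numeric(1))
  pct <- vapply(gts, function(g) g$pctChange, numeric(1))
  expect_equal(cor(d, pct), 0.7, tolerance = 0.12)
  expect_equal(mean(pct), 3.35, tolerance = 3 * 10 / sqrt(200))
})

test_that("trials-only cohorts skip the BOLD stage", {
  cs <- cohortSpec(nSubjects = 3, seed = 19)
  cohort <- simulateCohort(cs, smallDesign(), series = FALSE)
  expect_null(cohort$subjects[[1]]$series)
  expect_equal(nrow(cohort$trials), 3 * 2 * 30)
})
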