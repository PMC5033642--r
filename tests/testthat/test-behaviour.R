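test_that("trial cleaning applies accuracy, voice-key then deviation rules", {
  # identical RTs: nothing excluded
  tr <- makeTrials(rt = rep(800, 10))
  out <- cleanTrials(tr)
  expect_equal(nrow(out$trials), 10)
  expect_equal(out$log$pctExcluded, 0)
  # nine at 800 ms plus one at 2000 ms: mean 920, sd 379.47, cutoff
  # mean + 2 sd = 1678.9, so only the 2000 ms trial falls
  tr2 <- makeTrials(rt = c(rep(800, 9), 2000))
  out2 <- cleanTrials(tr2)
  expect_equal(nrow(out2$trials), 9)
  expect_equal(out2$log$nOutlier, 1)
  expect_false(2000 %in% out2$trials$rt_ms)
  # an inaccurate trial goes first, regardless of its unremarkable RT
  tr3 <- makeTrials(rt = rep(800, 10), accurate = c(rep(TRUE, 9), FALSE))
  out3 <- cleanTrials(tr3)
  expect_equal(out3$log$nAccuracy, 1)
  expect_equal(nrow(out3$trials), 9)
  # voice-key failures likewise
  tr4 <- makeTrials(rt = rep(800, 10), voicekey_ok = c(FALSE, rep(TRUE, 9)))
  expect_equal(cleanTrials(tr4)$log$nVoiceKey, 1)
  expect_error(cleanTrials(makeTrials(rt = 800, accurate = FALSE)),
               "excluded")
})

test_that("cleaning never adds trials and its log accounts for every loss", {
  set.seed(4)
  for (r in 1:20) {
    n <- sample(20:60, 1)
    tr <- makeTrials(rt = rlnorm(n, log(800), 0.3),
                     accurate = runif(n) < 0.9,
                     voicekey_ok = runif(n) < 0.95,
                     condition = sample(c("anodal", "sham"), n, TRUE))
    out <- cleanTrials(tr)
    expect_lte(nrow(out$trials), n)
    with(out$log,
         expect_equal(nAccuracy + nVoiceKey + nOutlier, nInput - nRetained))
  }
})

test_that("condition means aggregate by subject or item", {
  tr <- rbind(makeTrials("s1", "anodal", 700, item = "i1"),
              makeTrials("s1", "sham", 800, item = "i1"))
  m <- conditionMeans(tr, by = "subject")
  expect_equal(m$anodal, 700)
  expect_equal(m$sham, 800)
  # permutation invariance and a hand-computed 3-subject table
  tr3 <- rbind(
    makeTrials("s1", "anodal", c(700, 720)), makeTrials("s1", "sham", c(820, 800)),
    makeTrials("s2", "anodal", c(650, 610)), makeTrials("s2", "sham", c(700, 640)),
    makeTrials("s3", "anodal", c(900, 880)), makeTrials("s3", "sham", 980))
  m3 <- conditionMeans(tr3, by = "subject")
  expect_equal(m3$anodal, c(710, 630, 890))
  expect_equal(m3$sham, c(810, 670, 980))
  set.seed(1)
  m3p <- conditionMeans(tr3[sample(nrow(tr3)), ], by = "subject")
  expect_equal(m3p, m3)
  # a unit missing one condition is dropped with a warning
  tr4 <- rbind(tr3, makeTrials("s4", "anodal", 750))
  expect_warning(m4 <- conditionMeans(tr4, by = "subject"), "missing")
  expect_equal(nrow(m4), 3)
})

test_that("one-tailed paired t matches the textbook formula", {
  a <- c(812, 790, 845, 803, 830)
  b <- c(840, 802, 841, 835, 858)
  got <- pairedTOneTailed(b, a, "greater")
  d <- b - a
  tHand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(got$t, tHand)
  expect_equal(got$df, 4)
  expect_equal(got$p, pt(tHand, 4, lower.tail = FALSE))
  # sign flip negates t and complements p
  flip <- pairedTOneTailed(a, b, "greater")
  expect_equal(flip$t, -got$t)
  expect_equal(flip$p, 1 - got$p)
  # identical vectors carry no evidence either way
  same <- pairedTOneTailed(a, a, "greater")
  expect_equal(same$t, 0)
  expect_equal(same$p, 0.5)
  expect_error(pairedTOneTailed(a + 5, a, "greater"), "variance")
  expect_error(pairedTOneTailed(1, 2, "greater"), "at least 2")
})

test_that("percentage facilitation is the relative RT change", {
  expect_equal(rtChangePercent(800, 800), 0)
  expect_equal(rtChangePercent(812, 840), 100 * 28 / 840)
  expect_equal(round(rtChangePercent(811.4, 839.5), 2), 3.35)
  expect_error(rtChangePercent(800, 0), "positive")
})

test_that("the brain-behaviour correlation matches the covariance formula", {
  x <- c(0.12, -0.05, 0.30, 0.22, -0.10, 0.05, 0.40, 0.18, -0.02, 0.09)
  y <- c(2.1, -1.0, 4.5, 2.9, -2.2, 0.4, 6.0, 3.1, 0.3, 1.2)
  got <- brainBehaviourCorr(x, y)
  rHand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, rHand)
  expect_equal(got$R2, rHand^2)
  expect_equal(got$df, 8)          # n - 2
  expect_equal(got$dfPrinted, 10)  # the study's printed convention
  tHand <- rHand * sqrt(8 / (1 - rHand^2))
  expect_equal(got$p, 2 * pt(-abs(tHand), 8))
  # exact limits
  expect_equal(brainBehaviourCorr(1:5, 2 * (1:5) + 3)$r, 1)
  expect_equal(brainBehaviourCorr(1:5, -(1:5))$r, -1)
  # affine invariance
  got2 <- brainBehaviourCorr(10 * x + 3, -2 * y + 7)
  expect_equal(abs(got2$r), abs(got$r))
  expect_error(brainBehaviourCorr(rep(1, 5), y[1:5]), "variance")
})

test_that("leave-one-out refit drops the lowest connectivity change", {
  x <- c(-1.5, 0.1, 0.2, 0.3, 0.4, 0.5, 0.15, 0.25, 0.35, 0.05)
  y <- x * 2 + rnorm(10, sd = 0.01)
  got <- brainBehaviourCorr(x, y, dropLowest = TRUE)
  ref <- brainBehaviourCorr(x[-1], y[-1])
  expect_equal(got$refit$r, ref$r)
  expect_equal(got$refit$df, 7)
})

test_that("matrix input yields a per-connection correlation table", {
  set.seed(6)
  M <- cbind(`VPM->IFS` = rnorm(10), `IFS->VPM` = rnorm(10))
  y <- rnorm(10)
  tabl <- brainBehaviourCorr(M, y)
  expect_equal(nrow(tabl), 2)
  expect_identical(tabl$connection, c("VPM->IFS", "IFS->VPM"))
  expect_equal(tabl$R2, tabl$r^2)
})

test_that("a planted correlation of 0.7 at n = 10 has the right sign almost always", {
  signs <- vapply(1:500, function(r) {
    cs <- cohortSpec(nSubjects = 10, seed = 10000 + r)
    gts <- tdcsdcm:::drawGroundTruth(cs)
    d <- vapply(gts, function(g) g$forwardDelta, numeric(1))
    pct <- vapply(gts, function(g) g$pctChange, numeric(1))
    sign(brainBehaviourCorr(d, pct)$r)
  }, numeric(1))
  expect_gte(mean(signs > 0), 0.9)
})
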