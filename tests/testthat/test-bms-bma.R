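test_that("FFX model probabilities are the softmax of summed evidence", {
  ev <- matrix(c(0, 0), 1, 2, dimnames = list(NULL, c("m1", "m2")))
  expect_equal(unname(ffxBms(ev)$group), c(0.5, 0.5))
  ev2 <- matrix(c(0, log(4)), 1, 2, dimnames = list(NULL, c("m1", "m2")))
  expect_equal(unname(ffxBms(ev2)$group), c(0.2, 0.8))
  # random three-model table against brute-force normalized exponentials
  set.seed(2)
  ev3 <- matrix(rnorm(15, sd = 3), 5, 3,
                dimnames = list(NULL, c("m1", "m2", "m3")))
  got <- ffxBms(ev3)
  brute <- exp(colSums(ev3)) / sum(exp(colSums(ev3)))
  expect_equal(unname(got$group), unname(brute), tolerance = 1e-12)
  bruteSub <- t(apply(ev3, 1, function(f) exp(f) / sum(exp(f))))
  expect_equal(unname(got$bySubject), unname(bruteSub), tolerance = 1e-12)
  expect_equal(sum(got$group), 1, tolerance = 1e-12)
  expect_true(all(abs(rowSums(got$bySubject) - 1) < 1e-12))
})

test_that("FFX is invariant to a constant shift and guards overflow", {
  set.seed(3)
  ev <- matrix(rnorm(8), 2, 4, dimnames = list(NULL, paste0("m", 1:4)))
  expect_equal(ffxBms(ev)$group, ffxBms(ev + 1234.5)$group,
               tolerance = 1e-12)
  big <- ev + 5000   # exp(5000) overflows without max-subtraction
  expect_true(all(is.finite(ffxBms(big)$group)))
  ev[1, 1] <- NaN
  expect_error(ffxBms(ev), "finite")
  expect_error(ffxBms(matrix(0, 1, 1)), "two models")
})

# two fake single-parameter-table models over the two-region space
bmaFixture <- function(meansByModel, probs, F = c(0, 0)) {
  specs <- buildModelSpace()[c("backward-inVPM", "bidirectional-inVPM")]
  fits <- list(lapply(seq_along(specs), function(k) {
    tab <- tdcsdcm:::paramTable(specs[[k]], c("anodal", "sham"))
    fakePosterior(tab, meansByModel[[k]], spec = specs[[k]], F = F[k])
  }))
  list(fits = fits, weights = matrix(probs, 1))
}

test_that("BMA samples models in proportion to their posterior probability", {
  specs <- buildModelSpace()[c("backward-inVPM", "bidirectional-inVPM")]
  tab1 <- tdcsdcm:::paramTable(specs[[1]], c("anodal", "sham"))
  tab2 <- tdcsdcm:::paramTable(specs[[2]], c("anodal", "sham"))
  # tag the models by a recognizable backward-connection value
  m1 <- ifelse(tab1$slot == "A" & tab1$i == 2 & tab1$j == 1, -1, 0)
  m2 <- ifelse(tab2$slot == "A" & tab2$i == 2 & tab2$j == 1, +1, 0)
  fits <- list(list(fakePosterior(tab1, m1, spec = specs[[1]]),
                    fakePosterior(tab2, m2, spec = specs[[2]])))
  # remaining mass on a third model is irrelevant to the 5x ratio, so
  # renormalize 0.1 / 0.5 onto two models
  w <- matrix(c(0.1, 0.5) / 0.6, 1)
  bma <- bmaSample(w, fits, nSamples = 10000, seed = 99)
  backs <- connectionSamples(bma, "IFS->VPM", "anodal")
  n2 <- sum(backs > 0.5)
  n1 <- sum(backs < -0.5)
  expect_equal(n1 + n2, 10000)
  # 5x sampling ratio within 3 binomial SEs at n = 10,000
  pHat <- n2 / 10000
  se <- sqrt(pHat * (1 - pHat) / 10000)
  expect_lt(abs(pHat - 5 / 6), 3 * se)
})

test_that("connections absent from every model are sampled as exactly zero", {
  spec <- buildModelSpace()[["backward-inVPM"]]
  # a generalized table with no entries touching the forward connection
  tab <- rbind(
    tabRow("A(IFS self)", "A", 1, 1, NA, "a_diag", -0.5, 0.0625),
    tabRow("A(VPM self)", "A", 2, 2, NA, "a_diag", -0.5, 0.0625),
    tabRow("A(IFS->VPM)", "A", 2, 1, NA, "a_off"))
  fits <- list(list(fakePosterior(tab, c(-0.4, -0.3, -0.2),
                                  cov = diag(0.01, 3), spec = spec)))
  bma <- bmaSample(matrix(1), fits, nSamples = 500, seed = 3,
                   conditions = c("anodal", "sham"))
  expect_true(all(connectionSamples(bma, "VPM->IFS", "anodal") == 0))
  expect_equal(mean(connectionSamples(bma, "VPM->IFS", "sham")), 0)
  # present connections do vary
  expect_gt(sd(connectionSamples(bma, "IFS->VPM", "anodal")), 0)
})

test_that("BMA connection means converge to the weighted per-model means", {
  specs <- buildModelSpace()[c("backward-inVPM", "bidirectional-inVPM")]
  tab1 <- tdcsdcm:::paramTable(specs[[1]], c("anodal", "sham"))
  tab2 <- tdcsdcm:::paramTable(specs[[2]], c("anodal", "sham"))
  m1 <- ifelse(tab1$slot == "A" & tab1$i == 1 & tab1$j == 2, 0.9, -0.3)
  m2 <- ifelse(tab2$slot == "A" & tab2$i == 1 & tab2$j == 2, 0.5, -0.3)
  fits <- list(list(
    fakePosterior(tab1, m1, cov = diag(0.04, nrow(tab1)), spec = specs[[1]]),
    fakePosterior(tab2, m2, cov = diag(0.04, nrow(tab2)), spec = specs[[2]])))
  w <- matrix(c(0.3, 0.7), 1)
  bma <- bmaSample(w, fits, nSamples = 1e6, seed = 7)
  s <- connectionSamples(bma, "VPM->IFS", "sham")
  # forward entry: model 1 contributes A=0.9 (plus B.sham since
  # bMask[1,2] is FALSE there => no B), model 2 contributes 0.5 + B.sham
  # (mean -0.3); closed-form weighted mean:
  want <- 0.3 * 0.9 + 0.7 * (0.5 - 0.3)
  se <- sd(s) / sqrt(length(s))
  expect_lt(abs(mean(s) - want), 3 * se)
})

test_that("the two-distribution test behaves at its analytic landmarks", {
  set.seed(5)
  a <- rnorm(5000); b <- rnorm(5000)
  t1 <- twoDistributionTest(a, b, seed = 2)
  expect_lt(abs(t1$proportion - 0.5), 0.03)
  expect_false(t1$significant)
  # point masses at distinct values separate completely
  t2 <- twoDistributionTest(rep(1, 100), rep(0, 100), seed = 2)
  expect_equal(t2$proportion, 1)
  expect_true(t2$significant)
  expect_equal(t2$direction, "a>b")
  # the 95% boundary: N(0,1) vs N(1.645*sqrt(2),1) puts the exceedance at
  # Phi(1.645) ~ 0.95
  a3 <- rnorm(20000)
  b3 <- rnorm(20000, 1.645 * sqrt(2))
  t3 <- twoDistributionTest(a3, b3, seed = 3)
  expect_equal(t3$direction, "a<b")
  expect_lt(abs(t3$proportion - pnorm(1.645)), 0.01)
})

test_that("the two-distribution test is exactly antisymmetric", {
  set.seed(8)
  a <- rnorm(3000, 0.3); b <- rnorm(3000)
  t1 <- twoDistributionTest(a, b, seed = 11)
  t2 <- twoDistributionTest(b, a, seed = 11)
  expect_identical(t1$proportion, t2$proportion)
  expect_identical(t1$pAGreater, 1 - t2$pAGreater)
  expect_true(t1$direction != t2$direction)
  expect_error(twoDistributionTest(numeric(0), numeric(0)), "non-empty")
  expect_error(twoDistributionTest(rnorm(3), rnorm(4)), "equal length")
})

test_that("condition contrasts report means, exceedance and direction", {
  specs <- buildModelSpace()["backward-inVPM"]
  tab <- tdcsdcm:::paramTable(specs[[1]], c("anodal", "sham"))
  # plant a 5-pooled-SD separation on the backward connection via B
  mean <- numeric(nrow(tab))
  mean[tab$slot == "A" & tab$i == 2 & tab$j == 1] <- -0.45
  mean[tab$slot == "B" & tab$i == 2 & tab$j == 1 & tab$cond == "anodal"] <- -0.25
  mean[tab$slot == "B" & tab$i == 2 & tab$j == 1 & tab$cond == "sham"] <- 0.25
  fits <- list(list(fakePosterior(tab, mean, cov = diag(0.005, nrow(tab)),
                                  spec = specs[[1]])))
  bma <- bmaSample(matrix(1), fits, nSamples = 4000, seed = 21)
  cc <- conditionContrast(bma, "IFS->VPM")
  expect_true(cc$test$significant)
  expect_equal(cc$test$direction, "a<b")
  expect_equal(cc$meanA, -0.70, tolerance = 0.02)
  expect_equal(cc$meanB, -0.20, tolerance = 0.02)
  expect_equal(cc$percentA + cc$percentB, 100)
  expect_equal(cc$percentA, 100 * cc$test$pAGreater)
  # identical sample arrays are never significant
  b2 <- bma
  b2@samples[, "IFS->VPM", "sham"] <- b2@samples[, "IFS->VPM", "anodal"]
  cc2 <- conditionContrast(b2, "IFS->VPM")
  expect_false(cc2$test$significant)
  expect_equal(cc2$meanA, cc2$meanB)
  expect_error(conditionContrast(bma, "nope"), "unknown connection")
  # the full table has one row per connection
  expect_equal(nrow(contrastTable(bma)), 4)
})
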