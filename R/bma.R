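# Sampling-based Bayesian model averaging over subjects and models, and the
# two-distribution test used to compare condition-specific connection-value
# distributions.

connectionLabels <- function(regions) {
  n <- length(regions)
  out <- character(0)
  for (j in seq_len(n)) for (i in seq_len(n))
    out <- c(out, if (i == j) sprintf("%s self", regions[i])
             else sprintf("%s->%s", regions[j], regions[i]))
  out
}

#' Bayesian model averaging by weighted posterior sampling
#'
#' Builds the posterior distribution over per-connection, per-condition
#' effective connection values, marginal over model architecture: each
#' sample draws a subject uniformly, a model according to that subject's
#' posterior model probability, and a parameter vector from that model's
#' Gaussian posterior; the sample's connection values are the effective
#' (A + B_cond) entries, with a connection absent from the drawn model
#' contributing exactly zero. Ten thousand samples are drawn by default.
#'
#' @param weights subjects x models matrix of posterior model probabilities
#'   (rows sum to 1), e.g. \code{ffxBms(ev)$bySubject}; a single row may be
#'   given as a vector.
#' @param fits list (subjects) of named lists (models) of
#'   [DCMPosterior-class], model order matching \code{weights} columns.
#' @param nSamples number of samples (default 10000).
#' @param seed sampler seed.
#' @param subjects optional subset of subject indices to sample from
#'   (subject-restricted BMA, used for per-subject connection means).
#' @param conditions condition labels; taken from the fitted posteriors'
#'   parameter tables when NULL.
#' @return a [BMAResult-class].
#' @export
bmaSample <- function(weights, fits, nSamples = 10000, seed = 1,
                      subjects = NULL, conditions = NULL) {
  if (is.vector(weights)) weights <- matrix(weights, nrow = 1)
  nSub <- length(fits)
  nMod <- length(fits[[1]])
  if (nrow(weights) != nSub || ncol(weights) != nMod)
    stop("weights must be subjects x models, matching the fits list")
  if (any(abs(rowSums(weights) - 1) > 1e-6))
    stop("each subject's model probabilities must sum to 1")
  if (nSamples < 1) stop("nSamples must be >= 1")
  if (is.null(subjects)) subjects <- seq_len(nSub)
  spec1 <- fits[[1]][[1]]@spec
  regions <- spec1@regions
  tab1 <- fits[[1]][[1]]@diagnostics$paramTable
  conds <- if (is.null(conditions)) unique(stats::na.omit(tab1$cond))
           else conditions
  if (!length(conds))
    stop("no condition labels available; pass `conditions`")
  connLabs <- connectionLabels(regions)
  out <- array(0, dim = c(nSamples, length(connLabs), length(conds)),
               dimnames = list(NULL, connLabs, conds))
  withSeed(seed, {
    subDraw <- sample(subjects, nSamples, replace = TRUE)
    modDraw <- integer(nSamples)
    for (sidx in unique(subDraw)) {
      sel <- which(subDraw == sidx)
      modDraw[sel] <- sample.int(nMod, length(sel), replace = TRUE,
                                 prob = weights[sidx, ])
    }
    for (sidx in unique(subDraw)) for (midx in unique(modDraw[subDraw == sidx])) {
      sel <- which(subDraw == sidx & modDraw == midx)
      q <- fits[[sidx]][[midx]]
      tab <- q@diagnostics$paramTable
      theta <- rmvn(length(sel), q@mean, q@cov)
      # linear map from free parameters to effective connection values:
      # value(i<-j, cond) = A[i,j] + B_cond[i,j]; masked entries stay 0
      for (ci in seq_along(conds)) {
        L <- matrix(0, nrow(tab), length(connLabs))
        n <- length(regions)
        colOf <- function(i, j) (j - 1) * n + i
        for (r in seq_len(nrow(tab))) {
          if (tab$slot[r] == "A")
            L[r, colOf(tab$i[r], tab$j[r])] <- 1
          else if (tab$slot[r] == "B" && tab$cond[r] == conds[ci])
            L[r, colOf(tab$i[r], tab$j[r])] <- 1
        }
        out[sel, , ci] <- theta %*% L
      }
    }
  })
  new("BMAResult", samples = out, seed = as.integer(seed),
      weights = as.matrix(weights))
}

#' Per-subject BMA connection means
#'
#' Average effective connection strengths per subject per connection,
#' obtained by subject-restricted BMA sampling: only the given subject is
#' drawn, models weighted by that subject's posterior probabilities. These
#' per-subject means feed the brain-behaviour correlation.
#'
#' @inheritParams bmaSample
#' @param nSamples samples per subject.
#' @return array (subjects x connections x conditions) of posterior mean
#'   connection values.
#' @export
bmaSubjectMeans <- function(weights, fits, nSamples = 2000, seed = 1) {
  if (is.vector(weights)) weights <- matrix(weights, nrow = 1)
  nSub <- length(fits)
  out <- NULL
  for (sidx in seq_len(nSub)) {
    b <- bmaSample(weights, fits, nSamples = nSamples,
                   seed = childSeed(seed, sidx), subjects = sidx)
    m <- apply(b@samples, c(2, 3), mean)
    if (is.null(out))
      out <- array(0, dim = c(nSub, dim(m)),
                   dimnames = c(list(names(fits)), dimnames(m)))
    out[sidx, , ] <- m
  }
  out
}

#' Two-distribution test for a condition difference
#'
#' Compares two sampled connection-value distributions (one per condition)
#' by randomly pairing samples across conditions and asking what proportion
#' of the paired differences share the majority sign. Pairing uses
#' independent index draws under a fixed seed, and each drawn index pair is
#' used in both orders, which makes the test exactly antisymmetric in its
#' arguments. The difference is deemed significant when the proportion
#' reaches \code{threshold} (default 0.95, the study's criterion).
#'
#' @param samplesA,samplesB equal-length numeric sample vectors.
#' @param threshold posterior probability required to reject equality.
#' @param seed seed for the random pairing.
#' @return list: \code{proportion} (exceedance proportion, >= 0.5),
#'   \code{significant}, \code{direction} ("a>b" or "a<b"),
#'   \code{pAGreater} (probability that a random A sample exceeds a random
#'   B sample).
#' @export
twoDistributionTest <- function(samplesA, samplesB, threshold = 0.95,
                                seed = 1) {
  if (!length(samplesA) || !length(samplesB))
    stop("sample arrays must be non-empty")
  if (length(samplesA) != length(samplesB))
    stop("sample arrays must have equal length")
  n <- length(samplesA)
  d <- withSeed(seed, {
    ia <- sample.int(n, n, replace = TRUE)
    ib <- sample.int(n, n, replace = TRUE)
    c(samplesA[ia] - samplesB[ib], samplesA[ib] - samplesB[ia])
  })
  pA <- mean(d > 0) + 0.5 * mean(d == 0)
  proportion <- max(pA, 1 - pA)
  list(proportion = proportion,
       significant = proportion >= threshold,
       direction = if (pA >= 0.5) "a>b" else "a<b",
       pAGreater = pA)
}

#' Condition contrast for one connection
#'
#' Condition means and the two-distribution test for one connection of a
#' BMA result, with the exceedance proportion also formatted as the
#' percentage pair the study reports (100 p vs 100 (1 - p)).
#'
#' @param bma a [BMAResult-class].
#' @param connection connection label (see dimnames of the samples).
#' @param condA,condB condition labels to contrast (A vs B).
#' @param threshold significance threshold on the exceedance proportion.
#' @param seed pairing seed for the test.
#' @return list: \code{meanA}, \code{meanB}, \code{test} (from
#'   [twoDistributionTest()]), \code{percentA}, \code{percentB} (the
#'   exceedance percentage of A over B and its complement).
#' @export
conditionContrast <- function(bma, connection, condA = "anodal",
                              condB = "sham", threshold = 0.95, seed = 1) {
  a <- connectionSamples(bma, connection, condA)
  b <- connectionSamples(bma, connection, condB)
  tst <- twoDistributionTest(a, b, threshold = threshold, seed = seed)
  list(connection = connection,
       meanA = mean(a), meanB = mean(b),
       test = tst,
       percentA = 100 * tst$pAGreater,
       percentB = 100 * (1 - tst$pAGreater))
}

#' Group contrast table over all connections
#'
#' @param bma a [BMAResult-class].
#' @param condA,condB,threshold,seed as in [conditionContrast()].
#' @return data.frame, one row per connection: condition means (Hz, to the
#'   reporting precision of 2 decimals in the formatted columns), exceedance
#'   percentages and significance.
#' @export
contrastTable <- function(bma, condA = "anodal", condB = "sham",
                          threshold = 0.95, seed = 1) {
  conns <- dimnames(bma@samples)[[2]]
  rows <- lapply(conns, function(cn) {
    cc <- conditionContrast(bma, cn, condA, condB, threshold, seed)
    data.frame(connection = cn,
               meanA = cc$meanA, meanB = cc$meanB,
               percentA = cc$percentA, percentB = cc$percentB,
               significant = cc$test$significant,
               direction = cc$test$direction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:5] <- c(paste0("mean_", condA), paste0("mean_", condB),
                       paste0("pct_", condA), paste0("pct_", condB))
  out
}
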