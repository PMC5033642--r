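# Reaction-time cleaning, condition summaries, one-tailed paired tests and
# the brain-behaviour correlation.

#' Clean naming trials
#'
#' Two-stage exclusion, applied once (not iteratively): first any trial
#' with an incorrect response or an invalid voice-key activation is removed
#' regardless of its RT; then, on the accuracy-cleaned set, trials whose RT
#' lies more than two sample standard deviations from their
#' subject-by-condition mean are removed. The log reports counts per rule
#' and the total exclusion percentage.
#'
#' @param trials data.frame with columns subject, condition, item, rt_ms,
#'   accurate, voicekey_ok.
#' @param sdCutoff deviation cutoff in SD units (default 2).
#' @return list with \code{trials} (retained rows) and \code{log}
#'   (data.frame: nInput, nAccuracy, nVoiceKey, nOutlier, nRetained,
#'   pctExcluded).
#' @export
cleanTrials <- function(trials, sdCutoff = 2) {
  if (!nrow(trials)) stop("trial table is empty")
  accurate <- as.logical(trials$accurate)
  vk <- as.logical(trials$voicekey_ok)
  nAcc <- sum(!accurate)
  nVk <- sum(accurate & !vk)
  keep1 <- trials[accurate & vk, , drop = FALSE]
  if (!nrow(keep1)) stop("all trials excluded by accuracy/voice-key rules")
  grp <- interaction(keep1$subject, keep1$condition, drop = TRUE)
  mu <- ave(keep1$rt_ms, grp, FUN = mean)
  sd_ <- ave(keep1$rt_ms, grp, FUN = stats::sd)
  sd_[is.na(sd_)] <- 0
  out <- abs(keep1$rt_ms - mu) > sdCutoff * sd_
  keep2 <- keep1[!out, , drop = FALSE]
  if (!nrow(keep2)) stop("all trials excluded")
  log <- data.frame(
    nInput = nrow(trials), nAccuracy = nAcc, nVoiceKey = nVk,
    nOutlier = sum(out), nRetained = nrow(keep2),
    pctExcluded = 100 * (nrow(trials) - nrow(keep2)) / nrow(trials))
  list(trials = keep2, log = log)
}

#' By-subject or by-item condition means
#'
#' One row per unit (subject or item), one column per condition, computed
#' over retained trials only. Units missing a condition entirely are
#' dropped with a warning.
#'
#' @param trials cleaned trial data.frame.
#' @param by \code{"subject"} or \code{"item"}.
#' @return data.frame with a unit column and one mean-RT column (ms) per
#'   condition.
#' @export
conditionMeans <- function(trials, by = c("subject", "item")) {
  by <- match.arg(by)
  unit <- trials[[by]]
  conds <- sort(unique(trials$condition))
  agg <- stats::aggregate(trials$rt_ms,
                          list(unit = unit, condition = trials$condition),
                          mean)
  wide <- stats::reshape(agg, idvar = "unit", timevar = "condition",
                         direction = "wide")
  names(wide) <- sub("^x\\.", "", names(wide))
  missing <- !stats::complete.cases(wide)
  if (any(missing)) {
    warning(sum(missing), " unit(s) missing a condition; dropped")
    wide <- wide[!missing, , drop = FALSE]
  }
  rownames(wide) <- NULL
  wide[, c("unit", conds)]
}

#' One-tailed paired t-test
#'
#' Classical paired t on unit means with df = n - 1 and the one-tailed tail
#' in the stated direction for the mean of a - b.
#'
#' @param meansA,meansB equal-length numeric vectors of unit means.
#' @param direction \code{"greater"} (mean(a - b) > 0) or \code{"less"}.
#' @return list: \code{t}, \code{df}, \code{p}.
#' @export
pairedTOneTailed <- function(meansA, meansB,
                             direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(meansA) != length(meansB) || length(meansA) < 2)
    stop("need equal-length vectors with at least 2 pairs")
  d <- meansA - meansB
  if (all(d == 0))
    return(list(t = 0, df = length(d) - 1, p = 0.5))
  if (stats::var(d) == 0)
    stop("zero variance of paired differences; t undefined")
  tt <- stats::t.test(meansA, meansB, paired = TRUE,
                      alternative = direction)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Percentage naming facilitation
#'
#' Percentage RT change under anodal tDCS relative to sham:
#' 100 (sham - anodal) / sham. Positive values mean faster naming under
#' anodal stimulation.
#'
#' @param meanAnodal,meanSham condition mean RTs (ms); sham must be
#'   positive.
#' @return percentage facilitation.
#' @examples
#' rtChangePercent(811.4, 839.5)  # ~3.35
#' @export
rtChangePercent <- function(meanAnodal, meanSham) {
  if (any(meanSham <= 0)) stop("sham mean RT must be positive")
  100 * (meanSham - meanAnodal) / meanSham
}

#' Brain-behaviour correlation
#'
#' Two-tailed Pearson correlation between per-subject connectivity change
#' (anodal - sham connection values) and per-subject percentage naming
#' facilitation. Reports r, R^2 = r^2, the two-tailed p, and the degrees of
#' freedom under both conventions: \code{df} = n - 2 (the Pearson
#' convention) and \code{dfPrinted} = n (the convention the study's report
#' uses); the p-value follows df = n - 2. Optionally refits after removing
#' the subject with the lowest connectivity change (leave-one-out check).
#'
#' @param deltaConn per-subject connection change (vector), or a
#'   subjects x connections matrix for a per-connection table.
#' @param deltaRt per-subject percentage RT change.
#' @param dropLowest if TRUE, also report the refit without the subject
#'   with the lowest connectivity change.
#' @return for vector input, a list with r, df, dfPrinted, p, R2 (and
#'   \code{refit} when requested); for matrix input, a data.frame with one
#'   row per connection.
#' @export
brainBehaviourCorr <- function(deltaConn, deltaRt, dropLowest = FALSE) {
  if (is.matrix(deltaConn)) {
    rows <- lapply(colnames(deltaConn), function(cn) {
      r <- brainBehaviourCorr(deltaConn[, cn], deltaRt)
      data.frame(connection = cn, r = r$r, df = r$df,
                 dfPrinted = r$dfPrinted, p = r$p, R2 = r$R2,
                 stringsAsFactors = FALSE)
    })
    return(do.call(rbind, rows))
  }
  n <- length(deltaConn)
  if (n < 3 || length(deltaRt) != n)
    stop("need equal-length vectors with at least 3 subjects")
  if (stats::var(deltaConn) == 0 || stats::var(deltaRt) == 0)
    stop("zero variance in correlation input")
  ct <- stats::cor.test(deltaConn, deltaRt, alternative = "two.sided",
                        method = "pearson")
  out <- list(r = unname(ct$estimate), df = unname(ct$parameter),
              dfPrinted = n, p = unname(ct$p.value),
              R2 = unname(ct$estimate)^2)
  if (dropLowest) {
    keep <- -which.min(deltaConn)
    out$refit <- brainBehaviourCorr(deltaConn[keep], deltaRt[keep])
  }
  out
}
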