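#' Cohort specification with the study's planted conditions
#'
#' Constructor for [CohortSpec-class]. The default population means are the
#' per-condition effective connection values reported for the study: under
#' sham, IFS self -0.60, VPM self -0.26, forward VPM-to-IFS 0.96, backward
#' IFS-to-VPM -0.26 Hz; under anodal tDCS, IFS self -0.57, VPM self -0.09,
#' forward 0.87, backward -0.67 Hz. The two planted condition effects are
#' thus a more negative backward connection and a less negative VPM
#' self-connection under anodal stimulation. The driving input enters VPM
#' (the winning architecture). Condition values are generated
#' within-subject correlated, as in real crossover data: a subject's sham
#' value and their anodal-minus-sham difference are drawn separately.
#' Between-region couplings vary additively (Gaussian, SD
#' \code{betweenSD}); self-connections are decay-rate constants and vary
#' multiplicatively (mean-corrected log-normal), which keeps them negative
#' without truncating the planted condition means.
#'
#' @param nSubjects cohort size (default 10).
#' @param betweenSD between-subject SD of between-region connection values
#'   and their condition differences (Hz, default 0.15; additive).
#' @param selfLogSD,selfCondLogSD log-scale SDs of the multiplicative
#'   between-subject (default 0.35) and condition-specific (default 0.15)
#'   variability of self-connections; self-connections are rate constants,
#'   so they vary multiplicatively and stay negative.
#' @param rho planted correlation between the subject's forward-connection
#'   (VPM to IFS) anodal-minus-sham change and their percentage naming
#'   facilitation (default 0.7).
#' @param snr target signal-to-noise ratio of the simulated BOLD (default 1).
#' @param seed master seed; every random quantity in the cohort derives
#'   from it.
#' @param ... further slot overrides (\code{effMeans}, \code{cMean},
#'   \code{cSD}, \code{inputSite}, \code{rt}, \code{regions},
#'   \code{condNoiseMask}).
#' @return a [CohortSpec-class].
#' @export
cohortSpec <- function(nSubjects = 10, betweenSD = 0.15, selfLogSD = 0.35,
                       selfCondLogSD = 0.15, rho = 0.7,
                       snr = 1, seed = 1, ...) {
  ov <- list(...)
  regions <- if (is.null(ov$regions)) c("IFS", "VPM") else ov$regions
  effMeans <- if (is.null(ov$effMeans)) list(
    anodal = matrix(c(-0.57, -0.67, 0.87, -0.09), 2, 2,
                    dimnames = list(regions, regions)),
    sham = matrix(c(-0.60, -0.26, 0.96, -0.26), 2, 2,
                  dimnames = list(regions, regions))
  ) else ov$effMeans
  rt <- utils::modifyList(
    list(shamMean = 839.5, subjectSD = 94.2, pctMean = 3.35, pctSD = 10,
         trialSD = 120, itemSD = 60, minRT = 200, accuracy = 0.97,
         voiceKeyOK = 0.99),
    if (is.null(ov$rt)) list() else ov$rt)
  new("CohortSpec", nSubjects = nSubjects, effMeans = effMeans,
      betweenSD = betweenSD, selfLogSD = selfLogSD,
      selfCondLogSD = selfCondLogSD,
      cMean = if (is.null(ov$cMean)) 0.5 else ov$cMean,
      cSD = if (is.null(ov$cSD)) 0.1 else ov$cSD,
      inputSite = if (is.null(ov$inputSite)) "VPM" else ov$inputSite,
      condNoiseMask = if (is.null(ov$condNoiseMask))
        matrix(TRUE, length(regions), length(regions))
      else ov$condNoiseMask,
      snr = snr, rho = rho, rt = rt, regions = regions,
      seed = as.integer(seed))
}

# subject-level ground truth: per-condition effective matrices, C, the
# RT model, all drawn from the cohort population
drawGroundTruth <- function(cs, seed = cs@seed) {
  n <- length(cs@regions)
  conds <- names(cs@effMeans)
  ref <- conds[length(conds)]          # last condition is the baseline (sham)
  withSeed(seed, {
    out <- vector("list", cs@nSubjects)
    for (s in seq_len(cs@nSubjects)) {
      for (attempt in 1:100) {
        # between-region couplings vary additively; self-connections are
        # rate constants and vary multiplicatively (log-normal, mean
        # corrected), which respects the inhibitory constraint without
        # truncation and so preserves the planted condition means exactly
        offNoise <- matrix(stats::rnorm(n * n, 0, cs@betweenSD), n, n)
        diag(offNoise) <- 0
        lnBase <- stats::rnorm(n, -cs@selfLogSD^2 / 2, cs@selfLogSD)
        eff <- list()
        ok <- TRUE
        for (cond in conds) {
          condNoise <- matrix(stats::rnorm(n * n, 0, cs@betweenSD), n, n)
          diag(condNoise) <- 0
          condNoise[!cs@condNoiseMask] <- 0
          if (cond == ref) condNoise[] <- 0
          lnCond <- stats::rnorm(n, -cs@selfCondLogSD^2 / 2,
                                 cs@selfCondLogSD)
          E <- cs@effMeans[[cond]] + offNoise + condNoise
          diag(E) <- diag(cs@effMeans[[cond]]) * exp(lnBase + lnCond)
          eff[[cond]] <- E
        }
        for (cond in conds) {
          if (any(diag(eff[[cond]]) >= 0) ||
              any(Re(eigen(eff[[cond]], only.values = TRUE)$values) >= -0.01)) {
            ok <- FALSE
            break
          }
        }
        if (ok) break
      }
      if (!ok) stop("could not draw a stable subject after 100 attempts")
      cvec <- max(cs@cMean + stats::rnorm(1, 0, cs@cSD), 0.1)
      C <- matrix(0, n, 1, dimnames = list(cs@regions, NULL))
      C[cs@inputSite, 1] <- cvec
      A <- Reduce(`+`, eff) / length(eff)
      B <- lapply(eff, function(E) E - A)
      params <- connectivityParams(A, B, C, regions = cs@regions)
      # planted behaviour: facilitation correlated with the forward
      # (region2 -> region1, VPM -> IFS) connection change
      dFwd <- eff[[conds[1]]][1, 2] - eff[[ref]][1, 2]
      muD <- cs@effMeans[[conds[1]]][1, 2] - cs@effMeans[[ref]][1, 2]
      z <- (dFwd - muD) / cs@betweenSD
      eps <- stats::rnorm(1)
      pct <- cs@rt$pctMean +
        cs@rt$pctSD * (cs@rho * z + sqrt(1 - cs@rho^2) * eps)
      shamRT <- max(stats::rnorm(1, cs@rt$shamMean, cs@rt$subjectSD), 400)
      rtMeans <- stats::setNames(c(shamRT * (1 - pct / 100), shamRT), conds)
      out[[s]] <- list(subject = sprintf("sub%02d", s), params = params,
                       effective = eff, pctChange = pct, rtMeans = rtMeans,
                       forwardDelta = dFwd, noiseSd = NA_real_)
    }
    out
  })
}

#' Simulate one synthetic subject
#'
#' Generates the two-session ROI BOLD series (one per condition) and the
#' trial-level behavioural table for one subject's ground truth. The
#' observation-noise SD is set from the subject's own noise-free signal SD
#' and the cohort's target SNR. Deterministic given the seed.
#'
#' @param gt one element of the list returned by the ground-truth sampler
#'   (fields \code{params}, \code{rtMeans}, \code{subject}).
#' @param design a [DesignSpec-class].
#' @param cs the [CohortSpec-class] (for SNR and the RT model).
#' @param seed subject seed.
#' @param itemEffects named per-item RT offsets (ms) shared across the
#'   cohort; drawn from the seed when NULL.
#' @param series simulate the BOLD series (TRUE) or trials only.
#' @param dt integration step (s).
#' @return list: \code{series} (named list per condition of nVolumes x n
#'   matrices), \code{trials} (data.frame), \code{events} (per condition),
#'   \code{noiseSd}.
#' @export
simulateSubject <- function(gt, design = designSpec(), cs = cohortSpec(),
                            seed = 1, itemEffects = NULL, series = TRUE,
                            dt = 0.1) {
  conds <- design@conditions
  items <- sprintf("item%03d", seq_len(design@nTrials))
  if (is.null(itemEffects))
    itemEffects <- withSeed(childSeed(seed, 1),
      stats::setNames(stats::rnorm(length(items), 0, cs@rt$itemSD), items))
  evs <- lapply(seq_along(conds), function(k)
    makeDesign(design, seed = childSeed(seed, 10 + k)))
  names(evs) <- conds
  out <- list(events = lapply(evs, `[[`, "events"))
  noiseSd <- NA_real_
  if (series) {
    clean <- lapply(conds, function(cond)
      simulateBold(gt$params, hemodynamicParams(length(cs@regions)), design,
                   evs[[cond]]$events$onset, cond, dt = dt, noiseSd = 0))
    names(clean) <- conds
    sigSd <- stats::sd(unlist(lapply(clean, function(y)
      as.numeric(scale(y, center = TRUE, scale = FALSE)))))
    noiseSd <- sigSd / cs@snr
    out$series <- lapply(seq_along(conds), function(k) {
      y <- clean[[k]]
      y + withSeed(childSeed(seed, 20 + k),
                   matrix(stats::rnorm(length(y), 0, noiseSd),
                          nrow(y), ncol(y)))
    })
    names(out$series) <- conds
  }
  trials <- withSeed(childSeed(seed, 30), {
    do.call(rbind, lapply(conds, function(cond) {
      it <- evs[[cond]]$events$item
      rt <- gt$rtMeans[[cond]] + itemEffects[it] +
        stats::rnorm(length(it), 0, cs@rt$trialSD)
      data.frame(subject = gt$subject, condition = cond, item = it,
                 rt_ms = pmax(rt, cs@rt$minRT),
                 accurate = stats::runif(length(it)) < cs@rt$accuracy,
                 voicekey_ok = stats::runif(length(it)) < cs@rt$voiceKeyOK,
                 stringsAsFactors = FALSE)
    }))
  })
  rownames(trials) <- NULL
  out$trials <- trials
  out$noiseSd <- noiseSd
  out
}

#' Simulate a synthetic cohort
#'
#' Draws per-subject ground truth from the cohort population and simulates
#' every subject's sessions and trials. All randomness flows from the
#' master seed, so regeneration is bit-identical. The returned ground-truth
#' ledger is sufficient to score recovery of connectivity, condition
#' effects and the planted brain-behaviour correlation.
#'
#' @param cs a [CohortSpec-class].
#' @param design a [DesignSpec-class].
#' @param seed overrides the cohort master seed.
#' @param series simulate BOLD series (TRUE) or behavioural tables only.
#' @param dt integration step (s).
#' @return list: \code{subjects} (per-subject output of
#'   [simulateSubject()]), \code{trials} (all trials), \code{groundTruth}
#'   (per-subject list: params, effective matrices, pctChange, rtMeans,
#'   noiseSd), \code{effectiveArray} (subjects x connections x conditions
#'   true values), \code{design}, \code{spec} (the cohort spec).
#' @export
simulateCohort <- function(cs = cohortSpec(), design = designSpec(),
                           seed = cs@seed, series = TRUE, dt = 0.1) {
  gts <- drawGroundTruth(cs, seed = childSeed(seed, 1000))
  items <- sprintf("item%03d", seq_len(design@nTrials))
  itemEffects <- withSeed(childSeed(seed, 2000),
    stats::setNames(stats::rnorm(length(items), 0, cs@rt$itemSD), items))
  subjects <- vector("list", cs@nSubjects)
  for (s in seq_len(cs@nSubjects)) {
    subjects[[s]] <- simulateSubject(gts[[s]], design, cs,
                                     seed = childSeed(seed, 3000 + s),
                                     itemEffects = itemEffects,
                                     series = series, dt = dt)
    gts[[s]]$noiseSd <- subjects[[s]]$noiseSd
  }
  names(subjects) <- vapply(gts, `[[`, "", "subject")
  conds <- names(cs@effMeans)
  connLabs <- connectionLabels(cs@regions)
  effArr <- array(0, dim = c(cs@nSubjects, length(connLabs), length(conds)),
                  dimnames = list(names(subjects), connLabs, conds))
  for (s in seq_len(cs@nSubjects)) for (ci in seq_along(conds))
    effArr[s, , ci] <- as.numeric(gts[[s]]$effective[[conds[ci]]])
  list(subjects = subjects,
       trials = do.call(rbind, lapply(subjects, `[[`, "trials")),
       groundTruth = gts, effectiveArray = effArr,
       design = design, spec = cs)
}
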