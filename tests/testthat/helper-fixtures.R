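# shared fixtures: small parameter sets, designs and fake posteriors built
# in code (no stored data)

fixtureParams <- function(conds = c("anodal", "sham"),
                          Bvals = NULL, Cvals = c(0, 0.5)) {
  A <- matrix(c(-0.5, -0.3, 0.9, -0.25), 2, 2)
  if (is.null(Bvals))
    Bvals <- stats::setNames(rep(list(matrix(0, 2, 2)), length(conds)), conds)
  connectivityParams(A, Bvals, C = Cvals, regions = c("IFS", "VPM"))
}

smallDesign <- function(nVolumes = 120, nTrials = 30)
  designSpec(nVolumes = nVolumes, nTrials = nTrials)

# simulate one subject's two sessions from known parameters at a given SNR
fixtureSubject <- function(params, design, seed = 1, snr = 1, dt = 0.1) {
  on <- makeDesign(design, seed = seed)$events$onset
  hp <- hemodynamicParams(2)
  conds <- names(params@B)
  clean <- lapply(conds, function(cc)
    simulateBold(params, hp, design, on, cc, dt = dt))
  names(clean) <- conds
  sig <- stats::sd(unlist(lapply(clean, function(y) scale(y, scale = FALSE))))
  noiseSd <- if (is.finite(snr) && snr > 0) sig / snr else 0
  data <- lapply(seq_along(clean), function(k) {
    y <- clean[[k]]
    if (noiseSd == 0) return(y)
    y + withr::with_seed(seed * 100 + k,
      matrix(stats::rnorm(length(y), 0, noiseSd), nrow(y), ncol(y)))
  })
  names(data) <- conds
  list(data = data, onsets = on, clean = clean, noiseSd = noiseSd)
}

# hand-built DCMPosterior over an explicit parameter table, for BMA tests
fakePosterior <- function(tab, mean, cov = NULL, F = 0,
                          spec = buildModelSpace()[[1]]) {
  if (is.null(cov)) cov <- diag(1e-12, length(mean))
  names(mean) <- tab$name
  new("DCMPosterior", mean = mean, cov = cov, lambda = 1, freeEnergy = F,
      spec = spec, converged = TRUE,
      diagnostics = list(paramTable = tab, explainedVariance = 1,
                         Ftrace = F, iterations = 1),
      settings = list(seed = 1L))
}

# parameter table rows built by hand (bypasses masks, for generalized cases)
tabRow <- function(name, slot, i, j, cond, cls, pmean = 0, pvar = 0.25)
  data.frame(name = name, slot = slot, i = i, j = j, cond = cond,
             class = cls, pmean = pmean, pvar = pvar,
             stringsAsFactors = FALSE)

# trial table builder
makeTrials <- function(subject = "s1", condition = "sham", rt,
                       accurate = TRUE, voicekey_ok = TRUE,
                       item = NULL) {
  n <- length(rt)
  data.frame(subject = rep_len(subject, n),
             condition = rep_len(condition, n),
             item = if (is.null(item)) sprintf("item%03d", seq_len(n))
                    else rep_len(item, n),
             rt_ms = rt,
             accurate = rep_len(accurate, n),
             voicekey_ok = rep_len(voicekey_ok, n),
             stringsAsFactors = FALSE)
}
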