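# Variational-Laplace inversion of a two-region DCM: Gauss-Newton ascent on
# the conditional mode with Levenberg-style damping, an EM point update of a
# single observation-noise precision, and the free-energy bound
# F = accuracy - KL(q || prior) as the convergence and model-comparison
# criterion.

#' Noise-free model prediction
#'
#' The deterministic forward prediction of a model: one simulated session
#' per condition, stacked row-wise in condition order. Identical to
#' [simulateBold()] with \code{noiseSd = 0} per session.
#'
#' @param spec a [DCMModelSpec-class]; params must respect its masks.
#' @param params a [ConnectivityParams-class].
#' @param design a [DesignSpec-class].
#' @param events onset vector, or named list of onset vectors per condition.
#' @param hp haemodynamic parameters.
#' @param dt integration step (s).
#' @return (conditions x nVolumes) x n matrix with a \code{condition}
#'   attribute marking each row's session.
#' @export
predictResponse <- function(spec, params, design, events,
                            hp = hemodynamicParams(nRegions(params)),
                            dt = 0.1) {
  conds <- names(params@B)
  evl <- eventsPerCondition(events, conds)
  assertRespectsSpec(params, spec)
  out <- lapply(conds, function(cond)
    simulateBold(params, hp, design, evl[[cond]], cond, dt = dt, noiseSd = 0))
  y <- do.call(rbind, out)
  attr(y, "condition") <- rep(conds, each = design@nVolumes)
  y
}

eventsPerCondition <- function(events, conditions) {
  if (is.list(events) && !is.data.frame(events)) {
    if (!all(conditions %in% names(events)))
      stop("events list must name every condition")
    return(events[conditions])
  }
  if (is.data.frame(events)) events <- events$onset
  stats::setNames(rep(list(as.numeric(events)), length(conditions)),
                  conditions)
}

# Gaussian KL divergence KL(N(m,S) || N(mu0, diag(s0)))
gaussianKL <- function(m, S, mu0, s0) {
  p <- length(m)
  0.5 * (sum(diag(S) / s0) + sum((m - mu0)^2 / s0) - p +
         sum(log(s0)) - logDet(S))
}

# F = expected log-likelihood under q - KL(q||prior); e are residuals and J
# the forward-model Jacobian at the posterior mean
freeEnergyCore <- function(e, J, S, lambda, m, mu0, s0, N) {
  acc <- -0.5 * lambda * (sum(e^2) + sum((J %*% S) * J)) +
    0.5 * N * log(lambda / (2 * pi))
  acc - gaussianKL(m, S, mu0, s0)
}

unstableE <- function(E) {
  if (nrow(E) == 2) {                 # analytic Routh-Hurwitz for 2 x 2
    E[1, 1] + E[2, 2] >= 0 || E[1, 1] * E[2, 2] - E[1, 2] * E[2, 1] <= 0
  } else any(Re(eigen(E, only.values = TRUE)$values) >= 0)
}

# fast per-theta predictor; precomputes regressors and sampling grid. When
# `cond` is given only that session is predicted, which lets the Jacobian
# skip sessions a B parameter cannot affect.
makePredictor <- function(spec, design, events, hp, conditions, dt,
                          tab, center = TRUE) {
  n <- length(spec@regions)
  duration <- (design@nVolumes - 1) * design@TR
  nSteps <- ceiling(duration / dt + 1e-9)
  evl <- eventsPerCondition(events, conditions)
  U <- lapply(evl, function(on) {
    if (length(on) && max(on) > design@nVolumes * design@TR)
      stop("design events extend beyond the scanned interval")
    matrix(inputRegressor(on, dt, nSteps), ncol = 1)
  })
  trTimes <- (seq_len(design@nVolumes) - 1) * design@TR
  function(theta, cond = NULL) {
    pv <- paramsFromVector(theta, tab, spec, conditions)
    use <- if (is.null(cond)) conditions else cond
    out <- vector("list", length(use))
    for (ci in seq_along(use)) {
      E <- pv$A + pv$B[[use[ci]]]
      if (unstableE(E)) stop("unstable effective connectivity")
      y <- .dcm_integrate(E, pv$C, U[[use[ci]]], hp@kappa, hp@gamma, hp@tau,
                          hp@alpha, hp@E0, hp@V0 * pv$gain, dt, trTimes)
      if (center) y <- sweep(y, 2, colMeans(y))
      out[[ci]] <- as.numeric(y)
    }
    unlist(out, use.names = FALSE)
  }
}

# central finite-difference Jacobian. With a parameter table the
# per-condition block structure is exploited: a B parameter of one condition
# leaves the other sessions' predictions untouched, so those blocks are
# exactly zero and need no simulation.
jacobianFD <- function(fn, theta, step = 1e-4, f0 = NULL, tab = NULL,
                       conditions = NULL) {
  p <- length(theta)
  if (is.null(f0)) f0 <- fn(theta)
  J <- matrix(0, length(f0), p)
  blockLen <- if (!is.null(conditions)) length(f0) / length(conditions)
  fd <- function(k, cond) {
    tp <- theta; tm <- theta
    tp[k] <- tp[k] + step
    tm[k] <- tm[k] - step
    f0b <- if (is.null(cond)) f0
           else f0[(match(cond, conditions) - 1) * blockLen + seq_len(blockLen)]
    fp <- tryCatch(fn(tp, cond), error = function(e) NULL)
    fm <- tryCatch(fn(tm, cond), error = function(e) NULL)
    if (is.null(fp) && is.null(fm))
      stop("Jacobian undefined: both perturbations unstable")
    if (is.null(fp)) (f0b - fm) / step
    else if (is.null(fm)) (fp - f0b) / step
    else (fp - fm) / (2 * step)
  }
  for (k in seq_len(p)) {
    condk <- if (!is.null(tab) && !is.null(conditions)) tab$cond[k] else NA
    if (!is.na(condk)) {
      rows <- (match(condk, conditions) - 1) * blockLen + seq_len(blockLen)
      J[rows, k] <- fd(k, condk)
    } else {
      J[, k] <- fd(k, NULL)
    }
  }
  J
}

#' Variational free energy of a fitted posterior
#'
#' Evaluates the free-energy bound for given data, model and Gaussian
#' posterior: expected log-likelihood of the (mean-centred) data under the
#' posterior minus the KL divergence from the shrinkage prior. When the
#' posterior equals the prior the complexity term is exactly zero.
#'
#' @param data named list of nVolumes x n matrices, one per condition.
#' @param spec a [DCMModelSpec-class].
#' @param q a [DCMPosterior-class] (its mean, covariance and noise
#'   precision are used).
#' @param priors a [DCMPriors-class].
#' @param design,events,hp,dt forward-model context, as in [invertVL()].
#' @return free energy in nats.
#' @export
freeEnergy <- function(data, spec, q, priors, design, events,
                       hp = hemodynamicParams(length(spec@regions)),
                       dt = 0.1) {
  conds <- names(data)
  tab <- paramTable(spec, conds, priors,
                    estimateGain = isTRUE(q@settings$estimateGain),
                    clampB = isTRUE(q@settings$clampB))
  if (nrow(tab) != length(q@mean))
    stop("posterior dimensions do not match the model's free parameters")
  y <- centredDataVector(data)
  fn <- makePredictor(spec, design, events, hp, conds, dt, tab)
  g <- fn(q@mean)
  J <- jacobianFD(fn, q@mean, f0 = g, tab = tab, conditions = conds)
  freeEnergyCore(y - g, J, q@cov, q@lambda, q@mean, tab$pmean, tab$pvar,
                 length(y))
}

centredDataVector <- function(data) {
  unlist(lapply(data, function(Y)
    as.numeric(scale(Y, center = TRUE, scale = FALSE))), use.names = FALSE)
}

#' Invert a DCM by variational Laplace
#'
#' Fits one candidate model to one subject's per-condition ROI time series.
#' Both sessions are inverted jointly as a single model with one modulatory
#' matrix per condition (default), so the condition difference is carried by
#' B while A captures coupling common to both sessions; a per-session
#' separate mode is available. The optimizer is Gauss-Newton on the
#' conditional mode with Levenberg damping: steps are accepted only if the
#' free energy increases, the noise precision is re-estimated by EM each
#' iteration, and convergence is declared when the free-energy change falls
#' below \code{tol}.
#'
#' @param data named list of nVolumes x n numeric matrices, one per
#'   condition (same region order as \code{spec}); at least 100 volumes.
#' @param spec a [DCMModelSpec-class].
#' @param design a [DesignSpec-class].
#' @param events onset vector or named per-condition list.
#' @param priors a [DCMPriors-class].
#' @param hp haemodynamic parameters (fixed during inversion).
#' @param settings list: \code{maxIter} (default 32), \code{tol} (nats,
#'   default 0.01), \code{dt} (s, 0.1), \code{fdStep} (1e-4),
#'   \code{estimateGain} (FALSE), \code{sessions} ("joint" or "separate"),
#'   \code{multistart} (FALSE; when TRUE, two deterministic starts are run
#'   and the higher-F fit kept), \code{seed} (recorded for provenance; the
#'   optimizer is deterministic).
#' @return a [DCMPosterior-class]; in separate-sessions mode, a named list
#'   of them (one per condition, with B clamped to zero).
#' @export
invertVL <- function(data, spec, design, events, priors = defaultPriors(),
                     hp = hemodynamicParams(length(spec@regions)),
                     settings = list()) {
  s <- utils::modifyList(list(maxIter = 32, tol = 1e-2, dt = 0.1,
                              fdStep = 1e-4, estimateGain = FALSE,
                              sessions = "joint", clampB = FALSE,
                              multistart = FALSE, startOffset = NULL,
                              seed = 1L), settings)
  stopifnot(is.list(data), !is.null(names(data)))
  for (Y in data) {
    if (!all(is.finite(Y))) stop("data must be finite")
    if (nrow(Y) < 100) stop("need at least 100 volumes per session")
    if (nrow(Y) != design@nVolumes)
      stop("design does not match data length")
  }
  if (identical(s$sessions, "separate")) {
    evl <- eventsPerCondition(events, names(data))
    out <- lapply(names(data), function(cond) {
      s2 <- s; s2$sessions <- "joint"; s2$clampB <- TRUE
      invertVL(data[cond], spec, design, evl[cond], priors, hp, s2)
    })
    return(stats::setNames(out, names(data)))
  }
  if (isTRUE(s$multistart)) {
    # two deterministic starts guard against the slow-decay/fast-decay local
    # optima of the self-connections; keep the fit with the higher F
    s1 <- s; s1$multistart <- FALSE
    fits <- lapply(list(c(), c(a_diag = -0.25, c = 0.5)), function(ov) {
      s2 <- s1; s2$startOffset <- ov
      invertVL(data, spec, design, events, priors, hp, s2)
    })
    return(fits[[which.max(vapply(fits, freeEnergyOf, numeric(1)))]])
  }
  conds <- names(data)
  tab <- paramTable(spec, conds, priors, estimateGain = s$estimateGain,
                    clampB = isTRUE(s$clampB))
  p <- nrow(tab)
  mu0 <- tab$pmean; s0 <- tab$pvar
  y <- centredDataVector(data)
  N <- length(y)
  fn <- makePredictor(spec, design, events, hp, conds, s$dt, tab)
  P0 <- diag(1 / s0, p)
  m <- mu0
  if (!is.null(s$startOffset) && length(s$startOffset)) {
    for (cls in names(s$startOffset)) {
      sel <- tab$class == cls
      if (cls == "a_diag") m[sel] <- s$startOffset[[cls]]
      else m[sel] <- m[sel] + s$startOffset[[cls]]
    }
  }
  g <- fn(m)   # prior mean must be simulable; error here is fatal
  e <- y - g
  lambda <- max(1 / stats::var(y), 1e-3)
  J <- jacobianFD(fn, m, step = s$fdStep, f0 = g, tab = tab,
                  conditions = conds)
  JJ <- crossprod(J)
  # coordinate-ascent refresh of the noise precision (Gamma-regularized EM
  # point estimate, maximizing F in lambda) and the posterior covariance
  refresh <- function(e, JJ, lambda) {
    S <- solve(lambda * JJ + P0)
    ess <- sum(e^2) + sum(JJ * S)
    lambda <- (N + 2 * priors@noiseShape - 2) / (ess + 2 * priors@noiseRate)
    lambda <- max(lambda, 1e-8)
    list(S = solve(lambda * JJ + P0), lambda = lambda)
  }
  up <- refresh(e, JJ, lambda)
  S <- up$S; lambda <- up$lambda
  Fcur <- freeEnergyCore(e, J, S, lambda, m, mu0, s0, N)
  nu <- 1
  Ftrace <- Fcur
  converged <- FALSE
  iters <- 0
  for (iter in seq_len(s$maxIter)) {
    iters <- iter
    # damped Gauss-Newton step; a candidate is accepted only if the fully
    # recomputed free energy (with its own Jacobian) improves, so the
    # recorded trace is non-decreasing by construction
    grad <- lambda * crossprod(J, e) - P0 %*% (m - mu0)
    accepted <- FALSE
    for (try in 1:8) {
      H <- lambda * JJ + P0 + diag(nu, p)
      dm <- drop(solve(H, grad))
      mc <- m + dm
      gc <- tryCatch(fn(mc), error = function(e) NULL)
      if (!is.null(gc)) {
        ec <- y - gc
        Jc <- jacobianFD(fn, mc, step = s$fdStep, f0 = gc, tab = tab,
                         conditions = conds)
        JJc <- crossprod(Jc)
        upc <- refresh(ec, JJc, lambda)
        Fc <- freeEnergyCore(ec, Jc, upc$S, upc$lambda, mc, mu0, s0, N)
        if (Fc > Fcur) {
          m <- mc; g <- gc; e <- ec; J <- Jc; JJ <- JJc
          S <- upc$S; lambda <- upc$lambda
          dF <- Fc - Fcur
          Fcur <- Fc
          Ftrace <- c(Ftrace, Fcur)
          nu <- max(nu / 2, 1e-6)
          accepted <- TRUE
          break
        }
      }
      nu <- nu * 10
    }
    if (!accepted) { converged <- TRUE; break }
    if (dF < s$tol) { converged <- TRUE; break }
  }
  S <- (S + t(S)) / 2
  Ffin <- Fcur
  names(m) <- tab$name
  dimnames(S) <- list(tab$name, tab$name)
  new("DCMPosterior", mean = m, cov = S, lambda = lambda,
      freeEnergy = Ffin, spec = spec, converged = converged,
      diagnostics = list(
        Ftrace = Ftrace, iterations = iters,
        explainedVariance = 1 - sum(e^2) / sum(y^2),
        paramTable = tab),
      settings = s)
}

#' Map a posterior to condition-specific effective connection values
#'
#' Posterior means of A + B_cond entries (and C), the identified quantities
#' a two-session joint inversion reports per condition.
#'
#' @param q a [DCMPosterior-class].
#' @return named list per condition of n x n effective matrices, plus
#'   \code{C}.
#' @export
posteriorEffective <- function(q) {
  tab <- q@diagnostics$paramTable
  conds <- unique(stats::na.omit(tab$cond))
  spec <- q@spec
  pv <- paramsFromVector(q@mean, tab, spec, conds)
  eff <- lapply(conds, function(cond) pv$A + pv$B[[cond]])
  names(eff) <- conds
  c(eff, list(C = pv$C))
}
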