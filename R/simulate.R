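#' Step-averaged driving-input regressor
#'
#' Driving inputs are stick functions at picture onsets: unit-mass pulses of
#' fixed width \code{width} (so C carries Hz units and the injected mass per
#' event is independent of the integration step). The pulse train is averaged
#' over each integration step, making the integral of the regressor exactly
#' the event count for any dt.
#'
#' @param onsets event onset times (s).
#' @param dt integration step (s).
#' @param nSteps number of integration steps.
#' @param width stick width (s); fixed, not tied to dt.
#' @return numeric vector of length nSteps (step-averaged input).
#' @export
inputRegressor <- function(onsets, dt, nSteps, width = 0.1) {
  u <- numeric(nSteps)
  if (!length(onsets)) return(u)
  if (any(onsets < 0)) stop("onsets must be non-negative")
  for (on in onsets) {
    k0 <- floor(on / dt) + 1
    k1 <- min(ceiling((on + width) / dt), nSteps)
    if (k0 > nSteps) next
    for (k in k0:k1) {
      lo <- (k - 1) * dt; hi <- k * dt
      ov <- max(0, min(hi, on + width) - max(lo, on))
      u[k] <- u[k] + ov / (width * dt)
    }
  }
  u
}

# shared stability gate for forward simulation
assertStable <- function(E) {
  re <- Re(eigen(E, only.values = TRUE)$values)
  if (any(re >= 0))
    stop("effective connectivity is unstable (eigenvalue with non-negative ",
         "real part); simulation refused")
  invisible(max(re))
}

#' Simulate ROI BOLD time series for one session
#'
#' Runs the bilinear neural dynamics under one condition's effective
#' coupling, pushes the neuronal states through the balloon-Windkessel
#' haemodynamics, reads out percent BOLD change at the TR sampling grid, and
#' optionally adds white Gaussian observation noise. Integration is
#' fixed-step RK4 at \code{dt}; outputs are interpolated from the fine grid
#' to volume times.
#'
#' @param params a [ConnectivityParams-class].
#' @param hp a [HemodynamicParams-class] (defaults to the canonical set).
#' @param design a [DesignSpec-class]; supplies TR and nVolumes.
#' @param onsets event onset times (s) for the driving input, within the
#'   scanned interval.
#' @param cond condition label selecting the modulatory matrix.
#' @param spec optional [DCMModelSpec-class]; if given, params are checked
#'   against its masks.
#' @param dt integration step (s), must be positive and at most TR.
#' @param noiseSd observation noise SD (percent signal); 0 = deterministic.
#' @param seed RNG seed for the noise (ignored when noiseSd = 0).
#' @return nVolumes x n matrix of percent BOLD change, columns named by
#'   region. Volume k is sampled at t = (k-1) TR.
#' @examples
#' p <- connectivityParams(
#'   A = matrix(c(-0.5, -0.2, 0.4, -0.4), 2, 2),
#'   B = list(sham = matrix(0, 2, 2)), C = c(0.5, 0),
#'   regions = c("IFS", "VPM"))
#' d <- designSpec(nVolumes = 20)
#' y <- simulateBold(p, design = d, onsets = c(5, 8.92), cond = "sham")
#' @export
simulateBold <- function(params, hp = hemodynamicParams(nRegions(params)),
                         design = designSpec(), onsets, cond,
                         spec = NULL, dt = 0.1, noiseSd = 0, seed = NULL) {
  stopifnot(is(params, "ConnectivityParams"), is(hp, "HemodynamicParams"),
            is(design, "DesignSpec"))
  if (dt <= 0 || dt > design@TR) stop("dt must lie in (0, TR]")
  if (!is.null(spec)) assertRespectsSpec(params, spec)
  E <- effectiveConnectivity(params, cond)
  assertStable(E)
  n <- nRegions(params)
  duration <- (design@nVolumes - 1) * design@TR
  if (length(onsets) && max(onsets) > design@nVolumes * design@TR)
    stop("design events extend beyond the scanned interval")
  nSteps <- ceiling(duration / dt + 1e-9)
  m <- ncol(params@C)
  U <- matrix(0, nSteps, m)
  for (k in seq_len(m)) U[, k] <- inputRegressor(onsets, dt, nSteps)
  tr_times <- (seq_len(design@nVolumes) - 1) * design@TR
  y <- .dcm_integrate(E, params@C, U, hp@kappa, hp@gamma, hp@tau, hp@alpha,
                      hp@E0, hp@V0 * hp@gain, dt, tr_times)
  colnames(y) <- params@regions
  if (noiseSd > 0) {
    y <- y + withSeed(seed, matrix(stats::rnorm(length(y), 0, noiseSd),
                                   nrow(y), ncol(y)))
  }
  y
}

# check that parameter values are zero wherever the model's masks forbid them
assertRespectsSpec <- function(params, spec) {
  offA <- params@A; diag(offA) <- 0
  if (any(offA[!spec@aMask] != 0))
    stop("params have non-zero A entries outside the model's aMask")
  for (cond in names(params@B))
    if (any(params@B[[cond]][!spec@bMask] != 0))
      stop("params have non-zero B entries outside the model's bMask in ", cond)
  if (any(params@C[!spec@cMask] != 0))
    stop("params have non-zero C entries outside the model's cMask")
  invisible(TRUE)
}
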