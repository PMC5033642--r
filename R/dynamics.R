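#' Bilinear neural state derivative
#'
#' Evaluates \eqn{\dot x = (A + B_{cond}) x + C u} for one condition of a
#' bilinear DCM. The condition selects which modulatory matrix is active;
#' the driving input u is condition-independent.
#'
#' @param x neuronal state vector (one entry per region, arbitrary units).
#' @param u driving input vector (one entry per input column of C).
#' @param cond condition label, must name an entry of \code{params@B}.
#' @param params a [ConnectivityParams-class].
#' @return dx/dt in Hz (numeric vector, one entry per region).
#' @examples
#' p <- connectivityParams(
#'   A = matrix(c(-0.5, -0.3, 0.9, -0.25), 2, 2),
#'   B = list(sham = matrix(0, 2, 2)), C = c(0, 0))
#' neuralDerivative(c(1, 0), 0, "sham", p)  # first column of A
#' @export
neuralDerivative <- function(x, u, cond, params) {
  stopifnot(is(params, "ConnectivityParams"))
  n <- nRegions(params)
  if (length(x) != n)
    stop("state x must have one entry per region")
  if (!cond %in% names(params@B))
    stop("unknown condition label: ", cond)
  if (length(u) != ncol(params@C))
    stop("input u must have one entry per column of C")
  drop((params@A + params@B[[cond]]) %*% x + params@C %*% u)
}

#' Condition-specific effective connectivity
#'
#' The effective coupling under one condition, A + B_cond. The study reports
#' one connection value per condition; this composition is how those values
#' are formed from the intrinsic and modulatory matrices.
#'
#' @param params a [ConnectivityParams-class].
#' @param cond condition label.
#' @return n x n effective coupling matrix (Hz) with strictly negative
#'   diagonal.
#' @export
setGeneric("effectiveConnectivity", function(params, cond)
  standardGeneric("effectiveConnectivity"))

#' @rdname effectiveConnectivity
#' @export
setMethod("effectiveConnectivity", "ConnectivityParams", function(params, cond) {
  if (!cond %in% names(params@B))
    stop("unknown condition label: ", cond)
  E <- params@A + params@B[[cond]]
  if (any(diag(E) >= 0))
    stop("effective self-connections must be negative (stability violation)")
  E
})

#' Half-life of a self-connection
#'
#' A negative self-connection a (Hz) makes regional activity decay as
#' exp(a t); the half-life ln(0.5)/a is the time for activity to halve.
#' Weaker (less negative) self-connections mean more persistent regional
#' activity.
#'
#' @param a self-connection value in Hz; must be negative.
#' @return half-life in seconds.
#' @examples
#' halfLife(-0.26)  # 2.67 s
#' halfLife(-0.09)  # 7.70 s
#' @export
halfLife <- function(a) {
  if (any(!is.finite(a)) || any(a >= 0))
    stop("self-connection must be negative for a decay half-life")
  log(0.5) / a
}

#' Neural trajectory by fixed-step RK4 (no haemodynamics)
#'
#' Integrates the bilinear neural dynamics alone from an initial state under
#' a constant input. Used to check the integrator against the
#' matrix-exponential closed form of the linear regime.
#'
#' @param params a [ConnectivityParams-class].
#' @param cond condition label.
#' @param x0 initial neuronal state.
#' @param times sample times (s), non-negative, increasing.
#' @param u constant driving input (default 0).
#' @param dt integration step (s).
#' @return length(times) x n matrix of neuronal states.
#' @export
neuralTrajectory <- function(params, cond, x0, times, u = 0, dt = 0.01) {
  E <- effectiveConnectivity(params, cond)
  n <- nrow(E)
  if (length(u) != ncol(params@C)) u <- rep_len(u, ncol(params@C))
  cu <- drop(params@C %*% u)
  f <- function(x) drop(E %*% x) + cu
  tmax <- max(times)
  nsteps <- ceiling(tmax / dt + 1e-9)
  out <- matrix(NA_real_, length(times), n)
  x <- as.numeric(x0)
  grid <- numeric(0)
  xs <- matrix(NA_real_, nsteps + 1, n)
  xs[1, ] <- x
  for (k in seq_len(nsteps)) {
    k1 <- f(x); k2 <- f(x + dt / 2 * k1)
    k3 <- f(x + dt / 2 * k2); k4 <- f(x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    xs[k + 1, ] <- x
  }
  tg <- (0:nsteps) * dt
  for (i in seq_along(times)) {
    j <- findInterval(times[i], tg, all.inside = TRUE)
    w <- (times[i] - tg[j]) / dt
    out[i, ] <- (1 - w) * xs[j, ] + w * xs[j + 1, ]
  }
  out
}
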