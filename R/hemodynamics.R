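#' Balloon-Windkessel state derivative (single region)
#'
#' The haemodynamic cascade linking neuronal activity z to the BOLD signal:
#' neuronal activity drives a vasodilatory signal s, which drives blood
#' inflow f; volume v and deoxyhaemoglobin q follow Windkessel dynamics with
#' transit time tau and outflow v^(1/alpha). At rest (z = 0, s = 0,
#' f = v = q = 1) all derivatives vanish.
#'
#' @param h named numeric state vector \code{c(s=, f=, v=, q=)}.
#' @param z neuronal activity (scalar).
#' @param hp a [HemodynamicParams-class]; the first region's values are used.
#' @param region index of the region whose parameters apply.
#' @return named derivative vector (ds, df, dv, dq).
#' @export
hemoDerivative <- function(h, z, hp, region = 1) {
  stopifnot(is(hp, "HemodynamicParams"))
  s <- h[["s"]]; f <- h[["f"]]; v <- h[["v"]]; q <- h[["q"]]
  if (f <= 0 || v <= 0 || q <= 0)
    stop("inflow, volume and deoxyhaemoglobin must be strictly positive")
  i <- region
  fout <- v^(1 / hp@alpha[i])
  Ef <- 1 - (1 - hp@E0[i])^(1 / f)
  c(s = z - hp@kappa[i] * s - hp@gamma[i] * (f - 1),
    f = s,
    v = (f - fout) / hp@tau[i],
    q = (f * Ef / hp@E0[i] - fout * q / v) / hp@tau[i])
}

#' BOLD observation equation (single region)
#'
#' Percent BOLD signal change as a weighted sum of deoxyhaemoglobin and
#' volume deviations from rest:
#' \eqn{y = 100 V_0 (k_1(1-q) + k_2(1-q/v) + k_3(1-v))} with
#' \eqn{k_1 = 7E_0}, \eqn{k_2 = 2}, \eqn{k_3 = 2E_0 - 0.2}. Zero at the
#' resting point v = q = 1; decreasing q at fixed v increases the signal.
#'
#' @param h named state vector with at least \code{v} and \code{q}.
#' @param hp a [HemodynamicParams-class].
#' @param region region index for parameter lookup.
#' @return percent BOLD signal change (scalar).
#' @export
boldObservation <- function(h, hp, region = 1) {
  stopifnot(is(hp, "HemodynamicParams"))
  v <- h[["v"]]; q <- h[["q"]]
  if (v <= 0 || q <= 0) stop("v and q must be strictly positive")
  i <- region
  k1 <- 7 * hp@E0[i]; k2 <- 2; k3 <- 2 * hp@E0[i] - 0.2
  100 * hp@V0[i] * hp@gain[i] *
    (k1 * (1 - q) + k2 * (1 - q / v) + k3 * (1 - v))
}
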