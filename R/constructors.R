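#' Create connectivity parameters
#'
#' @param A n x n intrinsic coupling matrix (Hz), strictly negative diagonal.
#' @param B named list of n x n modulatory matrices, one per condition; a
#'   single matrix is accepted and wrapped as condition \code{"on"}.
#' @param C n x m driving-input gain matrix (a vector is treated as one
#'   column).
#' @param regions region labels; defaults to rownames of A or R1..Rn.
#' @return A [ConnectivityParams-class] object.
#' @examples
#' p <- connectivityParams(
#'   A = matrix(c(-0.5, -0.1, 0.9, -0.25), 2, 2),
#'   B = list(anodal = matrix(0, 2, 2), sham = matrix(0, 2, 2)),
#'   C = c(0, 0.5), regions = c("IFS", "VPM"))
#' effectiveConnectivity(p, "anodal")
#' @export
connectivityParams <- function(A, B, C, regions = NULL) {
  if (is.matrix(B)) B <- list(on = B)
  if (!is.matrix(C)) C <- matrix(C, ncol = 1)
  if (is.null(regions)) {
    regions <- rownames(A)
    if (is.null(regions)) regions <- paste0("R", seq_len(nrow(A)))
  }
  dimnames(A) <- list(regions, regions)
  B <- lapply(B, function(m) { dimnames(m) <- list(regions, regions); m })
  rownames(C) <- regions
  # Class is named exactly so the slot named C cannot partially match it
  new(Class = "ConnectivityParams", A = A, B = B, C = C, regions = regions)
}

#' Canonical haemodynamic parameters
#'
#' Returns the canonical balloon-Windkessel parameter set (signal decay
#' kappa = 0.64 1/s, autoregulation gamma = 0.32 1/s, transit time
#' tau = 2 s, stiffness alpha = 0.32, resting oxygen extraction E0 = 0.4,
#' resting venous volume fraction V0 = 0.04), replicated per region. These
#' are treated as fixed constants of the forward model; a per-region
#' observation gain can be estimated instead (see [invertVL()]).
#'
#' @param nRegions number of regions.
#' @param kappa,gamma,tau,alpha,E0,V0,gain overrides, recycled per region.
#' @return A [HemodynamicParams-class] object.
#' @export
hemodynamicParams <- function(nRegions = 2, kappa = 0.64, gamma = 0.32,
                              tau = 2, alpha = 0.32, E0 = 0.4, V0 = 0.04,
                              gain = 1) {
  r <- function(x) rep_len(x, nRegions)
  new("HemodynamicParams", kappa = r(kappa), gamma = r(gamma), tau = r(tau),
      alpha = r(alpha), E0 = r(E0), V0 = r(V0), gain = r(gain))
}

#' Session design specification
#'
#' Constructor for [DesignSpec-class]; defaults encode the emulated study
#' design (107 trials in blocks of 6, 7 s rests, ITI 3.92 s, TR 3.36 s,
#' 344 volumes, anodal and sham sessions).
#'
#' @param ... slot overrides, e.g. \code{nVolumes = 100}.
#' @return A [DesignSpec-class] object.
#' @export
designSpec <- function(...) new("DesignSpec", ...)

#' Number of regions
#' @param x an object with regions.
#' @return integer count of regions.
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' @rdname nRegions
#' @export
setMethod("nRegions", "ConnectivityParams", function(x) nrow(x@A))

#' @rdname nRegions
#' @export
setMethod("nRegions", "DCMModelSpec", function(x) length(x@regions))

#' Region labels
#' @param x an object with regions.
#' @return character vector of region labels.
#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))

#' @rdname regionNames
#' @export
setMethod("regionNames", "ConnectivityParams", function(x) x@regions)

#' @rdname regionNames
#' @export
setMethod("regionNames", "DCMModelSpec", function(x) x@regions)

#' Free energy of a fitted model
#' @param x a [DCMPosterior-class].
#' @return free energy in nats.
#' @export
setGeneric("freeEnergyOf", function(x) standardGeneric("freeEnergyOf"))

#' @rdname freeEnergyOf
#' @export
setMethod("freeEnergyOf", "DCMPosterior", function(x) x@freeEnergy)

#' Posterior mean and covariance accessors
#' @param x a [DCMPosterior-class].
#' @return named mean vector / covariance matrix.
#' @export
setGeneric("posteriorMean", function(x) standardGeneric("posteriorMean"))

#' @rdname posteriorMean
#' @export
setMethod("posteriorMean", "DCMPosterior", function(x) x@mean)

#' @rdname posteriorMean
#' @export
setGeneric("posteriorCov", function(x) standardGeneric("posteriorCov"))

#' @rdname posteriorMean
#' @export
setMethod("posteriorCov", "DCMPosterior", function(x) x@cov)

#' BMA sample accessor
#'
#' @param x a [BMAResult-class].
#' @param connection connection label, e.g. \code{"IFS->VPM"}; omit for all.
#' @param condition condition label; omit for all.
#' @return numeric vector of samples, or the full array slice.
#' @export
setGeneric("connectionSamples",
           function(x, connection = NULL, condition = NULL)
             standardGeneric("connectionSamples"))

#' @rdname connectionSamples
#' @export
setMethod("connectionSamples", "BMAResult",
  function(x, connection = NULL, condition = NULL) {
    s <- x@samples
    if (!is.null(connection)) {
      if (!connection %in% dimnames(s)[[2]])
        stop("unknown connection: ", connection)
      s <- s[, connection, , drop = FALSE]
    }
    if (!is.null(condition)) {
      if (!condition %in% dimnames(s)[[3]])
        stop("unknown condition: ", condition)
      s <- s[, , condition, drop = FALSE]
    }
    drop(s)
  })

setMethod("show", "ConnectivityParams", function(object) {
  cat("ConnectivityParams over", paste(object@regions, collapse = ", "), "\n")
  cat("A (intrinsic, Hz):\n"); print(round(object@A, 3))
  for (cond in names(object@B)) {
    cat(sprintf("B[%s] (modulatory, Hz):\n", cond))
    print(round(object@B[[cond]], 3))
  }
  cat("C (driving gains):\n"); print(round(object@C, 3))
})

setMethod("show", "DCMModelSpec", function(object) {
  cat(sprintf("DCMModelSpec '%s' (%s)\n", object@label,
              paste(object@regions, collapse = ", ")))
  mod <- which(object@bMask & upper.tri(object@bMask) |
               object@bMask & lower.tri(object@bMask), arr.ind = TRUE)
  lab <- apply(mod, 1, function(ij)
    paste0(object@regions[ij[2]], "->", object@regions[ij[1]]))
  cat("  modulable between-region connections:",
      if (length(lab)) paste(lab, collapse = ", ") else "none", "\n")
  cat("  driving input to:",
      paste(object@regions[apply(object@cMask, 2, which)], collapse = ", "),
      "\n")
})

setMethod("show", "DCMPosterior", function(object) {
  cat(sprintf("DCMPosterior for model '%s': %d free parameters\n",
              object@spec@label, length(object@mean)))
  cat(sprintf("  F = %.2f nats, converged: %s, explained variance: %.1f%%\n",
              object@freeEnergy, object@converged,
              100 * object@diagnostics$explainedVariance))
})

setMethod("show", "BMAResult", function(object) {
  d <- dim(object@samples)
  cat(sprintf("BMAResult: %d samples x %d connections x %d conditions\n",
              d[1], d[2], d[3]))
  m <- apply(object@samples, c(2, 3), mean)
  cat("posterior mean effective connection values (Hz):\n")
  print(round(m, 3))
})

setMethod("show", "DesignSpec", function(object) {
  cat(sprintf(
    "DesignSpec: %d trials (blocks of %d, %.1f s rests, ITI %.2f s),\n",
    object@nTrials, object@blockSize, object@restDur, object@iti))
  cat(sprintf("  TR %.2f s, %d volumes, conditions: %s\n", object@TR,
              object@nVolumes, paste(object@conditions, collapse = ", ")))
})
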