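#' @import methods
NULL

#' Connectivity parameters of a bilinear two-region DCM
#'
#' Numeric values of the bilinear neural state equation
#' \eqn{\dot x = (A + B_{cond}) x + C u}: \code{A} holds the intrinsic
#' coupling (Hz), \code{B} one modulatory matrix per experimental condition
#' (Hz), and \code{C} the driving-input gains. Rows index the target region,
#' columns the source (\code{A[i, j]} couples region j to region i).
#' Self-connections (the diagonal of A) are inhibitory by construction and
#' must stay negative together with any condition modulation, so that each
#' region's activity decays.
#'
#' @slot A n x n intrinsic coupling matrix (Hz); strictly negative diagonal.
#' @slot B named list, one n x n modulatory matrix per condition (Hz).
#' @slot C n x m driving-input gain matrix (Hz per unit input).
#' @slot regions character vector of region labels, ordered as in A.
#'
#' @seealso [connectivityParams()], [effectiveConnectivity()], [halfLife()]
#' @export
setClass("ConnectivityParams",
  representation(A = "matrix", B = "list", C = "matrix",
                 regions = "character"),
  validity = function(object) {
    msg <- character()
    n <- nrow(object@A)
    if (ncol(object@A) != n)
      msg <- c(msg, "A must be square")
    if (!all(is.finite(object@A)))
      msg <- c(msg, "A entries must be finite")
    if (any(diag(object@A) >= 0))
      msg <- c(msg, "diagonal of A must be strictly negative (self-inhibition)")
    if (length(object@regions) != n || anyDuplicated(object@regions))
      msg <- c(msg, "regions must be unique labels, one per row of A")
    if (nrow(object@C) != n)
      msg <- c(msg, "C must have one row per region")
    if (is.null(names(object@B)) || anyDuplicated(names(object@B)))
      msg <- c(msg, "B must be a named list with unique condition labels")
    for (cond in names(object@B)) {
      Bc <- object@B[[cond]]
      if (!is.matrix(Bc) || any(dim(Bc) != n)) {
        msg <- c(msg, sprintf("B[['%s']] must be %d x %d", cond, n, n))
        next
      }
      if (any(diag(object@A) + diag(Bc) >= 0))
        msg <- c(msg, sprintf(
          "effective self-connection A_ii + B_ii must stay negative in '%s'",
          cond))
    }
    if (length(msg)) msg else TRUE
  })

#' Balloon-Windkessel haemodynamic parameters
#'
#' Region-wise parameters of the haemodynamic forward model that maps
#' neuronal activity to the BOLD signal: vasodilatory signal decay rate
#' \code{kappa} (1/s), flow autoregulation rate \code{gamma} (1/s), mean
#' vascular transit time \code{tau} (s), Grubb stiffness exponent
#' \code{alpha}, resting oxygen extraction fraction \code{E0} and resting
#' venous blood volume fraction \code{V0}. Defaults are the canonical
#' literature values (see [hemodynamicParams()]); they are held fixed during
#' inversion unless a per-region observation gain is estimated.
#'
#' @slot kappa,gamma,tau,alpha,E0,V0 numeric, one value per region.
#' @slot gain per-region observation gain (dimensionless, 1 at rest).
#' @export
setClass("HemodynamicParams",
  representation(kappa = "numeric", gamma = "numeric", tau = "numeric",
                 alpha = "numeric", E0 = "numeric", V0 = "numeric",
                 gain = "numeric"),
  validity = function(object) {
    msg <- character()
    len <- length(object@kappa)
    slots <- c("kappa", "gamma", "tau", "alpha", "E0", "V0", "gain")
    for (s in slots) {
      v <- slot(object, s)
      if (length(v) != len) msg <- c(msg, "all parameter slots must have equal length")
      if (any(v <= 0)) msg <- c(msg, sprintf("%s must be strictly positive", s))
    }
    if (any(object@E0 >= 1)) msg <- c(msg, "E0 must lie in (0, 1)")
    if (any(object@alpha >= 1)) msg <- c(msg, "alpha must lie in (0, 1)")
    if (length(msg)) msg else TRUE
  })

#' Structural specification of one candidate DCM
#'
#' Boolean masks stating which connections exist (\code{aMask}), which are
#' modulable by the experimental condition (\code{bMask}) and which region
#' receives the driving input (\code{cMask}). In the crossed model space used
#' here the A matrix is fully connected in every model, self-connections are
#' modulable in every model, and exactly one region receives the driving
#' input.
#'
#' @slot regions character vector of region labels.
#' @slot aMask,bMask n x n logical matrices.
#' @slot cMask n x m logical matrix (m = number of driving inputs).
#' @slot label character identifier encoding pattern and input site.
#' @seealso [buildModelSpace()], [validateModel()]
#' @export
setClass("DCMModelSpec",
  representation(regions = "character", aMask = "matrix", bMask = "matrix",
                 cMask = "matrix", label = "character"),
  validity = function(object) {
    v <- validateModel(object)
    if (length(v)) v else TRUE
  })

#' Timing and structure of one scanning session
#'
#' Event and acquisition timing of a naming session: trials are presented in
#' short blocks separated by fixation-only rests, each picture preceded by a
#' fixation cross, while volumes are acquired continuously. Defaults encode
#' the study design this package emulates: 107 naming events in blocks of 6
#' with 7 s rests, inter-trial interval 3.92 s, fixation lead 1 s, picture
#' duration 2.5 s, TR 3.36 s, 344 volumes, and the two stimulation
#' conditions (anodal, sham), one session each.
#'
#' @slot nTrials number of naming events per session.
#' @slot blockSize trials per block.
#' @slot restDur inter-block rest (s).
#' @slot iti inter-trial interval within a block (s).
#' @slot fixLead fixation-cross lead time before each picture (s).
#' @slot picDur picture display duration (s).
#' @slot TR repetition time (s).
#' @slot nVolumes volumes of interest per session.
#' @slot conditions condition labels, one session per condition.
#' @export
setClass("DesignSpec",
  representation(nTrials = "numeric", blockSize = "numeric",
                 restDur = "numeric", iti = "numeric", fixLead = "numeric",
                 picDur = "numeric", TR = "numeric", nVolumes = "numeric",
                 conditions = "character"),
  prototype(nTrials = 107, blockSize = 6, restDur = 7, iti = 3.92,
            fixLead = 1, picDur = 2.5, TR = 3.36, nVolumes = 344,
            conditions = c("anodal", "sham")),
  validity = function(object) {
    msg <- character()
    num <- c("nTrials", "blockSize", "restDur", "iti", "fixLead", "picDur",
             "TR", "nVolumes")
    for (s in num)
      if (length(slot(object, s)) != 1 || slot(object, s) <= 0)
        msg <- c(msg, sprintf("%s must be a single positive number", s))
    if (length(object@conditions) < 1 || anyDuplicated(object@conditions))
      msg <- c(msg, "conditions must be non-empty and unique")
    if (!length(msg)) {
      span <- designSpan(object)
      if (span > object@nVolumes * object@TR)
        msg <- c(msg, sprintf(
          "event span (%.1f s) exceeds scan duration (%.1f s)",
          span, object@nVolumes * object@TR))
    }
    if (length(msg)) msg else TRUE
  })

#' Shrinkage priors for DCM inversion
#'
#' Gaussian prior means and variances per parameter class, plus the Gamma
#' hyperprior on the observation-noise precision. Masked-out parameters are
#' clamped (zero prior variance) by exclusion from the free-parameter vector.
#'
#' @slot mean,var named numeric vectors over parameter classes
#'   \code{a_off}, \code{a_diag}, \code{b}, \code{c}, \code{gain}.
#' @slot noiseShape,noiseRate Gamma hyperprior on the noise precision.
#' @seealso [defaultPriors()]
#' @export
setClass("DCMPriors",
  representation(mean = "numeric", var = "numeric",
                 noiseShape = "numeric", noiseRate = "numeric"),
  validity = function(object) {
    msg <- character()
    cls <- c("a_off", "a_diag", "b", "c", "gain")
    if (!all(cls %in% names(object@mean)) || !all(cls %in% names(object@var)))
      msg <- c(msg, "mean and var must name classes a_off, a_diag, b, c, gain")
    if (any(object@var <= 0)) msg <- c(msg, "prior variances must be positive")
    if (object@noiseShape <= 0 || object@noiseRate <= 0)
      msg <- c(msg, "noise hyperprior parameters must be positive")
    if (length(msg)) msg else TRUE
  })

#' Posterior over DCM parameters from variational Laplace
#'
#' Gaussian posterior over the free parameters of one model fitted to one
#' subject's two-session ROI data, with the free-energy approximation to the
#' log model evidence used for model comparison.
#'
#' @slot mean named posterior mean over free parameters.
#' @slot cov posterior covariance (symmetric positive semi-definite).
#' @slot lambda observation-noise precision (EM point estimate).
#' @slot freeEnergy variational free energy (nats).
#' @slot spec the [DCMModelSpec-class] that was fitted.
#' @slot converged logical convergence flag.
#' @slot diagnostics list: free-energy trace, iterations, explained variance.
#' @slot settings inversion settings used (for provenance).
#' @export
setClass("DCMPosterior",
  representation(mean = "numeric", cov = "matrix", lambda = "numeric",
                 freeEnergy = "numeric", spec = "DCMModelSpec",
                 converged = "logical", diagnostics = "list",
                 settings = "list"),
  validity = function(object) {
    msg <- character()
    p <- length(object@mean)
    if (any(dim(object@cov) != p))
      msg <- c(msg, "cov must be p x p for p free parameters")
    else {
      if (max(abs(object@cov - t(object@cov))) > 1e-8)
        msg <- c(msg, "cov must be symmetric")
      ev <- eigen(object@cov, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-8 * max(abs(ev), 1))
        msg <- c(msg, "cov must be positive semi-definite")
    }
    if (!is.finite(object@freeEnergy))
      msg <- c(msg, "free energy must be finite")
    if (length(msg)) msg else TRUE
  })

#' Bayesian model averaging result
#'
#' Posterior samples of per-connection, per-condition effective connection
#' values, built by sampling subjects uniformly, models according to each
#' subject's posterior model probability, and parameters from the drawn
#' model's Gaussian posterior. A connection absent from the drawn model
#' contributes exactly zero.
#'
#' @slot samples numeric array (nSamples x connections x conditions) with
#'   dimnames.
#' @slot seed sampler seed.
#' @slot weights subjects x models matrix of posterior model probabilities
#'   used by the sampler.
#' @export
setClass("BMAResult",
  representation(samples = "array", seed = "integer", weights = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@samples)) != 3)
      msg <- c(msg, "samples must be a 3-d array (samples x connections x conditions)")
    if (is.null(dimnames(object@samples)[[2]]) ||
        is.null(dimnames(object@samples)[[3]]))
      msg <- c(msg, "samples must carry connection and condition dimnames")
    if (any(!is.finite(object@samples)))
      msg <- c(msg, "samples must be finite")
    if (length(msg)) msg else TRUE
  })

#' Population specification for a synthetic cohort
#'
#' Defines the population from which synthetic subjects are drawn: the
#' per-condition mean effective connectivity (the condition effects reported
#' for the study are the defaults: the IFS-to-VPM backward connection is more
#' negative under anodal tDCS, the VPM self-connection less negative),
#' between-subject variability, the driving-input gain, the target
#' signal-to-noise ratio of the BOLD series, the reaction-time model, and
#' the planted correlation \code{rho} between the forward-connection change
#' and naming facilitation.
#'
#' @slot nSubjects number of subjects (default 10).
#' @slot effMeans named list per condition of n x n population mean effective
#'   connectivity (Hz).
#' @slot betweenSD between-subject SD of each between-region connection and
#'   of its condition difference (Hz); additive Gaussian.
#' @slot selfLogSD,selfCondLogSD log-scale SDs of the multiplicative
#'   (log-normal, mean-corrected) between-subject and condition-specific
#'   variability of self-connections.
#' @slot cMean,cSD population mean and SD of the driving-input gain.
#' @slot condNoiseMask n x n logical; which between-region couplings
#'   receive subject-level condition-difference noise (all, by default).
#'   A recovery harness generating from an architecture without a given
#'   modulation sets that entry FALSE so the generative process matches the
#'   architecture exactly.
#' @slot inputSite region receiving the driving input.
#' @slot snr target ratio of signal SD to noise SD in simulated BOLD.
#' @slot rho planted correlation between forward-connection change and
#'   percentage RT facilitation.
#' @slot rt named list of RT-model constants (ms): shamMean, subjectSD,
#'   pctMean, pctSD, trialSD, itemSD, minRT, accuracy, voiceKeyOK.
#' @slot regions region labels.
#' @slot seed master seed; all cohort randomness derives from it.
#' @seealso [cohortSpec()], [simulateCohort()]
#' @export
setClass("CohortSpec",
  representation(nSubjects = "numeric", effMeans = "list",
                 betweenSD = "numeric", selfLogSD = "numeric",
                 selfCondLogSD = "numeric",
                 cMean = "numeric", cSD = "numeric",
                 condNoiseMask = "matrix",
                 inputSite = "character", snr = "numeric", rho = "numeric",
                 rt = "list", regions = "character", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nSubjects < 1) msg <- c(msg, "nSubjects must be >= 1")
    if (object@betweenSD < 0 || object@cSD < 0 ||
        object@selfLogSD < 0 || object@selfCondLogSD < 0)
      msg <- c(msg, "SDs must be non-negative")
    if (abs(object@rho) > 1) msg <- c(msg, "rho must lie in [-1, 1]")
    if (object@snr <= 0) msg <- c(msg, "snr must be positive")
    if (!object@inputSite %in% object@regions)
      msg <- c(msg, "inputSite must be one of the regions")
    n <- length(object@regions)
    for (cond in names(object@effMeans)) {
      M <- object@effMeans[[cond]]
      if (!is.matrix(M) || any(dim(M) != n))
        msg <- c(msg, sprintf("effMeans[['%s']] must be %d x %d", cond, n, n))
      else if (any(diag(M) >= 0))
        msg <- c(msg, sprintf("effMeans[['%s']] diagonal must be negative", cond))
    }
    if (length(msg)) msg else TRUE
  })
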