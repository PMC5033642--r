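#' Default shrinkage priors
#'
#' Weakly informative Gaussian shrinkage priors per parameter class,
#' consistent with reported connection magnitudes (|values| of order 1 Hz
#' or less): A off-diagonal N(0, 0.25); A diagonal N(-0.5, 0.0625), kept
#' negative by the stability gate of the forward model; B entries
#' N(0, 0.25); C entries N(0, 1); per-region observation gain N(1, 0.04)
#' when estimated. The observation-noise precision carries a weak Gamma
#' hyperprior used to regularize its EM update.
#'
#' @param ... overrides, e.g. \code{bVar = 0.5}.
#' @return a [DCMPriors-class].
#' @export
defaultPriors <- function(...) {
  ov <- list(...)
  mean <- c(a_off = 0, a_diag = -0.5, b = 0, c = 0, gain = 1)
  var <- c(a_off = 0.25, a_diag = 0.0625, b = 0.25, c = 1, gain = 0.04)
  map <- c(aOffMean = "a_off", aDiagMean = "a_diag", bMean = "b",
           cMean = "c", gainMean = "gain")
  for (nm in names(map)) if (!is.null(ov[[nm]])) mean[map[[nm]]] <- ov[[nm]]
  mapv <- c(aOffVar = "a_off", aDiagVar = "a_diag", bVar = "b", cVar = "c",
            gainVar = "gain")
  for (nm in names(mapv)) if (!is.null(ov[[nm]])) var[mapv[[nm]]] <- ov[[nm]]
  new("DCMPriors", mean = mean, var = var,
      noiseShape = if (is.null(ov$noiseShape)) 1 else ov$noiseShape,
      noiseRate = if (is.null(ov$noiseRate)) 1e-3 else ov$noiseRate)
}

# Free-parameter bookkeeping: one row per unclamped parameter, with its
# location in A/B/C/gain, its class, and its prior moments. Masked-out
# parameters never enter the vector (zero prior variance = clamped at the
# prior mean, which is 0 for everything maskable).
paramTable <- function(spec, conditions, priors = defaultPriors(),
                       estimateGain = FALSE, clampB = FALSE) {
  rg <- spec@regions
  n <- length(rg)
  rows <- list()
  add <- function(name, slot, i, j, cond, cls)
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, slot = slot, i = i, j = j, cond = cond, class = cls,
      stringsAsFactors = FALSE)
  for (j in seq_len(n)) for (i in seq_len(n)) if (spec@aMask[i, j]) {
    if (i == j) add(sprintf("A(%s self)", rg[i]), "A", i, j, NA, "a_diag")
    else add(sprintf("A(%s->%s)", rg[j], rg[i]), "A", i, j, NA, "a_off")
  }
  if (!clampB) for (cond in conditions)
    for (j in seq_len(n)) for (i in seq_len(n)) if (spec@bMask[i, j]) {
      lab <- if (i == j) sprintf("B.%s(%s self)", cond, rg[i])
             else sprintf("B.%s(%s->%s)", cond, rg[j], rg[i])
      add(lab, "B", i, j, cond, "b")
    }
  for (k in seq_len(ncol(spec@cMask))) for (i in seq_len(n))
    if (spec@cMask[i, k]) add(sprintf("C(%s)", rg[i]), "C", i, k, NA, "c")
  if (estimateGain)
    for (i in seq_len(n))
      add(sprintf("gain(%s)", rg[i]), "gain", i, NA, NA, "gain")
  tab <- do.call(rbind, rows)
  tab$pmean <- priors@mean[tab$class]
  tab$pvar <- priors@var[tab$class]
  tab
}

# Rebuild ConnectivityParams (and gain vector) from a free-parameter vector.
# Skips S4 validity (new("ConnectivityParams") checked elsewhere); invalid
# regions of parameter space are rejected by the forward model's stability
# gate instead, so intermediate optimizer states need not satisfy validity.
paramsFromVector <- function(theta, tab, spec, conditions) {
  n <- length(spec@regions)
  A <- matrix(0, n, n, dimnames = list(spec@regions, spec@regions))
  B <- stats::setNames(
    rep(list(matrix(0, n, n, dimnames = list(spec@regions, spec@regions))),
        length(conditions)), conditions)
  C <- matrix(0, n, ncol(spec@cMask), dimnames = list(spec@regions, NULL))
  gain <- rep(1, n)
  for (r in seq_len(nrow(tab))) {
    v <- theta[r]
    switch(tab$slot[r],
      A = { A[tab$i[r], tab$j[r]] <- v },
      B = { B[[tab$cond[r]]][tab$i[r], tab$j[r]] <- v },
      C = { C[tab$i[r], tab$j[r]] <- v },
      gain = { gain[tab$i[r]] <- v })
  }
  list(A = A, B = B, C = C, gain = gain)
}
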