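#' Fixed-effects Bayesian model selection
#'
#' Ranks models by summing free energies (log evidences) across subjects:
#' group posterior probabilities are proportional to exp of the summed free
#' energy under a uniform model prior, and per-subject probabilities to exp
#' of that subject's free energies. Overflow is guarded by subtracting the
#' maximum before exponentiation.
#'
#' @param evidence subjects x models numeric matrix of free energies
#'   (nats); column names label the models.
#' @return list with \code{group} (named probability vector summing to 1)
#'   and \code{bySubject} (subjects x models matrix of probabilities, rows
#'   summing to 1).
#' @examples
#' ffxBms(matrix(c(0, log(4)), 1, dimnames = list(NULL, c("m1", "m2"))))
#' @export
ffxBms <- function(evidence) {
  evidence <- as.matrix(evidence)
  if (nrow(evidence) < 1 || ncol(evidence) < 2)
    stop("need at least one subject and two models")
  if (any(is.na(evidence)) || any(!is.finite(evidence)))
    stop("free energies must be finite (no NaN)")
  softmax <- function(f) {
    w <- exp(f - max(f))
    w / sum(w)
  }
  group <- softmax(colSums(evidence))
  bySubject <- t(apply(evidence, 1, softmax))
  colnames(bySubject) <- colnames(evidence)
  names(group) <- colnames(evidence)
  list(group = group, bySubject = bySubject)
}

#' Evidence table from fitted posteriors
#'
#' Collects free energies from a subjects x models list-of-lists of
#' [DCMPosterior-class] into the matrix consumed by [ffxBms()], checking
#' that model order is consistent across subjects.
#'
#' @param fits list (subjects) of named lists (models) of
#'   [DCMPosterior-class].
#' @return subjects x models matrix of free energies.
#' @export
evidenceTable <- function(fits) {
  labels <- names(fits[[1]])
  ev <- t(vapply(fits, function(fl) {
    if (!identical(names(fl), labels))
      stop("model ordering differs across subjects")
    vapply(fl, freeEnergyOf, numeric(1))
  }, numeric(length(labels))))
  colnames(ev) <- labels
  if (is.null(rownames(ev))) rownames(ev) <- names(fits)
  ev
}
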