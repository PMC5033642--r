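#' Build the crossed candidate model space
#'
#' Constructs the candidate models as the crossing of between-region
#' modulation patterns with driving-input sites. In every model the A matrix
#' is fully connected and self-connections are modulable (included in B);
#' the models differ only in which between-region connections the condition
#' may modulate and which single region receives the driving input. With the
#' default three patterns and two regions this yields the six-model space
#' used in the study.
#'
#' Regions are ordered from higher to lower in the processing hierarchy
#' (here IFS above VPM): pattern \code{"forward"} lets the condition
#' modulate the ascending connection (region 2 to region 1, e.g. VPM to
#' IFS), \code{"backward"} the descending one, and \code{"bidirectional"}
#' both.
#'
#' @param regions ordered region labels (default \code{c("IFS", "VPM")}).
#' @param bPatterns subset of \code{c("forward", "backward",
#'   "bidirectional")}.
#' @param inputSites region labels that may receive the driving input.
#' @return list of [DCMModelSpec-class], one per pattern x site, in a
#'   deterministic order; labels encode pattern and input site.
#' @examples
#' length(buildModelSpace())  # 6
#' @export
buildModelSpace <- function(regions = c("IFS", "VPM"),
                            bPatterns = c("forward", "backward",
                                          "bidirectional"),
                            inputSites = regions) {
  if (length(regions) != 2)
    stop("the crossed space is defined for exactly two regions")
  if (!length(bPatterns)) stop("bPatterns must be non-empty")
  if (!length(inputSites)) stop("inputSites must be non-empty")
  bPatterns <- match.arg(bPatterns, c("forward", "backward", "bidirectional"),
                         several.ok = TRUE)
  if (!all(inputSites %in% regions))
    stop("inputSites must be a subset of the region labels")
  out <- list()
  for (pat in bPatterns) {
    for (site in inputSites) {
      b <- diag(TRUE, 2)  # self-connections modulable in all models
      if (pat %in% c("forward", "bidirectional")) b[1, 2] <- TRUE
      if (pat %in% c("backward", "bidirectional")) b[2, 1] <- TRUE
      cmask <- matrix(regions == site, ncol = 1)
      spec <- new("DCMModelSpec", regions = regions,
                  aMask = matrix(TRUE, 2, 2), bMask = b, cMask = cmask,
                  label = sprintf("%s-in%s", pat, site))
      out[[spec@label]] <- spec
    }
  }
  out
}

#' Validate a model specification
#'
#' Checks the structural contracts shared by all candidate models: a fully
#' connected A mask, modulable self-connections (bMask diagonal true), and
#' exactly one region receiving each driving input. Returns a character
#' vector of violations (empty when the model is valid), each naming the
#' offending mask.
#'
#' @param spec a [DCMModelSpec-class] (validity not yet enforced).
#' @return character vector of violation messages; empty if valid.
#' @export
validateModel <- function(spec) {
  msg <- character()
  n <- length(spec@regions)
  if (n < 2 || anyDuplicated(spec@regions))
    msg <- c(msg, "regions: need at least two unique labels")
  if (!is.logical(spec@aMask) || any(dim(spec@aMask) != n))
    msg <- c(msg, "aMask: must be an n x n logical matrix")
  else {
    bad <- which(!spec@aMask, arr.ind = TRUE)
    for (r in seq_len(nrow(bad)))
      msg <- c(msg, sprintf("aMask[%d,%d]: A must be fully connected",
                            bad[r, 1], bad[r, 2]))
  }
  if (!is.logical(spec@bMask) || any(dim(spec@bMask) != n))
    msg <- c(msg, "bMask: must be an n x n logical matrix")
  else {
    bad <- which(!diag(spec@bMask))
    for (i in bad)
      msg <- c(msg, sprintf(
        "bMask[%d,%d]: self-connections must be modulable in all models",
        i, i))
  }
  if (!is.logical(spec@cMask) || nrow(spec@cMask) != n)
    msg <- c(msg, "cMask: must be an n x m logical matrix")
  else {
    for (k in seq_len(ncol(spec@cMask)))
      if (sum(spec@cMask[, k]) != 1)
        msg <- c(msg, sprintf(
          "cMask[,%d]: exactly one region must receive each driving input", k))
  }
  msg
}

#' Serialize / restore a model space
#'
#' Writes the model space (labels and masks) to a JSON file for provenance,
#' and reads it back.
#'
#' @param space list of [DCMModelSpec-class] from [buildModelSpace()].
#' @param path file path.
#' @return \code{writeModelSpace} returns the path invisibly;
#'   \code{readModelSpace} the restored list of specs.
#' @export
writeModelSpace <- function(space, path) {
  enc <- lapply(space, function(s) list(
    label = s@label, regions = s@regions,
    aMask = s@aMask, bMask = s@bMask, cMask = s@cMask))
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeModelSpace
#' @export
readModelSpace <- function(path) {
  enc <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(enc, function(e) {
    n <- length(e$regions)
    new("DCMModelSpec", regions = e$regions,
        aMask = matrix(as.logical(e$aMask), n, n),
        bMask = matrix(as.logical(e$bMask), n, n),
        cMask = matrix(as.logical(e$cMask), n),
        label = e$label)
  })
  names(out) <- vapply(enc, `[[`, "", "label")
  out
}
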