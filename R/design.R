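#' Total span of the event sequence implied by a design
#'
#' Time from session start to the end of the last picture, given the
#' block/rest/ITI structure: the first onset follows the fixation lead,
#' consecutive within-block onsets are one ITI apart, and block boundaries
#' add the rest duration.
#'
#' @param design a [DesignSpec-class].
#' @return span in seconds.
#' @export
designSpan <- function(design) {
  on <- designOnsets(design)
  max(on) + design@picDur
}

# onset times implied by the block/rest/ITI structure (deterministic)
designOnsets <- function(design) {
  k <- seq_len(design@nTrials) - 1          # 0-based trial index
  block <- k %/% design@blockSize           # 0-based block index
  design@fixLead + k * design@iti + block * design@restDur
}

#' Generate the event table and input regressor of one session
#'
#' Lays out naming events in blocks separated by rests, with fixed ITI
#' within blocks, and pseudo-randomizes which item is shown at each event.
#' Onset times are fully determined by the design; the seed only shuffles
#' the item order (as in the study, where picture order was
#' pseudo-randomized but the timing grid was fixed).
#'
#' @param design a [DesignSpec-class].
#' @param seed seed for the item shuffle; \code{NULL} leaves items in order.
#' @return list with \code{events} (data.frame: onset, duration, trial_type,
#'   item) and \code{regressor} (nVolumes x 1 matrix of volume-averaged
#'   driving input, events per TR).
#' @examples
#' d <- makeDesign(designSpec(), seed = 1)
#' nrow(d$events)  # 107
#' @export
makeDesign <- function(design = designSpec(), seed = NULL) {
  stopifnot(is(design, "DesignSpec"))
  onsets <- designOnsets(design)
  if (max(onsets) + design@picDur > design@nVolumes * design@TR)
    stop("events overflow the scan duration")
  items <- sprintf("item%03d", seq_len(design@nTrials))
  if (!is.null(seed)) items <- withSeed(seed, sample(items))
  events <- data.frame(onset = onsets, duration = design@picDur,
                       trial_type = "naming", item = items,
                       stringsAsFactors = FALSE)
  # volume-averaged stick input on the TR grid (events per TR)
  reg <- inputRegressor(onsets, dt = design@TR, nSteps = design@nVolumes,
                        width = 0.1) * design@TR
  list(events = events, regressor = matrix(reg, ncol = 1,
                                           dimnames = list(NULL, "naming")))
}
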