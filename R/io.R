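#' Read and write event tables
#'
#' Tab-separated event files in the standard neuroimaging events dialect:
#' columns \code{onset} (s), \code{duration} (s), \code{trial_type}, plus
#' any extra columns (e.g. \code{item}). Onsets must be non-negative and
#' sorted; values round-trip to microsecond precision.
#'
#' @param path file path.
#' @param events data.frame with at least onset, duration, trial_type.
#' @return \code{readEvents} returns the event data.frame;
#'   \code{writeEvents} the path, invisibly.
#' @export
readEvents <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(ev)))
    stop("malformed event file: header must contain ",
         paste(need, collapse = ", "))
  if (nrow(ev)) {
    if (any(!is.finite(ev$onset)) || any(ev$onset < 0))
      stop("onsets must be finite and non-negative")
    if (is.unsorted(ev$onset)) stop("onsets must be sorted")
  }
  ev
}

#' @rdname readEvents
#' @export
writeEvents <- function(events, path) {
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(events)))
    stop("event table must contain ", paste(need, collapse = ", "))
  if (nrow(events) && is.unsorted(events$onset))
    stop("onsets must be sorted")
  fmt <- events
  for (col in c("onset", "duration"))
    fmt[[col]] <- sprintf("%.6f", events[[col]])
  utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write ROI time-series files
#'
#' Tab-separated, header row of region names, one row per volume. The
#' sampling interval lives in the run configuration, not the file. Values
#' round-trip to at least 1e-9.
#'
#' @param path file path.
#' @param series numeric matrix, columns named by region.
#' @return \code{readTimeseries} returns the matrix with region column
#'   names; \code{writeTimeseries} the path, invisibly.
#' @export
readTimeseries <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!ncol(df)) stop("empty time-series file")
  bad <- !vapply(df, is.numeric, logical(1))
  if (any(bad))
    stop("non-numeric cells in time-series column(s): ",
         paste(names(df)[bad], collapse = ", "))
  as.matrix(df)
}

#' @rdname readTimeseries
#' @export
writeTimeseries <- function(series, path) {
  if (is.null(colnames(series)))
    stop("time-series matrix must carry region names as column names")
  df <- as.data.frame(signif(series, 15))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write trial tables
#'
#' Tab-separated behavioural trial tables with the TrialRecord header:
#' subject, condition, item, rt_ms, accurate, voicekey_ok.
#'
#' @param path file path.
#' @param trials trial data.frame.
#' @return the trial data.frame / the path, invisibly.
#' @export
readTrials <- function(path) {
  tr <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject", "condition", "item", "rt_ms", "accurate",
            "voicekey_ok")
  if (!all(need %in% names(tr)))
    stop("malformed trial table: header must contain ",
         paste(need, collapse = ", "))
  tr$accurate <- as.logical(tr$accurate)
  tr$voicekey_ok <- as.logical(tr$voicekey_ok)
  tr
}

#' @rdname readTrials
#' @export
writeTrials <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Electrode current density
#'
#' Current density delivered through a rectangular pad electrode:
#' current / (width x height). At the study settings (2 mA through a
#' 5 x 7 cm electrode) this is 0.057 mA/cm^2.
#'
#' @param current_mA stimulation current (mA).
#' @param electrode_w_cm,electrode_h_cm electrode dimensions (cm).
#' @return current density in mA/cm^2.
#' @examples
#' currentDensity(2, 5, 7)
#' @export
currentDensity <- function(current_mA, electrode_w_cm, electrode_h_cm) {
  if (current_mA <= 0 || electrode_w_cm <= 0 || electrode_h_cm <= 0)
    stop("current and electrode dimensions must be positive")
  current_mA / (electrode_w_cm * electrode_h_cm)
}

#' Read a run configuration file
#'
#' YAML (or JSON, a YAML subset) run configuration: paths, model-space
#' options, priors, inversion settings, BMA settings (n_samples, threshold),
#' seeds, and stimulation metadata (current mA, electrode dimensions cm).
#' Missing fields take the package defaults.
#'
#' @param path YAML file path.
#' @return a named list with validated fields.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  defaults <- list(n_samples = 10000, threshold = 0.95, seed = 1,
                   max_iter = 32, tol = 1e-2, dt = 0.1)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (cfg$n_samples < 1) stop("n_samples must be >= 1")
  if (cfg$threshold <= 0.5 || cfg$threshold >= 1)
    stop("threshold must lie in (0.5, 1)")
  if (!is.null(cfg$stimulation)) {
    st <- cfg$stimulation
    if (!is.null(st$current_mA) && st$current_mA <= 0)
      stop("stimulation current must be positive")
    dims <- c(st$electrode_w_cm, st$electrode_h_cm)
    if (length(dims) && any(dims <= 0))
      stop("electrode dimensions must be positive")
    if (!is.null(st$current_mA) && length(dims) == 2)
      cfg$stimulation$current_density <- round(
        currentDensity(st$current_mA, st$electrode_w_cm, st$electrode_h_cm),
        3)
  }
  cfg
}
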