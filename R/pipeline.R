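# End-to-end pipeline stages and the report writer. Each stage writes its
# artifacts with a provenance block (package version, seeds, config hash).

#' Invert the full model space for a cohort
#'
#' Fits every candidate model to every subject's two-session data.
#'
#' @param cohort output of [simulateCohort()], or any list whose
#'   \code{subjects[[s]]$series} is a named per-condition list of matrices
#'   and \code{subjects[[s]]$events} the per-condition event tables.
#' @param space list of [DCMModelSpec-class] from [buildModelSpace()].
#' @param design a [DesignSpec-class].
#' @param priors,hp,settings passed to [invertVL()].
#' @return list (subjects) of named lists (models) of
#'   [DCMPosterior-class].
#' @export
invertCohort <- function(cohort, space = buildModelSpace(),
                         design = cohort$design,
                         priors = defaultPriors(),
                         hp = hemodynamicParams(2), settings = list()) {
  fits <- lapply(cohort$subjects, function(sub) {
    ev <- lapply(sub$events, function(e) e$onset)
    lapply(space, function(spec)
      invertVL(sub$series, spec, design, ev, priors, hp, settings))
  })
  fits
}

#' Posterior serialization
#'
#' Writes a fitted posterior (means, covariance, noise precision, free
#' energy, diagnostics, model label, settings hash) to a JSON results file.
#'
#' @param q a [DCMPosterior-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePosterior <- function(q, path) {
  doc <- list(model = q@spec@label,
              mean = as.list(q@mean),
              cov = q@cov,
              lambda = q@lambda,
              freeEnergy = q@freeEnergy,
              converged = q@converged,
              explainedVariance = q@diagnostics$explainedVariance,
              iterations = q@diagnostics$iterations,
              settingsHash = configHash(q@settings),
              provenance = provenance(seed = q@settings$seed,
                                      config = q@settings))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Group report: condition contrasts and brain-behaviour correlations
#'
#' Renders the group-level table (per-connection condition means to 2
#' decimals, exceedance percentages, significance at the 95% criterion) and
#' the correlation table (one column per connection, r and p), and writes
#' both with a provenance block.
#'
#' @param bma a [BMAResult-class].
#' @param corr data.frame from [brainBehaviourCorr()] matrix input, or
#'   NULL to omit.
#' @param path output JSON path (a .txt sibling gets the rendered tables).
#' @param threshold,seed passed to [contrastTable()].
#' @return list with the two tables, invisibly.
#' @export
writeReport <- function(bma, corr = NULL, path, threshold = 0.95, seed = 1) {
  ct <- contrastTable(bma, threshold = threshold, seed = seed)
  num <- vapply(ct, is.numeric, logical(1))
  ct[num] <- lapply(ct[num], round, 2)
  doc <- list(groupContrasts = ct,
              correlation = corr,
              definitions = list(
                exceedance = paste(
                  "percentages are the exceedance proportion of the",
                  "condition-difference sample distribution and its",
                  "complement, from the paired two-distribution test"),
                threshold = threshold),
              provenance = provenance(seed = seed))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  txt <- sub("\\.json$", ".txt", path)
  con <- file(txt, "w")
  on.exit(close(con))
  writeLines("Group condition contrasts (connection values in Hz):", con)
  utils::capture.output(print(ct), file = con, append = TRUE)
  if (!is.null(corr)) {
    writeLines("\nBrain-behaviour correlations:", con)
    utils::capture.output(print(corr), file = con, append = TRUE)
  }
  invisible(list(groupContrasts = ct, correlation = corr))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' simulate -> invert all models -> FFX BMS -> BMA -> condition contrasts
#' -> behavioural analysis -> brain-behaviour correlation -> report.
#' Artifacts are written under \code{outDir} when given. This is the
#' programmatic equivalent of the command-line interface's subcommands run
#' in sequence.
#'
#' @param cs a [CohortSpec-class].
#' @param design a [DesignSpec-class].
#' @param settings inversion settings (see [invertVL()]).
#' @param nSamples BMA sample count.
#' @param threshold two-distribution significance threshold.
#' @param seed master seed.
#' @param outDir output directory, or NULL to skip writing.
#' @param space candidate model space.
#' @return list: cohort, fits, evidence, bms, bma, contrasts, behaviour
#'   (cleaning log, by-subject and by-item tests), correlation table.
#' @export
runPipeline <- function(cs = cohortSpec(), design = designSpec(),
                        settings = list(), nSamples = 10000,
                        threshold = 0.95, seed = 1, outDir = NULL,
                        space = buildModelSpace(regions = cs@regions)) {
  cohort <- simulateCohort(cs, design, seed = seed)
  fits <- invertCohort(cohort, space, design, settings = settings)
  ev <- evidenceTable(fits)
  bms <- ffxBms(ev)
  bma <- bmaSample(bms$bySubject, fits, nSamples = nSamples,
                   seed = childSeed(seed, 7))
  contrasts <- contrastTable(bma, threshold = threshold,
                             seed = childSeed(seed, 8))
  cleaned <- cleanTrials(cohort$trials)
  bySub <- conditionMeans(cleaned$trials, by = "subject")
  byItem <- conditionMeans(cleaned$trials, by = "item")
  tests <- list(
    bySubject = pairedTOneTailed(bySub$sham, bySub$anodal, "greater"),
    byItem = pairedTOneTailed(byItem$sham, byItem$anodal, "greater"))
  pct <- rtChangePercent(bySub$anodal, bySub$sham)
  subjMeans <- bmaSubjectMeans(bms$bySubject, fits,
                               seed = childSeed(seed, 9))
  delta <- subjMeans[, , "anodal"] - subjMeans[, , "sham"]
  corr <- if (cs@nSubjects >= 3) brainBehaviourCorr(delta, pct) else NULL
  out <- list(cohort = cohort, fits = fits, evidence = ev, bms = bms,
              bma = bma, contrasts = contrasts,
              behaviour = list(log = cleaned$log, bySubject = bySub,
                               byItem = byItem, tests = tests,
                               pctChange = pct),
              correlation = corr)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeModelSpace(space, file.path(outDir, "model_space.json"))
    for (s in names(fits))
      for (mlab in names(fits[[s]]))
        writePosterior(fits[[s]][[mlab]],
                       file.path(outDir, sprintf("posterior_%s_%s.json",
                                                 s, mlab)))
    jsonlite::write_json(
      list(evidence = ev, group = as.list(bms$group),
           provenance = provenance(seed = seed)),
      file.path(outDir, "bms.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    writeReport(bma, corr, file.path(outDir, "report.json"),
                threshold = threshold, seed = childSeed(seed, 8))
  }
  out
}
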