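# End-to-end orchestration: from a synthetic study (or file inputs) through
# EEG preprocessing, cross-validated decoding, per-word null-corrected
# scoring and population averaging, to the stepwise hierarchical
# regressions on the word features.

#' Word-level decoding analysis of a simulated (or assembled) study
#'
#' Runs, for every subject: EEG preprocessing (optional), cross-validated
#' backward decoding with actual and time-reversed null decoders over the
#' full regularization grid, per-word voiced-span scoring, and the
#' null-corrected per-word score. Subject scores are averaged into
#' standardized population scores, outliers removed with the isolation
#' forest, and the stepwise hierarchical Huber regression fitted per
#' stimulus feature.
#'
#' @param study output of [simulateStudy()] (or a list with the same
#'   fields assembled from real data).
#' @param lambdaGrid normalized regularization grid.
#' @param lags backward [LagGrid-class].
#' @param k folds.
#' @param scoreFeatures stimulus features to score and regress (1, 2 or
#'   both).
#' @param preprocess apply [preprocessEEG()] (band-pass + average
#'   reference) to each part first. Synthetic EEG is generated already
#'   band-limited, so this mainly exercises the real-data contract.
#' @param outlierRemoval run the isolation-forest step.
#' @param isoTrees,isoSeed isolation-forest parameters.
#' @param fixedLambdaIndex also compute corrected scores at one fixed
#'   regularization value (index into `lambdaGrid`) for the control
#'   comparison; `NULL` to skip.
#' @return list: `regressions` (per scored feature, the
#'   [wordLevelRegression()] table), `population` (standardized scores),
#'   `rawMean`, `subjectScores`, `fixedLambdaPopulation` (if requested),
#'   `excludedWords` (voiceless), `flaggedShort`.
#' @export
wordResponsePipeline <- function(study, lambdaGrid = defaultLambdaGrid(),
                                 lags = backwardLagGrid(), k = 5,
                                 scoreFeatures = 1:2, preprocess = FALSE,
                                 outlierRemoval = TRUE, isoTrees = 1000,
                                 isoSeed = 1, fixedLambdaIndex = NULL) {
  nSub <- length(study$eegParts)
  subjectScores <- vector("list", nSub)
  fixedScores <- if (!is.null(fixedLambdaIndex)) vector("list", nSub)
  flagged <- character(0)
  for (s in seq_len(nSub)) {
    parts <- study$eegParts[[s]]
    if (preprocess)
      parts <- lapply(parts, function(M)
        preprocessEEG(eegRecording(M, study$spec$fs))@data)
    raw <- scoreWords(parts, study$featureParts, study$wordSegments,
                      lags = lags, lambdaGrid = lambdaGrid, k = k,
                      scoreFeatures = scoreFeatures)
    subjectScores[[s]] <- correctedScores(raw)
    if (!is.null(fixedLambdaIndex))
      fixedScores[[s]] <- correctedScores(raw, fixedLambdaIndex)
    flagged <- union(flagged, attr(raw, "flaggedShort"))
  }
  pop <- populationScores(subjectScores)
  fixedPop <- if (!is.null(fixedLambdaIndex)) populationScores(fixedScores)
  scoredIds <- as.integer(rownames(pop$population))
  featRows <- study$words[match(scoredIds, study$words$word),
                          wordFeatureOrder()]
  regressions <- list()
  for (j in scoreFeatures) {
    col <- c("f1", "f2")[j]
    regressions[[col]] <- wordLevelRegression(
      featRows, pop$population[, col], seed = isoSeed, nTrees = isoTrees,
      outlierRemoval = outlierRemoval)
  }
  list(regressions = regressions, population = pop$population,
       rawMean = pop$rawMean, subjectScores = subjectScores,
       fixedLambdaPopulation = if (!is.null(fixedLambdaIndex))
         fixedPop$population,
       excludedWords = attr(study$wordSegments, "voiceless"),
       flaggedShort = flagged)
}

#' Forward TRF analysis of a study
#'
#' Fits per-subject complex forward TRFs (actual and time-reversed null)
#' and runs the bootstrap lag-significance analysis.
#'
#' @param study output of [simulateStudy()].
#' @param lags forward [LagGrid-class].
#' @param lambdaN normalized regularization (default 1).
#' @param nBoot bootstrap draws.
#' @param seed bootstrap seed.
#' @param maxSeconds optionally restrict the fit to the first part(s)
#'   totalling at most this duration (NULL = all data).
#' @return list: `trfs`, `nullTrfs`, `summary` (population
#'   [trfSummary()]), `significance` ([bootstrapLagSignificance()]).
#' @export
forwardResponsePipeline <- function(study, lags = lagGrid(-50, 150, 1000),
                                    lambdaN = 1, nBoot = 10000, seed = 1,
                                    maxSeconds = NULL) {
  featParts <- study$featureParts
  keep <- seq_along(featParts)
  if (!is.null(maxSeconds)) {
    cum <- cumsum(study$partLens) / study$spec$fs
    keep <- seq_len(max(1, sum(cum <= maxSeconds)))
  }
  trfs <- list(); nullTrfs <- list()
  for (s in seq_along(study$eegParts)) {
    eegs <- study$eegParts[[s]][keep]
    trfs[[s]] <- fitForwardTRF(eegs, featParts[keep], lags, lambdaN)
    nullTrfs[[s]] <- fitForwardTRF(eegs, featParts[keep], lags, lambdaN,
                                   timeReversed = TRUE)
  }
  list(trfs = trfs, nullTrfs = nullTrfs,
       summary = trfSummary(averageTRF(trfs)),
       significance = bootstrapLagSignificance(trfs, nullTrfs,
                                               nBoot = nBoot, seed = seed))
}

#' Read a pipeline configuration file
#'
#' YAML schema with sections `mode` ("synthetic" or "files"), `paths`
#' (audio, eeg, alignment, probabilities, outputDir), `band`
#' (percentiles), `lags` (forward/backward ms ranges), `lambda` (log-grid
#' bounds and length), `folds`, `durations`, `bootstrap` (n, seed),
#' `outliers` (trees, subsample, seed), and `synthetic` (arguments of
#' [syntheticSpec()]). Validation errors are raised before any
#' computation.
#'
#' @param path YAML file path.
#' @return validated config list.
#' @export
readPipelineConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read config files")
  cfg <- yaml::read_yaml(path)
  validatePipelineConfig(cfg)
}

#' @rdname readPipelineConfig
#' @param cfg a config list to validate.
#' @export
validatePipelineConfig <- function(cfg) {
  cfg$mode <- cfg$mode %||% "synthetic"
  if (!cfg$mode %in% c("synthetic", "files"))
    stop("mode must be 'synthetic' or 'files'")
  if (cfg$mode == "files") {
    req <- c("eeg", "alignment")
    for (r in req)
      if (is.null(cfg$paths[[r]]))
        stop("config missing required path '", r, "' in files mode")
    for (r in names(cfg$paths))
      if (r != "outputDir" && !file.exists(cfg$paths[[r]]))
        stop("configured path does not exist: ", cfg$paths[[r]])
  }
  if (is.null(cfg$seed)) stop("a top-level seed is mandatory")
  cfg$folds <- cfg$folds %||% 5
  cfg$lambda <- cfg$lambda %||% list(logMin = -10, logMax = 10, n = 51)
  cfg$lags <- cfg$lags %||% list(forward = c(-250, 499),
                                 backward = c(-5, 49))
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline from a configuration
#'
#' Synthetic mode: simulate the study from the config's `synthetic`
#' section, then run [forwardResponsePipeline()] (when
#' `cfg$forward$enable` is not FALSE) and [wordResponsePipeline()], and
#' write regression tables, population scores and provenance into
#' `paths$outputDir` when set. Deterministic given the config seeds.
#'
#' @param cfg config list (see [readPipelineConfig()]) or path to a YAML
#'   file.
#' @return list: `study`, `forward`, `words` (pipeline outputs), `config`.
#' @export
runPipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- readPipelineConfig(cfg)
  cfg <- validatePipelineConfig(cfg)
  if (cfg$mode != "synthetic")
    stop("files mode requires assembling a study from the readers; ",
         "see the vignette for the per-stage functions")
  synthArgs <- cfg$synthetic %||% list()
  synthArgs$seed <- synthArgs$seed %||% cfg$seed
  if (!is.null(synthArgs$modulationBetas))
    synthArgs$modulationBetas <- as.numeric(synthArgs$modulationBetas)
  spec <- do.call(syntheticSpec, synthArgs)
  t0 <- Sys.time()
  study <- simulateStudy(spec)
  lambdaGrid <- 10^seq(cfg$lambda$logMin, cfg$lambda$logMax,
                       length.out = cfg$lambda$n)
  fw <- NULL
  if (!isFALSE(cfg$forward$enable)) {
    fwLags <- lagGrid(cfg$lags$forward[1], cfg$lags$forward[2], spec$fs)
    fw <- forwardResponsePipeline(
      study, fwLags, nBoot = cfg$bootstrap$n %||% 1000,
      seed = cfg$bootstrap$seed %||% cfg$seed,
      maxSeconds = cfg$forward$maxSeconds)
  }
  bwLags <- lagGrid(cfg$lags$backward[1], cfg$lags$backward[2], spec$fs)
  words <- wordResponsePipeline(
    study, lambdaGrid = lambdaGrid, lags = bwLags, k = cfg$folds,
    isoTrees = cfg$outliers$trees %||% 1000,
    isoSeed = cfg$outliers$seed %||% cfg$seed)
  out <- list(study = study, forward = fw, words = words, config = cfg,
              elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  dir <- cfg$paths$outputDir
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    hash <- sprintf("seed%d", cfg$seed)
    for (nm in names(words$regressions))
      writeRegressionTable(words$regressions[[nm]],
                           file.path(dir, paste0("regression_", nm, ".csv")),
                           configHash = hash)
    popDf <- data.frame(word = rownames(words$population),
                        words$population, check.names = FALSE)
    writeTableWithProvenance(popDf, file.path(dir, "population_scores.csv"),
                             configHash = hash)
  }
  out
}
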