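# Word-level neural-response scoring: per-word reconstruction scores for
# every regularization value, null-corrected per-word scores, and
# standardized population scores used as the regression response.

#' Voiced-span segments of a word table
#'
#' Converts a word table plus voiced-interval table into the per-word
#' sample segments used for scoring. Words without any voiced interval are
#' excluded (no neural response at f0 can be inferred for them) and
#' reported in the `"voiceless"` attribute.
#'
#' @param words data.frame with columns `word` (id), `part`, and the part
#'   start time `partStart` implied by `partLens`; onsets/offsets unused
#'   here.
#' @param voiced data.frame with columns `word`, `start`, `end` (global
#'   seconds, half-open intervals).
#' @param partLens numeric vector of part lengths in samples.
#' @param fs sampling rate (Hz).
#' @return data.frame (word, part, from, to) with part-relative 1-based
#'   sample indices; attribute `"voiceless"` lists excluded word ids.
#' @export
wordVoicedSegments <- function(words, voiced, partLens, fs = 1000) {
  partStart <- c(0, cumsum(partLens))[seq_along(partLens)] / fs
  voiceless <- setdiff(words$word, unique(voiced$word))
  p <- words$part[match(voiced$word, words$word)]
  from <- pmax(1, floor((voiced$start - partStart[p]) * fs) + 1)
  to <- pmin(partLens[p], ceiling((voiced$end - partStart[p]) * fs))
  keep <- to >= from
  out <- data.frame(word = voiced$word[keep], part = p[keep],
                    from = from[keep], to = to[keep])
  structure(out, voiceless = voiceless)
}

#' Per-word reconstruction scores for model and null decoders
#'
#' Runs cross-validated backward decoding (each word scored by the
#' decoders of the fold that holds it out, preventing leakage) and returns
#' the raw per-word score array: Pearson's r between reconstructed and
#' actual feature over the word's voiced samples, for every normalized
#' regularization value, for the actual and the time-reversed null
#' decoders. Scoring uses only the voiced samples of each word, where the
#' f0-band features carry signal.
#'
#' @inheritParams crossValidateDecoders
#' @param wordSegments per-word voiced spans from [wordVoicedSegments()].
#' @return the `wordScores` array of [crossValidateDecoders()]:
#'   (word x lambda x feature x model/null).
#' @export
scoreWords <- function(eegParts, featureParts, wordSegments,
                       lags = backwardLagGrid(),
                       lambdaGrid = defaultLambdaGrid(), k = 5,
                       scoreFeatures = 1:2, minLen = 20) {
  cv <- crossValidateDecoders(eegParts, featureParts, lags = lags,
                              lambdaGrid = lambdaGrid, k = k,
                              durations = numeric(0),
                              wordSegments = wordSegments,
                              scoreFeatures = scoreFeatures,
                              nullModel = TRUE, minLen = minLen)
  cv$wordScores
}

#' Null-corrected per-word score
#'
#' The per-word response strength is the model's best reconstruction score
#' over the regularization grid minus the null model's best score over the
#' same grid, with the optimum picked independently for each:
#' `r(i) = max_lambda r_model(i) - max_lambda r_null(i)`. The result may be
#' negative. Non-finite per-lambda scores are excluded; if nothing finite
#' remains, `NA` is returned (word dropped).
#'
#' @param modelScores numeric vector of per-lambda scores (model).
#' @param nullScores numeric vector over the same grid (null).
#' @return scalar corrected score, or `NA_real_`.
#' @examples
#' correctedWordScore(c(0.1, 0.4), c(0.2, 0.05))  # 0.2
#' @export
correctedWordScore <- function(modelScores, nullScores) {
  if (length(modelScores) == 0 || length(nullScores) == 0)
    stop("score lists must be nonempty")
  m <- suppressWarnings(max(modelScores[is.finite(modelScores)]))
  n <- suppressWarnings(max(nullScores[is.finite(nullScores)]))
  if (!is.finite(m) || !is.finite(n)) return(NA_real_)
  m - n
}

#' Corrected scores for a whole word-score array
#'
#' Applies [correctedWordScore()] word by word and feature by feature to a
#' raw score array; optionally with a fixed regularization value instead of
#' the per-word maximum (the fixed-regularization control analysis).
#'
#' @param raw array (word x lambda x feature x model) from [scoreWords()].
#' @param fixedLambdaIndex if given, use this single lambda index for both
#'   model and null instead of maximizing over the grid.
#' @return matrix (word x feature) of corrected scores with word ids as
#'   row names.
#' @export
correctedScores <- function(raw, fixedLambdaIndex = NULL) {
  nW <- dim(raw)[1]; nF <- dim(raw)[3]
  out <- matrix(NA_real_, nW, nF,
                dimnames = list(dimnames(raw)[[1]], dimnames(raw)[[3]]))
  for (j in seq_len(nF)) {
    if (is.null(fixedLambdaIndex)) {
      m <- suppressWarnings(apply(raw[, , j, 1, drop = FALSE], 1, max,
                                  na.rm = TRUE))
      n <- suppressWarnings(apply(raw[, , j, 2, drop = FALSE], 1, max,
                                  na.rm = TRUE))
    } else {
      m <- raw[, fixedLambdaIndex, j, 1]
      n <- raw[, fixedLambdaIndex, j, 2]
    }
    v <- m - n
    v[!is.finite(v)] <- NA_real_
    out[, j] <- v
  }
  out
}

#' Population word scores
#'
#' Averages per-word corrected scores across subjects (unweighted; words
#' missing in some subjects use the available ones) and standardizes the
#' averages to zero mean and unit standard deviation over the retained
#' words, per feature.
#'
#' @param subjectScores list of (word x feature) corrected-score matrices,
#'   one per subject, with identical row sets.
#' @return list: `population` (word x feature standardized matrix),
#'   `rawMean` (pre-standardization means), `nSubjects` (word x feature
#'   count of contributing subjects).
#' @export
populationScores <- function(subjectScores) {
  stopifnot(length(subjectScores) >= 1)
  arr <- simplify2array(subjectScores)        # word x feature x subject
  if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1)
  rawMean <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  nSub <- apply(!is.na(arr), c(1, 2), sum)
  rawMean[nSub == 0] <- NA_real_
  pop <- apply(rawMean, 2, function(v) {
    keep <- is.finite(v)
    v[keep] <- (v[keep] - mean(v[keep])) / sd(v[keep])
    v
  })
  dimnames(pop) <- dimnames(rawMean) <- dimnames(subjectScores[[1]])
  list(population = pop, rawMean = rawMean, nSubjects = nSub)
}
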