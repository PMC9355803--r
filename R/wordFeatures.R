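# Word-level predictors: three acoustic features from the pitch track
# (mean f0, f0 rate of change, voiced duration) and four linguistic
# features from a language probability source (inverted word frequency,
# surprisal, precision, precision x surprisal). All information measures
# use natural logarithms (nats).

#' A pluggable source of word probabilities
#'
#' Holds, per word position, the unconditional (unigram) probability of the
#' realized word and either the full conditional next-word distribution or
#' the precomputed realized-word conditional probability and entropy. Any
#' language model - neural, n-gram, or the package's toy Markov chain - can
#' fill this interface.
#'
#' @param unigram numeric vector: P(w) of the realized word per position.
#' @param conditional either a matrix (positions x vocabulary) of full
#'   conditional distributions (rows sum to 1), or `NULL` when
#'   `realizedP`/`entropy` are supplied directly.
#' @param realizedIndex with a full `conditional`, the vocabulary index of
#'   the realized word per position.
#' @param realizedP per-position conditional probability of the realized
#'   word (used when `conditional` is `NULL`).
#' @param entropy per-position conditional next-word entropy in nats (used
#'   when `conditional` is `NULL`).
#' @return an object of class `"LanguageProbabilitySource"`.
#' @export
probabilitySource <- function(unigram, conditional = NULL,
                              realizedIndex = NULL, realizedP = NULL,
                              entropy = NULL) {
  if (!is.null(conditional)) {
    conditional <- as.matrix(conditional)
    if (any(abs(rowSums(conditional) - 1) > 1e-9))
      stop("conditional distributions must sum to 1")
    if (is.null(realizedIndex))
      stop("realizedIndex required with a full conditional distribution")
    realizedP <- conditional[cbind(seq_len(nrow(conditional)), realizedIndex)]
    pc <- conditional
    entropy <- -rowSums(ifelse(pc > 0, pc * log(pc), 0))
  } else {
    if (is.null(realizedP) || is.null(entropy))
      stop("either a full conditional or realizedP + entropy is required")
  }
  structure(list(unigram = unigram, realizedP = realizedP,
                 entropy = entropy,
                 full = !is.null(conditional)),
            class = "LanguageProbabilitySource")
}

#' @export
print.LanguageProbabilitySource <- function(x, ...) {
  cat(sprintf("LanguageProbabilitySource: %d positions (%s distributions)\n",
              length(x$realizedP), if (x$full) "full" else "summarized"))
  invisible(x)
}

#' Information-theoretic word features
#'
#' For the word at `position`: inverted word frequency `-ln P(w)` from the
#' unigram probability, surprisal `-ln P(w_n | context)` from the
#' conditional probability, precision as the inverse conditional entropy
#' `1 / E(w_n)`, and the interaction `precision * surprisal`. A zero
#' entropy (deterministic prediction) is clamped at `entropyFloor` nats and
#' flagged, since the inverse is otherwise unbounded.
#'
#' @param source a `LanguageProbabilitySource`.
#' @param position word position index.
#' @param entropyFloor clamp for near-zero entropies (nats).
#' @return list: `invFreq`, `surprisal`, `precision`, `interaction`,
#'   `entropy`, `clamped` (logical flag).
#' @examples
#' src <- probabilitySource(unigram = exp(-2), realizedP = exp(-3),
#'                          entropy = 2)
#' informationFeatures(src, 1)$interaction  # 1.5
#' @export
informationFeatures <- function(source, position, entropyFloor = 1e-6) {
  stopifnot(inherits(source, "LanguageProbabilitySource"))
  pU <- source$unigram[position]
  pC <- source$realizedP[position]
  E <- source$entropy[position]
  if (is.na(pU) || is.na(pC) || pU < 0 || pC < 0)
    stop("invalid probabilities at position ", position)
  if (pU == 0 || pC == 0)
    stop("zero probability for the realized word at position ", position,
         "; map out-of-vocabulary words to the unknown token or enable ",
         "smoothing in the probability source")
  clamped <- E < entropyFloor
  Ec <- max(E, entropyFloor)
  surprisal <- -log(pC)
  precision <- 1 / Ec
  list(invFreq = -log(pU), surprisal = surprisal, precision = precision,
       interaction = precision * surprisal, entropy = E, clamped = clamped)
}

#' Acoustic word features from a pitch track
#'
#' Computes, per word, the mean fundamental frequency over its voiced
#' frames, the rate of f0 change (mean absolute first derivative over
#' consecutive voiced frame pairs within the same voiced interval - no
#' derivative is taken across unvoiced gaps), and the summed voiced
#' duration. Pitch frames are assigned to intervals by frame-center time;
#' word intervals are half-open `[onset, offset)`.
#'
#' @param pitch a [PitchTrack-class].
#' @param onset,offset word boundaries in seconds.
#' @param voicedIntervals data.frame with columns `start`, `end` (seconds)
#'   of the word's voiced spans; if `NULL`, the voiced pitch frames within
#'   the word define a single span per maximal voiced run.
#' @return list: `meanF0` (Hz), `f0Rate` (Hz/s), `voicedDuration` (s),
#'   `voiced` (FALSE when the word has no voiced frame; such words are
#'   excluded downstream).
#' @export
acousticFeatures <- function(pitch, onset, offset, voicedIntervals = NULL) {
  stopifnot(is(pitch, "PitchTrack"))
  inWord <- pitch@times >= onset & pitch@times < offset
  if (is.null(voicedIntervals)) {
    v <- inWord & !is.na(pitch@f0)
    if (!any(v))
      return(list(meanF0 = NA_real_, f0Rate = NA_real_,
                  voicedDuration = 0, voiced = FALSE))
    # maximal runs of voiced frames form the intervals
    r <- rle(v)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    keep <- which(r$values)
    voicedIntervals <- data.frame(
      start = pitch@times[starts[keep]] - pitch@frameStep / 2,
      end = pitch@times[ends[keep]] + pitch@frameStep / 2)
  }
  f0s <- numeric(0); rates <- numeric(0); dur <- 0
  for (i in seq_len(nrow(voicedIntervals))) {
    sel <- pitch@times >= voicedIntervals$start[i] &
      pitch@times < voicedIntervals$end[i] & inWord & !is.na(pitch@f0)
    dur <- dur + max(0, min(voicedIntervals$end[i], offset) -
                       max(voicedIntervals$start[i], onset))
    f <- pitch@f0[sel]; tt <- pitch@times[sel]
    f0s <- c(f0s, f)
    if (length(f) >= 2) rates <- c(rates, abs(diff(f) / diff(tt)))
  }
  if (length(f0s) == 0)
    return(list(meanF0 = NA_real_, f0Rate = NA_real_, voicedDuration = 0,
                voiced = FALSE))
  list(meanF0 = mean(f0s),
       f0Rate = if (length(rates)) mean(rates) else 0,
       voicedDuration = dur, voiced = TRUE)
}

#' The canonical word-feature order of the analysis
#'
#' Acoustic features first (expected to carry the largest share of the
#' response modulation), then the linguistic ones: (1) mean f0, (2) f0 rate
#' of change, (3) voiced duration, (4) inverted word frequency, (5) word
#' precision, (6) word surprisal, (7) precision x surprisal.
#'
#' @return character vector of the seven feature names in hierarchy order.
#' @export
wordFeatureOrder <- function()
  c("meanF0", "f0Rate", "voicedDuration", "invFreq", "precision",
    "surprisal", "interaction")

#' Pairwise correlations between word-level features
#'
#' Pearson correlation matrix over complete word records plus a
#' Benjamini-Yekutieli-corrected significance mask for the off-diagonal
#' pairs. Constant features yield undefined correlations and are masked.
#'
#' @param records data.frame with the seven feature columns of
#'   [wordFeatureOrder()] (extra columns ignored; rows with NA dropped).
#' @param alpha significance level for the mask.
#' @return list: `r` (7 x 7 symmetric, unit diagonal), `pRaw`, `pFdr`
#'   (corrected across the 21 pairs), `significant` (logical mask).
#' @export
featureCorrelationMatrix <- function(records, alpha = 0.05) {
  cols <- wordFeatureOrder()
  if (!all(cols %in% names(records)))
    stop("records must contain the columns: ", paste(cols, collapse = ", "))
  m <- as.matrix(records[, cols])
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3) stop("need at least 3 complete records")
  K <- length(cols)
  r <- diag(1, K); pRaw <- matrix(NA_real_, K, K)
  dimnames(r) <- dimnames(pRaw) <- list(cols, cols)
  for (i in 1:(K - 1)) for (j in (i + 1):K) {
    if (sd(m[, i]) == 0 || sd(m[, j]) == 0) {
      r[i, j] <- r[j, i] <- NA_real_
      next
    }
    ct <- cor.test(m[, i], m[, j])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    pRaw[i, j] <- pRaw[j, i] <- ct$p.value
  }
  up <- upper.tri(pRaw)
  pAdj <- p.adjust(pRaw[up], method = "BY")
  pFdr <- matrix(NA_real_, K, K, dimnames = dimnames(pRaw))
  pFdr[up] <- pAdj
  pFdr[lower.tri(pFdr)] <- t(pFdr)[lower.tri(pFdr)]
  list(r = r, pRaw = pRaw, pFdr = pFdr,
       significant = !is.na(pFdr) & pFdr < alpha, n = nrow(m))
}
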