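# Backward modeling: real-valued decoders reconstructing both stimulus
# features from lagged multichannel EEG, evaluated by five-fold
# cross-validation over a logarithmic grid of normalized regularization
# values, with segment-wise and word-wise Pearson scoring.
#
# Computational layout: the lagged-EEG design is never fitted per lambda.
# Per recording part we accumulate the Gram matrix X'X and the
# cross-products X'Y (actual features) and X'Y_null (time-reversed
# features); per cross-validation fold one symmetric eigendecomposition of
# the training Gram yields the whole lambda path. The null decoder shares
# X'X with the model decoder, since time reversal touches only the
# response side.

# Chunked Gram accumulation: X'X and X'Y of the lagged design of M
# without materializing the whole design (row blocks of `chunk`).
.laggedGram <- function(M, tau, Ylist, chunk = 65536L) {
  n <- nrow(M)
  t0 <- 1 + max(tau, 0); t1 <- n + min(tau, 0)
  if (t1 < t0) stop("recording shorter than the lag span")
  rows <- t0:t1
  p <- ncol(M) * length(tau)
  XtX <- matrix(0, p, p)
  XtY <- lapply(Ylist, function(Y) matrix(0, p, ncol(Y)))
  X <- matrix(0, min(chunk, length(rows)), p)  # reused chunk buffer
  for (start in seq(1, length(rows), by = chunk)) {
    idx <- rows[start:min(start + chunk - 1, length(rows))]
    if (length(idx) != nrow(X)) X <- matrix(0, length(idx), p)
    for (li in seq_along(tau))
      X[, (seq_len(ncol(M)) - 1) * length(tau) + li] <- M[idx - tau[li], ]
    XtX <- XtX + crossprod(X)
    for (k in seq_along(Ylist))
      XtY[[k]] <- XtY[[k]] +
        crossprod(X, Ylist[[k]][idx, , drop = FALSE])
  }
  list(XtX = XtX, XtY = XtY, n = length(rows), rows = rows)
}

# Chunked reconstruction: lagged design of M times B, rows as in
# .laggedGram. `rows` may restrict reconstruction to a subset of the
# valid time indices (e.g. only samples that are scored).
.laggedRecon <- function(M, tau, B, chunk = 65536L, rows = NULL) {
  n <- nrow(M)
  t0 <- 1 + max(tau, 0); t1 <- n + min(tau, 0)
  if (is.null(rows)) rows <- t0:t1
  else rows <- rows[rows >= t0 & rows <= t1]
  out <- matrix(0, length(rows), ncol(B))
  X <- matrix(0, min(chunk, length(rows)), nrow(B))  # reused chunk buffer
  for (start in seq(1, length(rows), by = chunk)) {
    sel <- start:min(start + chunk - 1, length(rows))
    idx <- rows[sel]
    if (length(idx) != nrow(X)) X <- matrix(0, length(idx), nrow(B))
    for (li in seq_along(tau))
      X[, (seq_len(ncol(M)) - 1) * length(tau) + li] <- M[idx - tau[li], ]
    out[sel, ] <- X %*% B
  }
  attr(out, "rows") <- rows
  out
}

#' The default grid of normalized regularization parameters
#'
#' 51 logarithmically spaced values from 1e-10 to 1e10.
#'
#' @return numeric vector of length 51.
#' @export
defaultLambdaGrid <- function() 10^seq(-10, 10, length.out = 51)

#' Default backward lag grid
#'
#' -5..49 ms (EEG may lag the stimulus by up to 49 ms and precede it by
#' 5 ms): 55 lags at 1 kHz, the window that captures the significant
#' forward-model latencies.
#'
#' @param fs sampling rate (Hz).
#' @return A [LagGrid-class].
#' @export
backwardLagGrid <- function(fs = 1000) lagGrid(-5, 49, fs)

#' Fit backward decoders over a regularization grid
#'
#' Fits, on all supplied data, one real-valued decoder per normalized
#' regularization value, reconstructing both stimulus features
#' simultaneously from lagged EEG. Parts are standardized separately and
#' their Gram matrices summed, as in [fitForwardTRF()].
#'
#' @param eeg an [EEGRecording-class], matrix, or list of parts.
#' @param features a [StimulusFeatures-class] or list of parts.
#' @param lags a [LagGrid-class] (default [backwardLagGrid()]).
#' @param lambdaGrid numeric vector of normalized regularization values
#'   (default [defaultLambdaGrid()]); must be nonempty.
#' @param standardize standardize each part before fitting.
#' @param timeReversed train against time-reversed features (null model).
#' @return list of [BackwardDecoder-class], one per lambda.
#' @export
fitBackwardDecoders <- function(eeg, features, lags = backwardLagGrid(),
                                lambdaGrid = defaultLambdaGrid(),
                                standardize = TRUE, timeReversed = FALSE) {
  if (length(lambdaGrid) == 0) stop("lambda grid must be nonempty")
  eegParts <- .asPartList(eeg, "eeg")
  featParts <- .asPartList(features, "features")
  tau <- .backwardLagSamples(lags)
  XtX <- NULL; XtY <- NULL; n <- 0
  for (k in seq_along(eegParts)) {
    R <- .partMatrix(eegParts[[k]])
    Yf <- cbind(featParts[[k]]@f1, featParts[[k]]@f2)
    if (timeReversed) Yf <- Yf[rev(seq_len(nrow(Yf))), , drop = FALSE]
    if (standardize) { R <- .standardize(R); Yf <- .standardize(Yf) }
    X <- .laggedDesign(R, tau)
    Yv <- Yf[attr(X, "rows"), , drop = FALSE]
    if (is.null(XtX)) { XtX <- crossprod(X); XtY <- crossprod(X, Yv) }
    else { XtX <- XtX + crossprod(X); XtY <- XtY + crossprod(X, Yv) }
    n <- n + nrow(X)
  }
  eig <- .ridgeEigen(XtX, n)
  nCh <- ncol(.partMatrix(eegParts[[1]]))
  lapply(lambdaGrid, function(lam) {
    b <- .ridgePathSolve(eig, XtY, lam)
    beta <- array(b, dim = c(lags@nLags, nCh, 2))
    new("BackwardDecoder", beta = beta, lagGrid = lags, lambdaN = lam,
        em = eig$em)
  })
}

#' Reconstruct the stimulus features with a decoder
#'
#' @param decoder a [BackwardDecoder-class].
#' @param eeg an [EEGRecording-class] or matrix (one part, standardized the
#'   same way the decoder's training data were).
#' @param standardize standardize the EEG part first (default TRUE).
#' @return matrix (validSamples x 2) of reconstructed features, with
#'   attribute `"rows"` giving the time indices of the valid samples.
#' @export
reconstructFeatures <- function(decoder, eeg, standardize = TRUE) {
  R <- .partMatrix(eeg)
  if (standardize) R <- .standardize(R)
  X <- .laggedDesign(R, .backwardLagSamples(decoder@lagGrid))
  d <- dim(decoder@beta)
  out <- X %*% matrix(decoder@beta, d[1] * d[2], d[3])
  attr(out, "rows") <- attr(X, "rows")
  out
}

# --- internal scoring primitives -------------------------------------------

# Pearson r between each column of R (reconstructions) and y (truth),
# separately within groups g (0 = unscored). Returns list(r = groups x K,
# n = group sizes). Zero-variance groups give NA.
.groupedPearson <- function(R, y, g) {
  keep <- g > 0
  if (!any(keep)) return(list(r = NULL, n = integer(0), ids = integer(0)))
  R <- R[keep, , drop = FALSE]; y <- y[keep]; g <- g[keep]
  gf <- factor(g)
  nG <- rowsum(rep(1, length(y)), gf)
  Sy <- rowsum(y, gf); Syy <- rowsum(y^2, gf)
  S1 <- rowsum(R, gf); S2 <- rowsum(R^2, gf); Sxy <- rowsum(R * y, gf)
  vy <- Syy - Sy^2 / nG
  vx <- S2 - S1^2 / as.numeric(nG)
  cov <- Sxy - S1 * as.numeric(Sy) / as.numeric(nG)
  den <- sqrt(vx) * sqrt(as.numeric(vy))
  r <- cov / den
  r[!is.finite(r)] <- NA_real_
  list(r = r, n = as.integer(nG), ids = as.integer(levels(gf)))
}

# Build a fixed-duration segmentation group vector for nValid samples.
.fixedSegments <- function(nValid, fs, duration) {
  len <- round(duration * fs)
  g <- ceiling(seq_len(nValid) / len)
  # drop a trailing partial segment
  if (nValid %% len != 0) g[g == max(g)] <- 0L
  g
}

#' Score reconstructions within segments of held-out data
#'
#' Reconstructs both features over the evaluation data once, then computes
#' Pearson's r between reconstruction and truth within each segment.
#' Segments are either fixed-duration windows or word-boundary intervals.
#' Segments shorter than `minLen` samples and zero-variance segments are
#' skipped and counted.
#'
#' @param decoder a [BackwardDecoder-class].
#' @param eeg evaluation EEG part (disjoint from the training folds).
#' @param features matching [StimulusFeatures-class].
#' @param scheme a list: `list(mode = "fixed_duration", duration = 1)` or
#'   `list(mode = "word_boundaries", words = data.frame(word, from, to))`
#'   with part-relative 1-based sample indices.
#' @param minLen minimum segment length in samples for Pearson scoring.
#' @param standardize standardize part before reconstruction/scoring.
#' @return data.frame with one row per (feature, segment): `feature`,
#'   `segment`, `r`, `n`; attribute `"nSkipped"` counts skipped segments.
#' @export
evaluateSegments <- function(decoder, eeg, features, scheme,
                             minLen = 20, standardize = TRUE) {
  recon <- reconstructFeatures(decoder, eeg, standardize = standardize)
  rows <- attr(recon, "rows")
  truth <- cbind(features@f1, features@f2)
  if (standardize) truth <- .standardize(truth)
  truth <- truth[rows, , drop = FALSE]
  nValid <- length(rows)
  fs <- features@fs
  g <- switch(scheme$mode,
    fixed_duration = .fixedSegments(nValid, fs, scheme$duration),
    word_boundaries = {
      gg <- integer(nValid)
      w <- scheme$words
      for (i in seq_len(nrow(w))) {
        sel <- rows >= w$from[i] & rows <= w$to[i]
        gg[sel] <- w$word[i]
      }
      gg
    },
    stop("unknown segmentation mode: ", scheme$mode))
  out <- NULL; skipped <- 0L
  for (j in 1:2) {
    gp <- .groupedPearson(recon[, j, drop = FALSE], truth[, j], g)
    if (is.null(gp$r)) next
    short <- gp$n < minLen
    bad <- is.na(gp$r[, 1])
    skipped <- skipped + sum(short | bad)
    keep <- !short & !bad
    if (any(keep))
      out <- rbind(out, data.frame(feature = j, segment = gp$ids[keep],
                                   r = gp$r[keep, 1], n = gp$n[keep]))
  }
  if (is.null(out))
    out <- data.frame(feature = integer(0), segment = integer(0),
                      r = numeric(0), n = integer(0))
  attr(out, "nSkipped") <- skipped
  out
}

# Assign parts to k contiguous folds with near-equal total length.
.assignFolds <- function(partLens, k) {
  nP <- length(partLens)
  if (k < 2) stop("k must be >= 2")
  if (k > nP) stop("k exceeds the number of recording parts")
  target <- cumsum(partLens) / sum(partLens)
  fold <- pmin(k, floor((target - partLens / sum(partLens) / 2) * k) + 1)
  fold <- cummax(fold)
  # guarantee all k folds non-empty
  if (length(unique(fold)) < k) fold <- sort(rep_len(seq_len(k), nP))
  fold
}

#' Cross-validated backward decoding with segment and word scoring
#'
#' Splits the recording parts into `k` contiguous folds of near-equal
#' duration, fits decoders for every normalized regularization value on the
#' training folds (actual and, optionally, time-reversed null features),
#' and scores reconstructions on the held-out fold within fixed-duration
#' segments, word-boundary segments, and/or per-word voiced spans.
#'
#' @param eegParts list of EEG parts (matrices or [EEGRecording-class]).
#' @param featureParts list of matching [StimulusFeatures-class].
#' @param lags backward [LagGrid-class].
#' @param lambdaGrid normalized regularization grid.
#' @param k number of folds (>= 2, <= number of parts).
#' @param durations numeric vector of fixed segment durations in seconds
#'   (possibly empty) for the segment-level score matrix.
#' @param wordSegments optional data.frame with columns `word` (id),
#'   `part` (part index), `from`, `to` (part-relative 1-based sample
#'   indices of a voiced span; a word may span several rows). Scored
#'   per word over the union of its spans, at every lambda, for model and
#'   null decoders.
#' @param scoreFeatures which features to score per word (1, 2 or both);
#'   both are always reconstructed and fitted jointly.
#' @param nullModel also fit/score the time-reversed null decoders.
#' @param minLen minimum samples for a Pearson score.
#' @param standardize standardize each part (features and EEG) before use.
#' @return list with elements:
#'   \describe{
#'   \item{segmentScores}{data.frame (fold, feature, scheme, lambdaN,
#'     modelType, meanR, nSegments, nSkipped), scheme labels like "1s" or
#'     "words"; mean is the arithmetic mean of segment r.}
#'   \item{wordScores}{array (word x lambda x feature x modelType) of
#'     per-word Pearson r, NA where unscorable; `dimnames` carry word ids;
#'     attribute `"flaggedShort"` lists words scored on fewer than
#'     `minLen` samples.}
#'   \item{folds}{fold assignment per part.}
#'   }
#' @export
crossValidateDecoders <- function(eegParts, featureParts,
                                  lags = backwardLagGrid(),
                                  lambdaGrid = defaultLambdaGrid(),
                                  k = 5, durations = numeric(0),
                                  wordSegments = NULL,
                                  scoreFeatures = 1:2,
                                  nullModel = TRUE, minLen = 20,
                                  standardize = TRUE) {
  if (length(lambdaGrid) == 0) stop("lambda grid must be nonempty")
  nP <- length(eegParts)
  stopifnot(nP == length(featureParts))
  tau <- .backwardLagSamples(lags)
  nLam <- length(lambdaGrid)
  # per-part sufficient statistics and standardized data
  partLens <- vapply(eegParts, function(p) nrow(.partMatrix(p)), 0L)
  folds <- .assignFolds(partLens, k)
  Rs <- vector("list", nP); Ys <- vector("list", nP)
  XtXs <- vector("list", nP); XtYs <- vector("list", nP)
  XtYn <- vector("list", nP); ns <- integer(nP)
  for (p in seq_len(nP)) {
    R <- .partMatrix(eegParts[[p]])
    Yf <- cbind(featureParts[[p]]@f1, featureParts[[p]]@f2)
    if (standardize) { R <- .standardize(R); Yf <- .standardize(Yf) }
    Rs[[p]] <- R; Ys[[p]] <- Yf
    Ylist <- list(Yf)
    if (nullModel)
      Ylist <- c(Ylist, list(Yf[rev(seq_len(nrow(Yf))), , drop = FALSE]))
    g <- .laggedGram(R, tau, Ylist)
    XtXs[[p]] <- g$XtX
    XtYs[[p]] <- g$XtY[[1]]
    if (nullModel) XtYn[[p]] <- g$XtY[[2]]
    ns[p] <- g$n
  }
  nCh <- ncol(Rs[[1]])
  pDim <- nCh * lags@nLags
  modelTypes <- if (nullModel) c("model", "null") else "model"
  segOut <- NULL
  wordIds <- if (!is.null(wordSegments)) sort(unique(wordSegments$word))
  wordR <- if (!is.null(wordSegments))
    array(NA_real_, dim = c(length(wordIds), nLam, 2, length(modelTypes)),
          dimnames = list(word = wordIds, lambda = NULL,
                          feature = c("f1", "f2"), model = modelTypes))
  flagged <- integer(0)
  for (f in seq_len(k)) {
    trainP <- which(folds != f); testP <- which(folds == f)
    XtX <- Reduce(`+`, XtXs[trainP])
    nTr <- sum(ns[trainP])
    eig <- .ridgeEigen(XtX, nTr)
    # coefficient stack: columns = (model/null) x feature x lambda
    featSet <- sort(unique(c(if (length(durations)) 1:2, scoreFeatures)))
    nFs <- length(featSet)
    XtYtr <- Reduce(`+`, XtYs[trainP])[, featSet, drop = FALSE]
    Bm <- vapply(lambdaGrid, function(lam) .ridgePathSolve(eig, XtYtr, lam),
                 matrix(0, pDim, nFs))            # pDim x nFs x nLam
    Bstack <- matrix(Bm, pDim, nFs * nLam)        # cols: featSet x lambda
    if (nullModel) {
      XtYnl <- Reduce(`+`, XtYn[trainP])[, featSet, drop = FALSE]
      Bn <- vapply(lambdaGrid, function(lam) .ridgePathSolve(eig, XtYnl, lam),
                   matrix(0, pDim, nFs))
      Bstack <- cbind(Bstack, matrix(Bn, pDim, nFs * nLam))
    }
    for (p in testP) {
      # word-span sample indices and their group labels for this part
      # (voiced spans of distinct words do not overlap)
      wordRows <- NULL; wordG <- NULL
      if (!is.null(wordSegments)) {
        w <- wordSegments[wordSegments$part == p, , drop = FALSE]
        if (nrow(w)) {
          w <- w[order(w$from), , drop = FALSE]
          lens <- w$to - w$from + 1
          wordRows <- unlist(mapply(seq, w$from, w$to, SIMPLIFY = FALSE))
          wordG <- rep(match(w$word, wordIds), lens)
        }
      }
      # restrict reconstruction to scored samples when only word spans
      # are evaluated (fixed-duration schemes need the full part)
      rowsNeeded <- if (!length(durations)) {
        if (is.null(wordRows)) integer(0) else wordRows
      } else NULL
      recon <- .laggedRecon(Rs[[p]], tau, Bstack, rows = rowsNeeded)
      rows <- attr(recon, "rows")
      truth <- Ys[[p]][rows, , drop = FALSE]
      nValid <- length(rows)
      gWords <- NULL
      if (!is.null(wordRows) && nValid > 0) {
        gWords <- integer(nValid)
        pos <- match(wordRows, rows)
        ok <- !is.na(pos)
        gWords[pos[ok]] <- wordG[ok]
      }
      # columns for feature j of model m are interleaved: Bm columns are
      # (featSet at lam1, featSet at lam2, ...) from the vapply layout
      colOf <- function(m, j) (m - 1) * nFs * nLam +
        (match(j, featSet) - 1) + seq(1, nFs * nLam, by = nFs)
      for (m in seq_along(modelTypes)) {
        for (j in featSet) {
          if (!j %in% scoreFeatures && !length(durations)) next
          cols <- colOf(m, j)
          Rj <- recon[, cols, drop = FALSE]
          # segment schemes
          for (d in durations) {
            g <- .fixedSegments(nValid, featureParts[[p]]@fs, d)
            gp <- .groupedPearson(Rj, truth[, j], g)
            ok <- !is.na(gp$r) & matrix(gp$n >= minLen, nrow(gp$r), ncol(gp$r))
            meanR <- colSums(ifelse(ok, gp$r, 0)) / pmax(colSums(ok), 1)
            meanR[colSums(ok) == 0] <- NA_real_
            segOut <- rbind(segOut, data.frame(
              fold = f, part = p, feature = j,
              scheme = paste0(format(d, trim = TRUE), "s"),
              lambdaN = lambdaGrid, modelType = modelTypes[m],
              meanR = meanR, nSegments = colSums(ok)[1],
              nSkipped = nrow(gp$r) - colSums(ok)[1]))
          }
          # per-word scoring over voiced spans
          if (!is.null(gWords) && j %in% scoreFeatures) {
            gp <- .groupedPearson(Rj, truth[, j], gWords)
            if (!is.null(gp$r)) {
              wordR[gp$ids, , j, m] <- gp$r
              flagged <- union(flagged, gp$ids[gp$n < minLen])
            }
          }
        }
      }
    }
  }
  if (!is.null(wordR))
    attr(wordR, "flaggedShort") <- wordIds[flagged]
  list(segmentScores = segOut, wordScores = wordR, folds = folds,
       lambdaGrid = lambdaGrid)
}

# --- duration comparison ----------------------------------------------------

# Friedman test with the documented ties convention: identical score
# columns (zero rank variance) give statistic 0, p = 1.
.friedmanSafe <- function(m) {
  ft <- suppressWarnings(try(friedman.test(m), silent = TRUE))
  if (inherits(ft, "try-error") || !is.finite(ft$statistic))
    return(list(statistic = 0, p.value = 1))
  list(statistic = unname(ft$statistic), p.value = ft$p.value)
}

# Paired Wilcoxon signed-rank with zero differences dropped; all-zero
# differences give p = 1. Exact distribution when n <= 25 and untied.
.wilcoxSafe <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0) return(1)
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  wt <- suppressWarnings(wilcox.test(d, exact = exact))
  wt$p.value
}

#' Compare reconstruction scores across evaluation segment durations
#'
#' Given one averaged reconstruction score per subject, feature and
#' segmentation scheme, runs per feature a Friedman test across schemes,
#' all pairwise Wilcoxon signed-rank post-hoc tests, and a per-scheme
#' paired comparison between the two features. Each family of p-values is
#' Benjamini-Yekutieli corrected separately.
#'
#' @param scores data.frame with columns `subject`, `feature` (1/2),
#'   `scheme`, `r` - one row per combination.
#' @return list with `friedman` (per feature), `pairwise` (per feature,
#'   data.frame of scheme pairs with raw and corrected p), and
#'   `featureComparison` (per scheme, f1 vs f2).
#' @export
segmentDurationComparison <- function(scores) {
  schemes <- unique(scores$scheme)
  subjects <- sort(unique(scores$subject))
  if (length(subjects) < 3) stop("Friedman test requires at least 3 subjects")
  getMat <- function(j) {
    m <- sapply(schemes, function(s)
      scores$r[scores$feature == j & scores$scheme == s][
        order(scores$subject[scores$feature == j & scores$scheme == s])])
    matrix(m, length(subjects), length(schemes),
           dimnames = list(NULL, schemes))
  }
  fried <- list(); pair <- list()
  for (j in 1:2) {
    m <- getMat(j)
    ft <- .friedmanSafe(m)
    fried[[paste0("f", j)]] <- data.frame(feature = j,
                                          statistic = ft$statistic,
                                          p = ft$p.value)
    cmb <- utils::combn(length(schemes), 2)
    praw <- apply(cmb, 2, function(ix) .wilcoxSafe(m[, ix[1]], m[, ix[2]]))
    pair[[paste0("f", j)]] <- data.frame(
      feature = j, schemeA = schemes[cmb[1, ]], schemeB = schemes[cmb[2, ]],
      pRaw = praw, pFdr = p.adjust(praw, method = "BY"))
  }
  m1 <- getMat(1); m2 <- getMat(2)
  pf <- vapply(seq_along(schemes), function(s) .wilcoxSafe(m1[, s], m2[, s]), 0)
  featureComparison <- data.frame(scheme = schemes, pRaw = pf,
                                  pFdr = p.adjust(pf, method = "BY"))
  list(friedman = do.call(rbind, fried),
       pairwise = do.call(rbind, pair),
       featureComparison = featureComparison)
}
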