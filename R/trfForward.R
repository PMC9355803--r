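# Forward modeling: complex-coefficient temporal response functions (TRFs)
# relating the two stimulus features (and their Hilbert transforms) to
# multichannel EEG through normalized ridge regression.

# Lagged design matrix. M is time-by-component; lags are integer sample
# lags (positive = stimulus precedes response). Only rows where every lag is
# in bounds are kept (no zero padding). Columns are ordered
# component-major: all lags of component 1, then all lags of component 2,
# etc., lags in grid order. Attribute "rows" holds the retained time
# indices of M.
.laggedDesign <- function(M, lags) {
  n <- nrow(M)
  t0 <- 1 + max(lags, 0)
  t1 <- n + min(lags, 0)
  if (t1 < t0) stop("recording shorter than the lag span")
  rows <- t0:t1
  nr <- length(rows)
  nc <- ncol(M)
  X <- matrix(0, nr, nc * length(lags))
  for (li in seq_along(lags)) {
    src <- rows - lags[li]
    X[, (seq_len(nc) - 1) * length(lags) + li] <- M[src, ]
  }
  attr(X, "rows") <- rows
  X
}

#' Build the Hilbert-augmented lagged design of the forward model
#'
#' Expands the two stimulus features and their Hilbert transforms into a
#' lagged design matrix with `4 * nLags` columns, ordered component-major
#' (`f1`, `f1h`, `f2`, `f2h`; all lags of a component contiguous, lags in
#' grid order). Only time samples where every lag is in bounds are used
#' (valid-sample convention, no zero padding), avoiding edge artifacts that
#' would bias short-latency estimates. Hilbert transforms are computed once
#' over the whole part before lagging.
#'
#' @param features a [StimulusFeatures-class] (standardized or not; callers
#'   that fit models standardize first).
#' @param lags a [LagGrid-class] whose `fs` matches the features.
#' @return design matrix with attribute `"rows"` (the retained time
#'   indices into the feature series).
#' @export
buildComplexLaggedDesign <- function(features, lags) {
  stopifnot(is(features, "StimulusFeatures"), is(lags, "LagGrid"))
  if (features@fs != lags@fs) stop("sampling rates of features and lag grid differ")
  M <- cbind(features@f1, hilbertImag(features@f1),
             features@f2, hilbertImag(features@f2))
  .laggedDesign(M, .lagSamples(lags))
}

.lagSamples <- function(lags)
  as.integer(round(lagTimes(lags) * lags@fs / 1000))

# Backward-model design lags: the decoder reconstructs the stimulus at t
# from EEG at t + tau (tau in [-5, 49] ms: EEG mostly AFTER the stimulus,
# where the lagged neural response lives, with a small acausal margin).
# .laggedDesign shifts by -lag, so the sample lags are negated.
.backwardLagSamples <- function(lags) -.lagSamples(lags)

# Ridge solution on the covariance scale:
#   (X'X/n + lambda_n * em * I) a = X'Y/n,  em = trace(X'X/n)/p.
# Returns the coefficient matrix (p x q).
.ridgeSolve <- function(XtX, XtY, n, lambdaN) {
  p <- ncol(XtX)
  C <- XtX / n
  em <- sum(diag(C)) / p
  A <- C + diag(lambdaN * em, p)
  a <- solve(A, XtY / n)
  attr(a, "em") <- em
  a
}

# Eigendecomposition path: solve the same system for many lambda_n from one
# symmetric eigendecomposition of X'X/n.
.ridgeEigen <- function(XtX, n) {
  C <- XtX / n
  e <- eigen(C, symmetric = TRUE)
  list(vectors = e$vectors, values = e$values,
       em = sum(e$values) / ncol(C), n = n)
}

.ridgePathSolve <- function(eig, XtY, lambdaN) {
  z <- crossprod(eig$vectors, XtY / eig$n)
  eig$vectors %*% (z / (eig$values + lambdaN * eig$em))
}

#' Ridge regression with normalized regularization
#'
#' Solves, per response column, `(X'X/n + lambda_n * em * I) a = X'Y/n`
#' where `em = trace(X'X/n)/p` is the mean eigenvalue of the design
#' covariance, so `lambda_n` is expressed in units of the average design
#' eigenvalue (`lambda = lambda_n * em`).
#'
#' @param X design matrix (standardized columns for model fits).
#' @param Y response matrix (same row count).
#' @param lambdaN normalized regularization parameter (>= 0).
#' @return coefficient matrix `p x q` with attribute `"em"`.
#' @export
ridgeFit <- function(X, Y, lambdaN = 1) {
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  .ridgeSolve(crossprod(X), crossprod(X, Y), nrow(X), lambdaN)
}

# Assemble the complex TRF from the stacked real coefficient matrix
# (component-major columns f1, f1h, f2, f2h).
.assembleComplexTRF <- function(a, lags, lambdaN, em, provenance = list()) {
  L <- lags@nLags
  nCh <- ncol(a)
  alpha <- array(complex(real = 0), dim = c(L, nCh, 2))
  for (j in 1:2) {
    re <- a[((2 * j - 2) * L + 1):((2 * j - 1) * L), , drop = FALSE]
    im <- a[((2 * j - 1) * L + 1):((2 * j) * L), , drop = FALSE]
    alpha[, , j] <- complex(real = re, imaginary = im)
  }
  new("ComplexTRF", alpha = alpha, lagGrid = lags, lambdaN = lambdaN,
      em = em, provenance = provenance)
}

#' Fit the complex forward TRF
#'
#' Fits the Hilbert-augmented forward model predicting every EEG channel
#' from both stimulus features simultaneously, by normalized ridge
#' regression, and assembles the paired real coefficients into complex
#' ones. Multiple recording parts may be passed as lists; each part is
#' standardized separately (features and EEG channels to zero mean, unit
#' sd), lagged designs are built per part and their Gram matrices summed.
#' EEG preprocessing (50-280 Hz band-pass, average reference) is the
#' caller's contract and is recorded in the provenance field.
#'
#' @param eeg an [EEGRecording-class], a time-by-channel matrix, or a list
#'   of these (recording parts).
#' @param features a [StimulusFeatures-class] or list of them, matching
#'   `eeg` part for part.
#' @param lags a [LagGrid-class]; defaults to the broad forward grid
#'   -250..499 ms (750 lags at 1 kHz).
#' @param lambdaN normalized regularization (default 1).
#' @param standardize standardize each part before fitting (default TRUE).
#' @param timeReversed fit the null model with time-reversed stimulus
#'   features (reversal applied per part before the Hilbert transform).
#' @return A [ComplexTRF-class].
#' @export
fitForwardTRF <- function(eeg, features, lags = lagGrid(-250, 499, 1000),
                          lambdaN = 1, standardize = TRUE,
                          timeReversed = FALSE) {
  eegParts <- .asPartList(eeg, "eeg")
  featParts <- .asPartList(features, "features")
  if (length(eegParts) != length(featParts))
    stop("eeg and features must have the same number of parts")
  tau <- .lagSamples(lags)
  XtX <- NULL; XtY <- NULL; n <- 0
  for (k in seq_along(eegParts)) {
    Y <- .partMatrix(eegParts[[k]])
    f <- featParts[[k]]
    f1 <- f@f1; f2 <- f@f2
    if (timeReversed) { f1 <- rev(f1); f2 <- rev(f2) }
    if (standardize) {
      f1 <- .standardize(f1); f2 <- .standardize(f2)
      Y <- .standardize(Y)
    }
    M <- cbind(f1, hilbertImag(f1), f2, hilbertImag(f2))
    if (nrow(Y) != nrow(M))
      stop("part ", k, ": EEG and features lengths differ")
    X <- .laggedDesign(M, tau)
    Yv <- Y[attr(X, "rows"), , drop = FALSE]
    if (is.null(XtX)) { XtX <- crossprod(X); XtY <- crossprod(X, Yv) }
    else { XtX <- XtX + crossprod(X); XtY <- XtY + crossprod(X, Yv) }
    n <- n + nrow(X)
  }
  a <- .ridgeSolve(XtX, XtY, n, lambdaN)
  .assembleComplexTRF(a, lags, lambdaN, attr(a, "em"),
                      provenance = list(standardized = standardize,
                                        timeReversed = timeReversed,
                                        nParts = length(eegParts),
                                        nSamples = n))
}

.asPartList <- function(x, what) {
  if (is.list(x) && !is(x, "EEGRecording") && !is(x, "StimulusFeatures"))
    x else list(x)
}

.partMatrix <- function(x) {
  if (is(x, "EEGRecording")) x@data else as.matrix(x)
}

#' Average complex TRFs across subjects
#'
#' Element-wise complex mean of subject-level TRFs (population model);
#' magnitudes are taken after averaging.
#'
#' @param trfs list of [ComplexTRF-class] with identical dimensions.
#' @return A [ComplexTRF-class].
#' @export
averageTRF <- function(trfs) {
  stopifnot(length(trfs) >= 1)
  alpha <- Reduce(`+`, lapply(trfs, function(t) t@alpha)) / length(trfs)
  out <- trfs[[1]]
  out@alpha <- alpha
  out@provenance <- c(out@provenance, list(nAveraged = length(trfs)))
  out
}

#' Summarize a complex TRF: magnitude, phase, lag profile, peak latency
#'
#' Magnitudes are the absolute values of the complex coefficients, phases
#' their angles. The lag profile is the channel-averaged magnitude per lag
#' and feature; the peak lag is its argmax per feature.
#'
#' @param trf a [ComplexTRF-class].
#' @return list with elements `magnitude` and `phase` (lag x channel x
#'   feature arrays), `profile` (lag x feature matrix), `lagsMs`, and
#'   `peakLagMs` (one per feature).
#' @export
trfSummary <- function(trf) {
  stopifnot(is(trf, "ComplexTRF"))
  mag <- Mod(trf@alpha)
  ph <- Arg(trf@alpha)
  profile <- apply(mag, c(1, 3), mean)
  lagsMs <- lagTimes(trf)
  peak <- lagsMs[apply(profile, 2, which.max)]
  list(magnitude = mag, phase = ph, profile = profile,
       lagsMs = lagsMs, peakLagMs = peak)
}

#' Bootstrap significance of TRF lags against time-reversed null models
#'
#' Resamples subjects with replacement, averages the resampled null TRFs
#' (fitted on time-reversed stimulus features), and records the
#' channel-averaged magnitude per lag of each draw. The observed statistic
#' is the same magnitude profile of the subject-averaged real TRFs. The
#' empirical p-value per lag uses the add-one estimator
#' `p = (1 + #draws >= observed) / (1 + nBoot)` (non-strict exceedance), so
#' p can never be exactly zero with a finite bootstrap. P-values are
#' corrected across lags, per feature, with the Benjamini-Yekutieli method,
#' and maximal runs with corrected p below `alpha` are reported as
#' significant latency ranges.
#'
#' @param subjectTrfs list of per-subject [ComplexTRF-class] (real models).
#' @param subjectNullTrfs list of matching null-model TRFs (same length).
#' @param nBoot number of bootstrap draws (>= 1).
#' @param seed integer seed; required for reproducibility.
#' @param alpha significance level applied to corrected p-values.
#' @return list of class `"LagSignificance"`: `profile` and `nullMean`
#'   (lag x feature), `pRaw`, `pFdr` (lag x feature), `lagsMs`,
#'   `significantRanges` (per feature, a matrix of ms intervals), `nBoot`.
#' @export
bootstrapLagSignificance <- function(subjectTrfs, subjectNullTrfs,
                                     nBoot = 10000, seed, alpha = 0.05) {
  if (missing(seed)) stop("a seed is required (reproducibility contract)")
  if (length(subjectTrfs) != length(subjectNullTrfs))
    stop("equal numbers of real and null subject models required")
  if (nBoot < 1) stop("nBoot must be >= 1")
  S <- length(subjectTrfs)
  d <- dim(subjectTrfs[[1]]@alpha)
  L <- d[1]; nCh <- d[2]; nF <- d[3]
  observed <- trfSummary(averageTRF(subjectTrfs))$profile
  # stack null coefficients: S x (L*nCh*nF), complex
  nullMat <- t(vapply(subjectNullTrfs,
                      function(t) as.vector(t@alpha),
                      complex(L * nCh * nF)))
  set.seed(seed)
  draws <- matrix(sample.int(S, nBoot * S, replace = TRUE), nBoot, S)
  exceed <- matrix(0L, L, nF)
  nullSum <- matrix(0, L, nF)
  chunk <- max(1L, as.integer(2e7 / (L * nCh * nF)))
  for (start in seq(1, nBoot, by = chunk)) {
    idx <- start:min(start + chunk - 1, nBoot)
    W <- matrix(0, length(idx), S)
    for (r in seq_along(idx)) {
      tab <- tabulate(draws[idx[r], ], nbins = S)
      W[r, ] <- tab / S
    }
    magAvg <- Mod(W %*% nullMat)               # draws x (L*nCh*nF)
    for (j in seq_len(nF)) {
      prof <- matrix(0, length(idx), L)        # channel-averaged profile
      for (cc in seq_len(nCh)) {
        cols <- (j - 1) * L * nCh + (cc - 1) * L + seq_len(L)
        prof <- prof + magAvg[, cols, drop = FALSE]
      }
      prof <- prof / nCh
      exceed[, j] <- exceed[, j] +
        colSums(prof >= matrix(observed[, j], length(idx), L, byrow = TRUE))
      nullSum[, j] <- nullSum[, j] + colSums(prof)
    }
  }
  pRaw <- (1 + exceed) / (1 + nBoot)
  pFdr <- apply(pRaw, 2, p.adjust, method = "BY")
  lagsMs <- lagTimes(subjectTrfs[[1]])
  ranges <- lapply(seq_len(nF), function(j) .runsToRanges(pFdr[, j] < alpha,
                                                         lagsMs))
  structure(list(profile = observed, nullMean = nullSum / nBoot,
                 pRaw = pRaw, pFdr = pFdr, lagsMs = lagsMs,
                 significantRanges = ranges, nBoot = nBoot, seed = seed),
            class = "LagSignificance")
}

.runsToRanges <- function(mask, lagsMs) {
  if (!any(mask)) return(matrix(numeric(0), 0, 2,
                                dimnames = list(NULL, c("fromMs", "toMs"))))
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  cbind(fromMs = lagsMs[starts[keep]], toMs = lagsMs[ends[keep]])
}

#' @export
print.LagSignificance <- function(x, ...) {
  cat(sprintf("LagSignificance: %d lags x %d features, %d bootstrap draws\n",
              nrow(x$pRaw), ncol(x$pRaw), x$nBoot))
  for (j in seq_len(ncol(x$pRaw))) {
    r <- x$significantRanges[[j]]
    if (nrow(r) == 0) cat(sprintf("  feature %d: no significant lags\n", j))
    else cat(sprintf("  feature %d: %s ms\n", j,
                     paste(sprintf("%g..%g", r[, 1], r[, 2]), collapse = ", ")))
  }
  invisible(x)
}
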