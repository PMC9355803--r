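# Relating population word scores to the seven word features: isolation
# forest outlier removal, then stepwise hierarchical robust regression with
# Huber weighting and Benjamini-Yekutieli-corrected coefficient p-values.

# Exact harmonic number H(m) via the digamma function.
.harmonic <- function(m) ifelse(m < 1, 0, digamma(m + 1) + 0.57721566490153286)

#' Average-path-length normalizer of the isolation forest
#'
#' `c(n) = 2 H(n-1) - 2 (n-1)/n`, the expected path length of an
#' unsuccessful binary-search-tree lookup among n points, computed with
#' exact harmonic numbers (so `isolationNormalizer(2) == 1`).
#'
#' @param n number of points (subsample or leaf size).
#' @return numeric normalizer, 0 for `n <= 1`.
#' @export
isolationNormalizer <- function(n)
  ifelse(n <= 1, 0, 2 * .harmonic(n - 1) - 2 * (n - 1) / n)

# Build one isolation tree on a subsample; returns flat node arrays.
.isolationTree <- function(x, heightLimit) {
  nMax <- 4 * nrow(x) + 8
  feat <- integer(nMax); splitv <- numeric(nMax)
  left <- integer(nMax); right <- integer(nMax)
  leafAdj <- numeric(nMax); isLeaf <- logical(nMax)
  nNodes <- 1L
  queue <- list(list(node = 1L, rows = seq_len(nrow(x)), depth = 0L))
  while (length(queue)) {
    it <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
    rows <- it$rows
    makeLeaf <- length(rows) <= 1 || it$depth >= heightLimit
    if (!makeLeaf) {
      f <- sample.int(ncol(x), 1)
      rng <- range(x[rows, f])
      if (rng[1] == rng[2]) {
        # try the remaining features once; identical points become a leaf
        cand <- sample(setdiff(seq_len(ncol(x)), f))
        f <- NA_integer_
        for (fc in cand) {
          rng2 <- range(x[rows, fc])
          if (rng2[1] < rng2[2]) { f <- fc; rng <- rng2; break }
        }
        if (is.na(f)) makeLeaf <- TRUE
      }
    }
    if (makeLeaf) {
      isLeaf[it$node] <- TRUE
      leafAdj[it$node] <- isolationNormalizer(length(rows))
      next
    }
    sv <- runif(1, rng[1], rng[2])
    goL <- x[rows, f] < sv
    feat[it$node] <- f; splitv[it$node] <- sv
    left[it$node] <- nNodes + 1L; right[it$node] <- nNodes + 2L
    nNodes <- nNodes + 2L
    queue[[length(queue) + 1]] <- list(node = left[it$node],
                                       rows = rows[goL],
                                       depth = it$depth + 1L)
    queue[[length(queue) + 1]] <- list(node = right[it$node],
                                       rows = rows[!goL],
                                       depth = it$depth + 1L)
  }
  list(feat = feat, splitv = splitv, left = left, right = right,
       leafAdj = leafAdj, isLeaf = isLeaf)
}

# Path lengths of all rows of x through one tree (vectorized level walk).
.isolationPaths <- function(tree, x) {
  n <- nrow(x)
  node <- rep(1L, n)
  depth <- numeric(n)
  active <- which(!tree$isLeaf[node])
  while (length(active)) {
    nd <- node[active]
    f <- tree$feat[nd]
    goL <- x[cbind(active, f)] < tree$splitv[nd]
    node[active] <- ifelse(goL, tree$left[nd], tree$right[nd])
    depth[active] <- depth[active] + 1
    active <- active[!tree$isLeaf[node[active]]]
  }
  depth + tree$leafAdj[node]
}

#' Isolation-forest outlier detection
#'
#' Builds `nTrees` random isolation trees on subsamples of the data and
#' scores every point by `s(x) = 2^(-E[h(x)] / c(psi))`, where `h(x)` is
#' the path length from root to the point's leaf (plus the normalizer
#' [isolationNormalizer()] of the leaf size when growth was truncated at
#' the height limit `ceil(log2 psi)`), and `psi` is the subsample size.
#' Points whose anomaly score exceeds the automatic threshold of 0.5 -
#' shorter-than-expected average paths - are flagged as outliers.
#' Deterministic given the seed.
#'
#' @param x numeric matrix (points x descriptors), finite.
#' @param nTrees number of trees (default 1000).
#' @param subsample per-tree subsample size (default 256, capped at n).
#' @param seed integer seed (required).
#' @param threshold anomaly-score threshold (default 0.5).
#' @return list: `inlier` (logical mask), `score` (anomaly scores),
#'   `threshold`, `nOutliers`.
#' @export
isolationForestOutliers <- function(x, nTrees = 1000, subsample = 256,
                                    seed, threshold = 0.5) {
  if (missing(seed)) stop("a seed is required (reproducibility contract)")
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("data must be finite")
  if (nTrees < 1) stop("nTrees must be >= 1")
  n <- nrow(x)
  psi <- min(subsample, n)
  heightLimit <- ceiling(log2(psi))
  set.seed(seed)
  pathSum <- numeric(n)
  for (b in seq_len(nTrees)) {
    rows <- sample.int(n, psi)
    tree <- .isolationTree(x[rows, , drop = FALSE], heightLimit)
    pathSum <- pathSum + .isolationPaths(tree, x)
  }
  avgPath <- pathSum / nTrees
  score <- 2^(-avgPath / isolationNormalizer(psi))
  inlier <- score <= threshold
  list(inlier = inlier, score = score, threshold = threshold,
       nOutliers = sum(!inlier))
}

#' Single-predictor Huber robust regression (no intercept)
#'
#' Iteratively reweighted least squares with Huber weights
#' `w(e) = min(1, k s / |e|)`, tuning constant `k = 1.345`, scale `s`
#' re-estimated each iteration as the MAD of the residuals. Both sides are
#' assumed standardized, so no intercept is fitted. The standard error
#' uses the asymptotic sandwich of the Huber estimating equation, with a
#' two-sided normal p-value.
#'
#' @param x standardized predictor (not constant).
#' @param y standardized response.
#' @param k Huber tuning constant.
#' @param maxit maximum IRLS iterations.
#' @param tol convergence threshold on the coefficient change.
#' @param conf confidence level of the interval.
#' @return list: `coeff`, `se`, `z`, `p`, `ci` (length 2), `iterations`,
#'   `scale`.
#' @export
huberFit <- function(x, y, k = 1.345, maxit = 200, tol = 1e-8,
                     conf = 0.95) {
  n <- length(x)
  if (n < 10) stop("need at least 10 observations")
  if (sd(x) == 0) stop("predictor is constant")
  if (length(y) != n) stop("x and y must have equal length")
  a <- sum(x * y) / sum(x * x)           # OLS start
  for (it in seq_len(maxit)) {
    e <- y - a * x
    s <- mad(e, center = 0)
    if (s < 1e-12) { s <- 0; break }     # (near-)exact fit
    w <- pmin(1, k * s / abs(e))
    w[e == 0] <- 1
    aNew <- sum(w * x * y) / sum(w * x * x)
    delta <- abs(aNew - a)
    a <- aNew
    if (delta < tol) break
    if (it == maxit)
      stop("Huber IRLS did not converge after ", maxit,
           " iterations (last change ", format(delta), ")")
  }
  e <- y - a * x
  if (s == 0) {
    se <- .Machine$double.eps
  } else {
    r <- e / s
    psi <- pmax(-k, pmin(k, r))
    dpsi <- as.numeric(abs(r) <= k)
    num <- sum(x^2 * psi^2) * s^2
    den <- sum(x^2 * dpsi)^2
    se <- sqrt(n / (n - 1) * num / den)
  }
  z <- a / se
  p <- 2 * pnorm(-abs(z))
  qz <- qnorm(1 - (1 - conf) / 2)
  list(coeff = a, se = se, z = z, p = p, ci = c(a - qz * se, a + qz * se),
       iterations = it, scale = s)
}

#' Stepwise hierarchical robust regression of word scores on word features
#'
#' Walks the fixed feature hierarchy: fits [huberFit()] of the current
#' residual scores on the next feature, records its statistics, subtracts
#' the fitted values, and repeats until all features are used. Shared
#' variance is thereby assigned conservatively to earlier (acoustic)
#' features; later (linguistic) coefficients reflect only variance not
#' explained before. The seven coefficient p-values are jointly
#' Benjamini-Yekutieli corrected.
#'
#' @param features matrix or data.frame (words x 7) of standardized
#'   features, columns named as in [wordFeatureOrder()].
#' @param scores standardized population word scores.
#' @param order feature order (names or indices); default the canonical
#'   hierarchy.
#' @param conf confidence level for the intervals.
#' @return data.frame with one row per feature in hierarchy order:
#'   `feature`, `coeff`, `se`, `ciLo`, `ciHi`, `z`, `pRaw`, `pFdr`;
#'   attributes `"residualVariance"` (variance path across steps, length
#'   8 starting at the input variance) and `"nRetained"`.
#' @export
stepwiseHierarchical <- function(features, scores,
                                 order = wordFeatureOrder(), conf = 0.95) {
  features <- as.matrix(as.data.frame(features)[, order, drop = FALSE])
  n <- nrow(features)
  if (length(scores) != n)
    stop("scores and features must describe the same words")
  res <- scores
  out <- vector("list", ncol(features))
  rv <- numeric(ncol(features) + 1)
  rv[1] <- var(res)
  for (kk in seq_len(ncol(features))) {
    fit <- huberFit(features[, kk], res, conf = conf)
    out[[kk]] <- data.frame(feature = colnames(features)[kk],
                            coeff = fit$coeff, se = fit$se,
                            ciLo = fit$ci[1], ciHi = fit$ci[2],
                            z = fit$z, pRaw = fit$p)
    res <- res - fit$coeff * features[, kk]
    rv[kk + 1] <- var(res)
  }
  tab <- do.call(rbind, out)
  tab$pFdr <- p.adjust(tab$pRaw, method = "BY")
  rownames(tab) <- NULL
  structure(tab, residualVariance = rv, nRetained = n)
}

#' Outlier removal plus stepwise hierarchical regression
#'
#' The full word-level analysis for one stimulus feature: standardize the
#' seven features and the population scores, remove outliers with the
#' isolation forest run on the eight standardized descriptors (seven
#' features + score), then run [stepwiseHierarchical()] on the retained
#' words.
#'
#' @param features data.frame (words x 7), columns of [wordFeatureOrder()].
#' @param scores population word scores (same length).
#' @param seed seed for the isolation forest.
#' @param nTrees,subsample isolation-forest parameters.
#' @param outlierRemoval set `FALSE` to skip the outlier step.
#' @return the [stepwiseHierarchical()] table with extra attributes
#'   `"nInput"`, `"nRetained"`, `"outlierScores"`.
#' @export
wordLevelRegression <- function(features, scores, seed = 1,
                                nTrees = 1000, subsample = 256,
                                outlierRemoval = TRUE) {
  keep <- stats::complete.cases(features) & is.finite(scores)
  features <- features[keep, , drop = FALSE]
  scores <- scores[keep]
  Z <- apply(as.matrix(features[, wordFeatureOrder()]), 2, .standardize)
  zs <- .standardize(scores)
  outlierScores <- NULL
  if (outlierRemoval) {
    iso <- isolationForestOutliers(cbind(Z, score = zs), nTrees = nTrees,
                                   subsample = subsample, seed = seed)
    outlierScores <- iso$score
    Z <- Z[iso$inlier, , drop = FALSE]
    zs <- zs[iso$inlier]
    # re-standardize over the retained words
    Z <- apply(Z, 2, .standardize)
    zs <- .standardize(zs)
  }
  tab <- stepwiseHierarchical(Z, zs)
  attr(tab, "nInput") <- sum(keep)
  attr(tab, "nRetained") <- length(zs)
  attr(tab, "outlierScores") <- outlierScores
  tab
}
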