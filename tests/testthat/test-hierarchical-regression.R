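# Isolation-forest outlier removal and stepwise hierarchical Huber
# regression.

test_that("the path-length normalizer uses exact harmonic numbers", {
  expect_equal(isolationNormalizer(2), 1)            # 2 H(1) - 2*(1/2)
  expect_equal(isolationNormalizer(1), 0)
  # closed form at n = 256
  H255 <- sum(1 / (1:255))
  expect_equal(isolationNormalizer(256), 2 * H255 - 2 * 255 / 256)
  # a point isolated at the root of every tree in a 256-subsample
  s <- 2^(-1 / isolationNormalizer(256))
  expect_equal(s, 2^(-1 / (2 * H255 - 510 / 256)))
})

test_that("an extreme point is flagged as outlier, identical data are not", {
  set.seed(11)
  x <- rbind(matrix(rnorm(1000 * 3), 1000, 3), rep(10, 3))
  iso <- isolationForestOutliers(x, nTrees = 200, seed = 5)
  expect_false(iso$inlier[1001])
  expect_gt(iso$score[1001], 0.5)
  expect_gt(mean(iso$inlier[1:1000]), 0.8)
  same <- matrix(1, 50, 3)
  iso2 <- isolationForestOutliers(same, nTrees = 50, seed = 5)
  expect_true(all(iso2$inlier))
  # deterministic given the seed
  iso3 <- isolationForestOutliers(x, nTrees = 200, seed = 5)
  expect_identical(iso$score, iso3$score)
  expect_error(isolationForestOutliers(x, nTrees = 10), "seed")
})

test_that("huberFit recovers exact and contaminated slopes", {
  set.seed(12)
  x <- rnorm(500)
  fit <- huberFit(x, 0.5 * x)
  expect_lt(abs(fit$coeff - 0.5), 1e-8)
  expect_lt(fit$p, 1e-10)
  # 1% gross leverage outliers: Huber beats OLS in every replicate
  for (s in 1:5) {
    set.seed(s)
    n <- 1000
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n, 0, 0.5)
    bad <- sample(n, n / 100)
    x[bad] <- 20; y[bad] <- 20
    hub <- huberFit(x, y)$coeff
    ols <- sum(x * y) / sum(x * x)
    expect_lt(abs(hub - 0.5), abs(ols - 0.5))
  }
  expect_error(huberFit(rep(1, 20), rnorm(20)), "constant")
  expect_error(huberFit(rnorm(5), rnorm(5)), "at least 10")
})

test_that("huberFit agrees with an independent M-estimator", {
  skip_if_not_installed("MASS")
  set.seed(13)
  x <- rnorm(2000)
  y <- 0.3 * x + rnorm(2000)
  y[1:20] <- y[1:20] + 15
  ours <- huberFit(x, y)
  ref <- MASS::rlm(y ~ x - 1, k = 1.345, maxit = 200, acc = 1e-10,
                   scale.est = "MAD")
  expect_lt(abs(ours$coeff - unname(coef(ref))), 0.01)
  expect_lt(abs(ours$se / summary(ref)$coefficients[1, 2] - 1), 0.3)
})

test_that("huber null calibration: independent x,y rarely significant", {
  hits <- 0
  for (s in 1:50) {
    set.seed(s + 100)
    f <- huberFit(rnorm(500), rnorm(500))
    if (f$p < 0.05) hits <- hits + 1
    expect_lt(abs(f$coeff), 0.2)
  }
  expect_lte(hits, 8)                     # ~5% nominal
})

test_that("stepwise regression equals simple slopes for orthogonal features", {
  set.seed(14)
  n <- 4000
  Q <- qr.Q(qr(matrix(rnorm(n * 7), n, 7))) * sqrt(n)   # orthonormal cols
  colnames(Q) <- wordFeatureOrder()
  beta <- c(-0.2, 0.1, 0, 0.05, 0, -0.1, 0)
  y <- as.numeric(Q %*% beta + rnorm(n, 0, 0.1))
  # exact identity in the linear limit: an OLS stepwise oracle written
  # here independently must reproduce the simple OLS slopes to machine
  # precision, in any order
  olsStep <- function(X, yy, ord) {
    res <- yy
    coefs <- numeric(ncol(X)); names(coefs) <- ord
    for (nm in ord) {
      a <- sum(X[, nm] * res) / sum(X[, nm]^2)
      coefs[nm] <- a
      res <- res - a * X[, nm]
    }
    coefs
  }
  simpleOls <- vapply(wordFeatureOrder(), function(k)
    sum(Q[, k] * y) / sum(Q[, k]^2), 0)
  s1 <- olsStep(Q, y, wordFeatureOrder())
  s2 <- olsStep(Q, y, rev(wordFeatureOrder()))
  expect_lt(max(abs(s1 - simpleOls)), 1e-6)
  expect_lt(max(abs(s2[wordFeatureOrder()] - simpleOls)), 1e-6)
  # with Huber weighting active the identity holds up to the (small)
  # nonlinearity of the reweighting
  tab <- stepwiseHierarchical(Q, y)
  simple <- vapply(1:7, function(k) huberFit(Q[, k], y)$coeff, 0)
  expect_lt(max(abs(tab$coeff - simple)), 0.01)
  perm <- rev(wordFeatureOrder())
  tabP <- stepwiseHierarchical(Q, y, order = perm)
  expect_lt(max(abs(sort(tabP$coeff) - sort(tab$coeff))), 0.01)
  # residual variance never increases across steps
  rv <- attr(tab, "residualVariance")
  expect_true(all(diff(rv) <= 1e-12))
})

test_that("correlated features make the stepwise coefficients order-dependent", {
  set.seed(15)
  n <- 3000
  z <- rnorm(n)
  X <- sapply(1:7, function(k) 0.7 * z + rnorm(n))
  colnames(X) <- wordFeatureOrder()
  y <- X[, 1] + rnorm(n)
  t1 <- stepwiseHierarchical(X, y)
  t2 <- stepwiseHierarchical(X, y, order = rev(wordFeatureOrder()))
  c1 <- t1$coeff[t1$feature == "interaction"]
  c2 <- t2$coeff[t2$feature == "interaction"]
  expect_gt(abs(c1 - c2), 0.05)
})

test_that("pure-noise scores yield no BY-significant features", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s + 300)
    X <- matrix(rnorm(5000 * 7), 5000, 7)
    colnames(X) <- wordFeatureOrder()
    tab <- stepwiseHierarchical(X, rnorm(5000))
    if (any(tab$pFdr < 0.05)) hits <- hits + 1
  }
  expect_lte(hits, 2)
})

test_that("planted coefficients with realistic feature correlations are recovered", {
  C <- defaultFeatureCorrelation()
  ch <- chol(C)
  recovered <- 0
  for (s in 1:5) {
    set.seed(s + 400)
    X <- matrix(rnorm(5732 * 7), 5732, 7) %*% ch
    colnames(X) <- wordFeatureOrder()
    y <- -0.17 * X[, 1] - 0.07 * X[, 2] - 0.04 * X[, 4] + rnorm(5732)
    tab <- stepwiseHierarchical(apply(X, 2, scale), as.numeric(scale(y)))
    ok <- tab$coeff[1] < 0 && tab$pFdr[1] < 0.05 &&
      tab$coeff[2] < 0 && tab$pFdr[2] < 0.05
    recovered <- recovered + ok
  }
  expect_gte(recovered, 5 * 0.9 - 1e-9)
})

test_that("outlier removal on clean data changes coefficients by less than one SE", {
  set.seed(16)
  n <- 3000
  X <- matrix(rnorm(n * 7), n, 7)
  colnames(X) <- wordFeatureOrder()
  y <- -0.2 * X[, 1] + rnorm(n)
  df <- as.data.frame(X)
  with0 <- wordLevelRegression(df, y, seed = 1, nTrees = 300,
                               outlierRemoval = FALSE)
  with1 <- wordLevelRegression(df, y, seed = 1, nTrees = 300,
                               outlierRemoval = TRUE)
  expect_true(all(abs(with0$coeff - with1$coeff) < with0$se + with1$se))
})
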