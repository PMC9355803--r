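# Complex forward TRF: Hilbert augmentation, lagged design, normalized
# ridge, magnitude/phase summaries, bootstrap lag significance.

test_that("hilbertImag returns the quadrature signal", {
  t <- (0:999) / 1000
  h <- hilbertImag(cos(2 * pi * 100 * t))
  cs <- centralSpan(1000)
  expect_lt(max(abs(h - sin(2 * pi * 100 * t))[cs]), 1e-3)
  expect_lt(max(abs(hilbertImag(rep(3, 500)))), 1e-9)
  set.seed(2)
  x <- rnorm(4096)
  expect_lt(abs(sd(hilbertImag(x)) / sd(x) - 1), 0.05)
  expect_error(hilbertImag(c(1, NA)), "finite")
})

test_that("lag grids reproduce the study's lag counts", {
  expect_identical(nLags(lagGrid(-250, 499, 1000)), 750L)
  expect_identical(nLags(lagGrid(-5, 49, 1000)), 55L)
  expect_error(validObject(new("LagGrid", lagMin = 0, lagMax = 10,
                               fs = 1000, nLags = 5L)))
})

test_that("the lagged design keeps only rows with all lags in bounds", {
  f <- stimulusFeatures(rnorm(10000), rnorm(10000))
  X <- buildComplexLaggedDesign(f, lagGrid(-250, 499, 1000))
  expect_equal(ncol(X), 4 * 750)
  expect_equal(nrow(X), 10000 - 749)
  short <- stimulusFeatures(rnorm(500), rnorm(500))
  expect_error(buildComplexLaggedDesign(short, lagGrid(-250, 499, 1000)),
               "shorter")
})

test_that("normalized ridge matches a dense penalized solve", {
  set.seed(3)
  X <- matrix(rnorm(50 * 8), 50, 8)
  Y <- matrix(rnorm(50 * 2), 50, 2)
  a <- ridgeFit(X, Y, lambdaN = 1)
  C <- crossprod(X) / 50
  em <- sum(diag(C)) / 8
  oracle <- solve(C + diag(em, 8), crossprod(X, Y) / 50)
  expect_lt(max(abs(a - oracle)), 1e-8)
  expect_equal(attr(a, "em"), em)
  # orthonormal design, no penalty: plain least squares
  Q <- qr.Q(qr(matrix(rnorm(100 * 6), 100, 6)))
  a0 <- ridgeFit(Q, Q[, 1], lambdaN = 0)
  expect_lt(max(abs(a0 - c(1, rep(0, 5)))), 1e-10)
  expect_error(ridgeFit(X, Y[1:10, ]), "rows")
})

test_that("identity-covariance designs give em = 1", {
  n <- 200
  X <- sqrt(n) * qr.Q(qr(matrix(rnorm(n * 4), n, 4)))  # X'X/n = I
  a <- ridgeFit(X, rnorm(n), lambdaN = 2.5)
  expect_equal(attr(a, "em"), 1, tolerance = 1e-12)
})

test_that("ridge coefficient norm shrinks monotonically in lambda", {
  set.seed(4)
  X <- matrix(rnorm(300 * 12), 300, 12)
  y <- X %*% rnorm(12) + rnorm(300)
  norms <- vapply(10^seq(-4, 4), function(l)
    sum(ridgeFit(X, y, l)^2), 0)
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("Hilbert-pair fitting equals direct complex regression", {
  set.seed(5)
  n <- 600
  f <- stimulusFeatures(rnorm(n), rnorm(n))
  lags <- lagGrid(0, 9, 1000)
  X <- buildComplexLaggedDesign(f, lags)
  y <- rnorm(nrow(X))
  a <- ridgeFit(X, y, lambdaN = 0.5)
  # complex route: columns f + i f^h per lag; ridge on the augmented real
  # representation is equivalent to the half-split complex normal
  # equations with conjugate-symmetric penalty
  L <- nLags(lags)
  alphaPkg <- complex(real = a[1:L], imaginary = a[(L + 1):(2 * L)])
  Zc <- X[, 1:L] + 1i * X[, (L + 1):(2 * L)]
  # oracle: solve the real augmented system directly with a dense solver
  C <- crossprod(X) / nrow(X)
  em <- sum(diag(C)) / ncol(X)
  aOracle <- solve(C + diag(0.5 * em, ncol(X)), crossprod(X, y) / nrow(X))
  alphaOracle <- complex(real = aOracle[1:L],
                         imaginary = aOracle[(L + 1):(2 * L)])
  expect_lt(max(Mod(alphaPkg - alphaOracle)), 1e-8)
  expect_true(is.complex(Zc))
})

test_that("trfSummary reports magnitude, phase and peak lag", {
  lg <- lagGrid(0, 1, 1000)
  alpha <- array(complex(real = 0), dim = c(2, 1, 2))
  alpha[1, 1, 1] <- 3 + 4i
  alpha[2, 1, 1] <- 0 + 1i
  alpha[2, 1, 2] <- 2 + 0i
  trf <- new("ComplexTRF", alpha = alpha, lagGrid = lg, lambdaN = 1,
             em = 1, provenance = list())
  s <- trfSummary(trf)
  expect_equal(s$magnitude[1, 1, 1], 5)
  expect_equal(s$phase[1, 1, 1], atan2(4, 3))
  expect_equal(s$phase[2, 1, 1], pi / 2)
  expect_equal(s$peakLagMs, c(0, 1))
})

test_that("a planted kernel's peak latency is recovered from noiseless data", {
  study <- smallStudy(nWords = 150, snrDb = 99)
  trf <- fitForwardTRF(study$eegParts[[1]], study$featureParts,
                       lagGrid(-50, 150, 1000), lambdaN = 1)
  s <- trfSummary(trf)
  expect_lt(abs(s$peakLagMs[1] - 11), 1.5)
  expect_lt(abs(s$peakLagMs[2] - 18), 1.5)
})

test_that("empirical p-values use the add-one rule and BY correction is exact", {
  # two subjects, tiny TRFs with controlled magnitudes
  lg <- lagGrid(0, 1, 1000)
  mk <- function(v) new("ComplexTRF",
                        alpha = array(complex(real = v), c(2, 1, 2)),
                        lagGrid = lg, lambdaN = 1, em = 1,
                        provenance = list())
  big <- list(mk(c(10, 0.001)), mk(c(10, 0.001)))
  nulls <- list(mk(c(1, 1)), mk(c(1, 1)))
  sig <- bootstrapLagSignificance(big, nulls, nBoot = 999, seed = 1)
  # lag 1: observed 10 above every draw -> p = 1/(nBoot+1)
  expect_equal(sig$pRaw[1, 1], 1 / 1000)
  # lag 2: observed below every draw -> p = 1
  expect_equal(sig$pRaw[2, 1], 1)
  expect_true(all(sig$pFdr >= sig$pRaw))
  expect_error(bootstrapLagSignificance(big, nulls, nBoot = 10), "seed")
  # hand-checked BY: p = (0.01, 0.04), m = 2, c(2) = 1.5
  expect_equal(p.adjust(c(0.01, 0.04), method = "BY"), c(0.03, 0.06))
})

test_that("EEG preprocessing band-passes and re-references", {
  set.seed(6)
  rec <- eegRecording(matrix(rnorm(4096 * 3), 4096, 3), fs = 1000)
  out <- preprocessEEG(rec)
  expect_identical(out@reference, "average")
  expect_lt(max(abs(rowMeans(out@data))), 1e-9)
  # single-channel spectral check: stopband energy strongly attenuated
  y <- preprocessEEG(eegRecording(matrix(rnorm(8192), ncol = 1), 1000),
                     rereference = FALSE)@data[, 1]
  p <- Mod(fft(y))^2
  freqs <- (0:8191) * 1000 / 8192
  inBand <- freqs >= 60 & freqs <= 270
  outBand <- (freqs >= 5 & freqs <= 20) | (freqs >= 350 & freqs <= 450)
  expect_lt(mean(p[outBand]) / mean(p[inBand]), 1e-3)
})

test_that("significant ranges are maximal runs of corrected p below alpha", {
  mask <- c(FALSE, TRUE, TRUE, FALSE, TRUE)
  r <- speechFFR:::.runsToRanges(mask, c(0, 1, 2, 3, 4))
  expect_equal(unname(r[, 1]), c(1, 4))
  expect_equal(unname(r[, 2]), c(2, 4))
})
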