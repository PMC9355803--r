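# Backward decoders: grids, reconstruction, segment scoring,
# cross-validation, duration comparison statistics.

test_that("the default grids have the study dimensions", {
  expect_length(defaultLambdaGrid(), 51)
  expect_equal(range(defaultLambdaGrid()), c(1e-10, 1e10))
  expect_identical(nLags(backwardLagGrid()), 55L)
  dec <- fitBackwardDecoders(matrix(rnorm(3000 * 2), 3000, 2),
                             stimulusFeatures(rnorm(3000), rnorm(3000)))
  expect_length(dec, 51)
  expect_equal(dim(dec[[1]]@beta), c(55, 2, 2))
  expect_error(fitBackwardDecoders(matrix(rnorm(100), 50, 2),
                                   stimulusFeatures(rnorm(50), rnorm(50)),
                                   lambdaGrid = numeric(0)), "nonempty")
})

test_that("an EEG channel that copies a feature is decoded almost perfectly", {
  set.seed(20)
  n <- 4000
  f1 <- as.numeric(arima.sim(list(ar = 0.9), n))
  f2 <- rnorm(n)
  feats <- stimulusFeatures(f1, f2)
  eeg <- cbind(f1, rnorm(n))
  dec <- fitBackwardDecoders(eeg, feats, lambdaGrid = 1e-10)
  recon <- reconstructFeatures(dec[[1]], eeg)
  truth <- scale(f1)[attr(recon, "rows")]
  expect_gt(cor(recon[, 1], truth), 0.999)
})

test_that("segment evaluation scores perfect and null reconstructions correctly", {
  set.seed(21)
  n <- 6000
  f1 <- as.numeric(arima.sim(list(ar = 0.8), n))
  feats <- stimulusFeatures(f1, rnorm(n))
  eeg <- cbind(f1, rnorm(n))                      # channel 1 = truth
  dec <- fitBackwardDecoders(eeg, feats, lambdaGrid = 1e-10)
  seg <- evaluateSegments(dec[[1]], eeg, feats,
                          scheme = list(mode = "fixed_duration", duration = 1))
  r1 <- seg$r[seg$feature == 1]
  expect_true(all(r1 > 0.99))
  # noise decoder: independent EEG
  set.seed(22)
  eegN <- matrix(rnorm(2 * n), n, 2)
  decN <- fitBackwardDecoders(eegN, feats, lambdaGrid = 1)
  segN <- evaluateSegments(decN[[1]], matrix(rnorm(2 * n), n, 2), feats,
                           scheme = list(mode = "fixed_duration",
                                         duration = 0.05))
  expect_lt(abs(mean(segN$r[segN$feature == 1])), 0.06)
  expect_gt(sum(segN$feature == 1), 100)
})

test_that("short and zero-variance segments are skipped and counted", {
  n <- 1000
  feats <- stimulusFeatures(rnorm(n), rnorm(n))
  eeg <- matrix(rnorm(2 * n), n, 2)
  dec <- fitBackwardDecoders(eeg, feats, lambdaGrid = 1)
  seg <- evaluateSegments(dec[[1]], eeg, feats,
                          scheme = list(mode = "fixed_duration",
                                        duration = 0.01), minLen = 20)
  expect_equal(nrow(seg), 0)              # all segments shorter than minLen
  expect_gt(attr(seg, "nSkipped"), 0)
})

test_that("contiguous folds are deterministic and respect part boundaries", {
  expect_equal(speechFFR:::.assignFolds(rep(100, 5), 5), 1:5)
  expect_equal(speechFFR:::.assignFolds(rep(100, 10), 5),
               rep(1:5, each = 2))
  expect_error(speechFFR:::.assignFolds(rep(100, 3), 5), "exceeds")
  expect_error(speechFFR:::.assignFolds(rep(100, 5), 1), ">= 2")
})

test_that("cross-validated fold scores agree for symmetric synthetic parts", {
  set.seed(23)
  n <- 4096
  mk <- function() {
    f1 <- as.numeric(arima.sim(list(ar = 0.8), n))
    f2 <- as.numeric(arima.sim(list(ar = 0.8), n))
    feats <- stimulusFeatures(f1, f2)
    eeg <- cbind(f1 + 0.5 * rnorm(n), f2 + 0.5 * rnorm(n))
    list(feats = feats, eeg = eeg)
  }
  p1 <- mk(); p2 <- mk()
  cv <- crossValidateDecoders(list(p1$eeg, p2$eeg),
                              list(p1$feats, p2$feats),
                              lambdaGrid = 1, k = 2, durations = 1)
  s <- cv$segmentScores
  r1 <- s$meanR[s$fold == 1 & s$feature == 1 & s$modelType == "model"]
  r2 <- s$meanR[s$fold == 2 & s$feature == 1 & s$modelType == "model"]
  expect_lt(abs(r1 - r2), 0.05)
  # model beats its time-reversed null
  rn <- s$meanR[s$feature == 1 & s$modelType == "null"]
  expect_gt(mean(c(r1, r2)), mean(rn) + 0.2)
})

test_that("cross-validated scores are invariant to channel permutation", {
  set.seed(27)
  n <- 4096
  mk <- function() {
    f1 <- as.numeric(arima.sim(list(ar = 0.8), n))
    feats <- stimulusFeatures(f1, rnorm(n))
    eeg <- cbind(f1 + rnorm(n), rnorm(n), 0.5 * f1 + rnorm(n))
    list(feats = feats, eeg = eeg)
  }
  p1 <- mk(); p2 <- mk()
  run <- function(perm) {
    cv <- crossValidateDecoders(list(p1$eeg[, perm], p2$eeg[, perm]),
                                list(p1$feats, p2$feats),
                                lambdaGrid = c(0.1, 10), k = 2,
                                durations = 1)
    cv$segmentScores$meanR
  }
  expect_equal(run(1:3), run(c(3, 1, 2)), tolerance = 1e-10)
})

test_that("duration comparison handles ties, shifts and identical pairs", {
  set.seed(24)
  base <- rnorm(13, 0.2, 0.05)
  schemes <- c("0.1s", "1s", "10s")
  mkScores <- function(shift3 = 0) {
    do.call(rbind, lapply(1:2, function(j)
      do.call(rbind, lapply(seq_along(schemes), function(s)
        data.frame(subject = 1:13, feature = j, scheme = schemes[s],
                   r = base + if (s == 3) shift3 else 0)))))
  }
  same <- segmentDurationComparison(mkScores(0))
  expect_equal(same$friedman$statistic, c(0, 0))
  expect_equal(same$friedman$p, c(1, 1))
  expect_true(all(same$pairwise$pFdr == 1))
  expect_true(all(same$featureComparison$pFdr == 1))
  shifted <- segmentDurationComparison(mkScores(10 * 0.05))
  pw <- shifted$pairwise
  hit <- pw$pFdr[pw$schemeA != pw$schemeB & (pw$schemeA == "10s" |
                                               pw$schemeB == "10s")]
  expect_true(all(hit < 0.01))
  expect_error(segmentDurationComparison(
    data.frame(subject = 1:2, feature = 1, scheme = "1s", r = 0)),
    "at least 3")
})

test_that("segmentation granularity leaves stationary scores unchanged", {
  set.seed(25)
  n <- 30000
  f1 <- as.numeric(arima.sim(list(ar = 0.8), n))
  feats <- stimulusFeatures(f1, rnorm(n))
  eeg <- cbind(f1 + rnorm(n), rnorm(n))
  dec <- fitBackwardDecoders(eeg, feats, lambdaGrid = 1)
  s1 <- evaluateSegments(dec[[1]], eeg, feats,
                         scheme = list(mode = "fixed_duration", duration = 1))
  s30 <- evaluateSegments(dec[[1]], eeg, feats,
                          scheme = list(mode = "fixed_duration",
                                        duration = 29.9))
  fisher <- function(r) tanh(mean(atanh(r)))
  expect_lt(abs(fisher(s1$r[s1$feature == 1]) -
                  fisher(s30$r[s30$feature == 1])), 0.1)
})

test_that("lambda-grid refinement never lowers the per-segment maximum", {
  set.seed(26)
  n <- 5000
  f1 <- as.numeric(arima.sim(list(ar = 0.8), n))
  feats <- stimulusFeatures(f1, rnorm(n))
  eeg <- cbind(f1 + 2 * rnorm(n), rnorm(n))
  coarse <- 10^seq(-4, 4, length.out = 5)
  fine <- 10^seq(-4, 4, length.out = 9)     # superset of coarse
  decC <- fitBackwardDecoders(eeg, feats, lambdaGrid = coarse)
  decF <- fitBackwardDecoders(eeg, feats, lambdaGrid = fine)
  segMax <- function(decs) {
    rs <- vapply(decs, function(d) {
      s <- evaluateSegments(d, eeg, feats,
                            scheme = list(mode = "fixed_duration",
                                          duration = 2))
      mean(s$r[s$feature == 1])
    }, 0)
    max(rs)
  }
  expect_gte(segMax(decF), segMax(decC) - 1e-12)
})
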