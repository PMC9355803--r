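# Synthetic-study generators: toy language model, copula word features,
# stimulus synthesis, planted-kernel EEG.

test_that("toy language model is a valid chain with exact stationary law", {
  lm <- toyLanguageModel(nTokens = 10, seed = 1)
  expect_true(validObject(lm))
  expect_lt(max(abs(drop(lm@unigram %*% lm@transition) - lm@unigram)), 1e-9)
  er <- entropyRate(lm)
  expect_gt(er, 0)
  expect_lte(er, log(10))
})

test_that("uniform and deterministic chains give closed-form features", {
  K <- 4
  lm <- new("ToyLanguageModel", vocabulary = letters[1:K],
            transition = matrix(1 / K, K, K), unigram = rep(1 / K, K))
  st <- generateWordStream(lm, 50, seed = 2)
  expect_true(all(abs(st$surprisal - log(4)) < 1e-12))
  expect_true(all(abs(st$precision - 1 / log(4)) < 1e-12))
  # deterministic cycle: zero surprisal and clamped precision
  P <- diag(K)[c(2:K, 1), ]
  det <- new("ToyLanguageModel", vocabulary = letters[1:K],
             transition = P, unigram = rep(1 / K, K))
  std <- generateWordStream(det, 20, seed = 3)
  expect_true(all(std$surprisal[-1] == 0))
  expect_true(all(std$clamped[-1]))
  expect_true(all(std$precision[-1] == 1e6))
})

test_that("mean surprisal converges to the entropy rate (AEP)", {
  lm <- toyLanguageModel(nTokens = 15, concentration = 0.7, seed = 5)
  st <- generateWordStream(lm, 10000, seed = 6)
  er <- entropyRate(lm)
  se <- sd(st$surprisal[-1]) / sqrt(nrow(st) - 1)
  expect_lt(abs(mean(st$surprisal[-1]) - er), 3 * se)
})

test_that("generators are bit-reproducible given seeds", {
  s1 <- simulateStudy(syntheticSpec(nWords = 40, nChannels = 2,
                                    nSubjects = 1, seed = 9))
  s2 <- simulateStudy(syntheticSpec(nWords = 40, nChannels = 2,
                                    nSubjects = 1, seed = 9))
  expect_identical(s1$eegParts, s2$eegParts)
  expect_identical(s1$words, s2$words)
  st1 <- generateWordStream(toyLanguageModel(8, seed = 1), 100, seed = 4)
  st2 <- generateWordStream(toyLanguageModel(8, seed = 1), 100, seed = 4)
  expect_identical(st1, st2)
})

test_that("copula word features approach the target correlation matrix", {
  spec <- syntheticSpec()
  f <- sampleWordFeatures(5000, spec, seed = 10)
  emp <- cor(as.matrix(f[, wordFeatureOrder()]))
  target <- spec$featureCorrelation
  dev <- emp - target
  off <- dev[upper.tri(dev)]
  expect_lt(mean(abs(off)), 0.03)
  expect_lt(sqrt(sum(dev^2)), 0.10)
  std <- attr(f, "standardized")
  expect_lt(max(abs(colMeans(std))), 1e-9)
})

test_that("the synthesized stimulus carries the planted pitch and alignment", {
  spec <- syntheticSpec(nWords = 40, seed = 12, f0Jitter = 2)
  feats <- sampleWordFeatures(40, spec, seed = 12)
  stim <- synthesizeStimulus(spec, feats, seed = 12)
  # the pitch band derived from the generated track contains the base f0
  band <- pitchBandFromPercentiles(stim$pitch)
  expect_lt(band@fLo, spec$f0Base)
  expect_gt(band@fHi, spec$f0Base)
  # per-word mean f0 from the exact pitch track matches the planted value
  errs <- vapply(seq_len(20), function(i) {
    a <- acousticFeatures(stim$pitch, stim$words$onset[i],
                          stim$words$offset[i])
    abs(a$meanF0 - stim$words$meanF0[i])
  }, 0)
  expect_lt(median(errs), 2)
  # words never straddle part boundaries
  partEnd <- cumsum(stim$partLens) / spec$fs
  for (p in seq_along(partEnd))
    expect_true(all(stim$words$offset[stim$words$part == p] <=
                      partEnd[p] + 1e-9))
})

test_that("audio synthesis round-trips through the feature extractors", {
  spec <- syntheticSpec(nWords = 25, seed = 13, audioFs = 8000,
                        harmonics = 1:8, f0Jitter = 2)
  feats <- sampleWordFeatures(25, spec, seed = 13)
  stim <- synthesizeStimulus(spec, feats, seed = 13, audio = TRUE)
  band <- pitchBandFromPercentiles(stim$pitch)
  f1 <- extractFundamentalWaveform(stim$audio, spec$audioFs, band, 1000)
  # within a long voiced span, the extracted fundamental dominates at the
  # planted f0 of that word
  i <- which.max(stim$words$voicedDuration[1:25])
  v <- stim$voiced[stim$voiced$word == i, ]
  idx <- (floor(v$start * 1000) + 20):(ceiling(v$end * 1000) - 20)
  seg <- f1[idx] - mean(f1[idx])
  p <- Mod(fft(seg))[2:floor(length(seg) / 2)]
  fpk <- (which.max(p)) * 1000 / length(seg)
  expect_lt(abs(fpk - stim$words$meanF0[i]), 5)
})

test_that("simulated EEG encodes the planted kernels and clips bad gains", {
  study <- smallStudy(nWords = 120, snrDb = 99, seed = 14)
  trf <- fitForwardTRF(study$eegParts[[1]], study$featureParts,
                       lagGrid(-30, 60, 1000), lambdaN = 1)
  pk <- trfSummary(trf)$peakLagMs
  expect_lt(abs(pk[1] - 11), 1.5)
  expect_lt(abs(pk[2] - 18), 1.5)
  # absurd betas force non-positive gains -> clipped with warning
  spec <- syntheticSpec(nWords = 30, nChannels = 2, nSubjects = 1,
                        modulationBetas = c(-3, 0, 0, 0, 0, 0, 0), seed = 15)
  feats <- sampleWordFeatures(30, spec, seed = 15)
  stim <- synthesizeStimulus(spec, feats, seed = 15)
  expect_warning(
    simulateEEG(stim$features, stim$words, spec, subjectSeed = 1,
                standardizedFeatures = attr(feats, "standardized")),
    "clipped")
})

test_that("spectrum-matched noise reproduces the smooth response spectrum", {
  set.seed(16)
  x <- as.numeric(arima.sim(list(ar = c(0.5, -0.3)), 16384))
  y <- speechFFR:::.phaseRandomized(x)
  expect_equal(mean(y^2), mean(x^2) - mean(x)^2, tolerance = 0.01)
  # band powers agree (the matching is at ~2 Hz spectral resolution)
  px <- Mod(fft(x))^2; py <- Mod(fft(y))^2
  bands <- cut(seq_along(px), 16)
  bx <- tapply(px, bands, sum); by <- tapply(py, bands, sum)
  expect_lt(max(abs(by / bx - 1)), 0.25)
  expect_lt(abs(cor(x, y)), 0.2)   # phases scrambled
})

test_that("invalid synthetic specs are rejected", {
  expect_error(syntheticSpec(modulationBetas = 1:3), "length 7")
  badC <- diag(7); badC[1, 2] <- badC[2, 1] <- 1.5
  expect_error(syntheticSpec(featureCorrelation = badC), "semidefinite")
  expect_error(syntheticSpec(kernelPeakMs = c(-5, 18)), "causal")
})
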