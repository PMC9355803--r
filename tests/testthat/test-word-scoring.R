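# Per-word null-corrected scores and population averaging.

test_that("corrected word score takes independent maxima over the grid", {
  expect_equal(correctedWordScore(0.3, 0.1), 0.2)
  expect_equal(correctedWordScore(c(0.1, 0.4), c(0.2, 0.05)), 0.2)
  expect_equal(correctedWordScore(c(0.2, 0.3), c(0.2, 0.3)), 0)
  expect_equal(correctedWordScore(c(NA, 0.4), c(0.1, NaN)), 0.3)
  expect_true(is.na(correctedWordScore(c(NA, NA), c(0.1, 0.2))))
  expect_error(correctedWordScore(numeric(0), 0.1), "nonempty")
})

test_that("correctedScores supports the fixed-lambda control", {
  raw <- array(NA_real_, c(2, 3, 2, 2),
               dimnames = list(word = c("1", "2"), lambda = NULL,
                               feature = c("f1", "f2"),
                               model = c("model", "null")))
  raw[1, , 1, 1] <- c(0.1, 0.5, 0.2); raw[1, , 1, 2] <- c(0.3, 0.1, 0.0)
  raw[2, , 1, 1] <- c(0.0, 0.1, 0.2); raw[2, , 1, 2] <- c(0.4, 0.1, 0.1)
  cs <- correctedScores(raw)
  expect_equal(unname(cs[, "f1"]), c(0.5 - 0.3, 0.2 - 0.4))
  fx <- correctedScores(raw, fixedLambdaIndex = 2)
  expect_equal(unname(fx[, "f1"]), c(0.4, 0.0))
})

test_that("population scores average subjects then standardize over words", {
  m1 <- matrix(c(0.1, 0.5, 0.2, 0.0), 2, 2,
               dimnames = list(c("1", "2"), c("f1", "f2")))
  m2 <- matrix(c(0.3, 0.7, 0.4, 0.2), 2, 2,
               dimnames = list(c("1", "2"), c("f1", "f2")))
  pop <- populationScores(list(m1, m2))
  expect_equal(unname(pop$rawMean[, "f1"]), c(0.2, 0.6))
  expect_lt(abs(mean(pop$population[, "f1"])), 1e-9)
  expect_lt(abs(sd(pop$population[, "f1"]) - 1), 1e-9)
  # a missing subject entry is averaged over the available ones
  m2[1, "f1"] <- NA
  pop2 <- populationScores(list(m1, m2))
  expect_equal(unname(pop2$rawMean[1, "f1"]), 0.1)
  expect_equal(unname(pop2$nSubjects[1, "f1"]), 1)
})

test_that("word segments map voiced intervals into part-relative samples", {
  words <- data.frame(word = 1:3, part = c(1, 1, 2))
  voiced <- data.frame(word = c(1, 3), start = c(0.10, 2.10),
                       end = c(0.30, 2.40))
  ws <- wordVoicedSegments(words, voiced, partLens = c(2000, 1000), fs = 1000)
  expect_equal(attr(ws, "voiceless"), 2)
  expect_equal(ws$part, c(1, 2))
  expect_equal(ws$from, c(101, 101))
  expect_equal(ws$to, c(300, 400))
})

test_that("word scoring produces the full bookkeeping array", {
  study <- smallStudy(nWords = 60, snrDb = 10, seed = 30, nParts = 5)
  raw <- scoreWords(study$eegParts[[1]], study$featureParts,
                    study$wordSegments, lambdaGrid = 10^seq(-4, 4,
                                                            length.out = 5))
  expect_equal(length(dim(raw)), 4)
  expect_equal(dim(raw)[2:4], c(5L, 2L, 2L))
  expect_equal(dim(raw)[1], length(unique(study$wordSegments$word)))
  scored <- apply(is.finite(raw[, , 2, 1]), 1, any)
  expect_gt(mean(scored), 0.9)
})

test_that("population scores track planted per-word gains", {
  spec <- syntheticSpec(nWords = 400, nChannels = 4, nSubjects = 3,
                        seed = 33, snrDb = 0,
                        modulationBetas = c(-0.3, 0, 0, 0, 0, 0, 0))
  study <- simulateStudy(spec)
  subj <- lapply(study$eegParts, function(parts)
    correctedScores(scoreWords(parts, study$featureParts,
                               study$wordSegments, scoreFeatures = 2)))
  pop <- populationScores(subj)
  ids <- as.integer(rownames(pop$population))
  g <- study$groundTruth$gains[ids]
  expect_gt(cor(pop$population[, "f2"], g, use = "complete.obs"), 0.3)
})

test_that("doubling the planted gain modulation never weakens the score-gain link", {
  cors <- vapply(c(0.15, 0.3), function(b) {
    spec <- syntheticSpec(nWords = 250, nChannels = 4, nSubjects = 2,
                          seed = 44, snrDb = 0,
                          modulationBetas = c(-b, 0, 0, 0, 0, 0, 0))
    study <- simulateStudy(spec)
    subj <- lapply(study$eegParts, function(parts)
      correctedScores(scoreWords(parts, study$featureParts,
                                 study$wordSegments, scoreFeatures = 2)))
    pop <- populationScores(subj)
    ids <- as.integer(rownames(pop$population))
    cor(pop$population[, "f2"], study$groundTruth$gains[ids],
        use = "complete.obs")
  }, 0)
  expect_gt(cors[2], cors[1] - 0.05)
})
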