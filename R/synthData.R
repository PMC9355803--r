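# Synthetic study generator: speech-like stimuli with known pitch and word
# alignment, toy language models with exact information-theoretic ground
# truth, correlated word features, and multichannel EEG generated as a
# lagged linear response with a known kernel plus band-matched noise, with
# a planted linear modulation of the per-word response gain.

#' Default target correlation matrix of the seven word features
#'
#' Mirrors the correlation structure observed between word-level features
#' in natural narrative speech: strong positive coupling of surprisal with
#' the precision-surprisal interaction (0.632) and with inverted word
#' frequency (0.431), of voiced duration with inverted frequency (0.632)
#' and surprisal (0.406), a weak f0-rate/inverted-frequency link (0.129),
#' and small residual correlations elsewhere. Adjusted, if necessary, to
#' the nearest positive-definite matrix.
#'
#' @return 7 x 7 correlation matrix with dimnames [wordFeatureOrder()].
#' @export
defaultFeatureCorrelation <- function() {
  f <- wordFeatureOrder()
  m <- diag(1, 7)
  dimnames(m) <- list(f, f)
  set2 <- function(a, b, v) {
    m[a, b] <<- v; m[b, a] <<- v
  }
  set2("surprisal", "interaction", 0.632)
  set2("invFreq", "surprisal", 0.431)
  set2("voicedDuration", "surprisal", 0.406)
  set2("voicedDuration", "invFreq", 0.632)
  set2("f0Rate", "invFreq", 0.129)
  set2("meanF0", "f0Rate", 0.10)
  set2("meanF0", "voicedDuration", -0.05)
  set2("meanF0", "invFreq", -0.05)
  set2("meanF0", "precision", 0.05)
  set2("meanF0", "surprisal", -0.10)
  set2("meanF0", "interaction", -0.05)
  set2("f0Rate", "voicedDuration", 0.05)
  set2("f0Rate", "precision", -0.05)
  set2("f0Rate", "surprisal", 0.05)
  set2("f0Rate", "interaction", 0.05)
  set2("voicedDuration", "precision", -0.157)
  set2("voicedDuration", "interaction", 0.20)
  set2("invFreq", "precision", -0.10)
  set2("invFreq", "interaction", 0.25)
  set2("precision", "surprisal", -0.10)
  set2("precision", "interaction", 0.274)
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) < 1e-6) {
    v <- pmax(e$values, 1e-6)
    m <- e$vectors %*% diag(v) %*% t(e$vectors)
    d <- sqrt(diag(m))
    m <- m / outer(d, d)
    dimnames(m) <- list(f, f)
  }
  m
}

#' Specification of a synthetic study
#'
#' Bundles all parameters of the synthetic-data generator. Defaults
#' emulate the narrative-listening study conditions: ~5000 words of mean
#' duration 0.26 s, a male-like speaker (f0 mean 107.2 Hz, sd 24.8 Hz,
#' harmonics up to order 8), response kernels peaking at 11 ms
#' (fundamental waveform) and 18 ms (envelope modulation, twice the
#' amplitude), EEG at 1 kHz with band-matched noise at 0 dB SNR, five
#' recording parts, and five subjects.
#'
#' @param nWords number of words.
#' @param wordDurationMean,wordDurationSdlog lognormal word-duration
#'   parameters (the mean is in seconds; sdlog on the log scale).
#' @param gap unvoiced silence between words (s).
#' @param voicedFraction fraction of a word's duration that is voiced.
#' @param f0Base,f0Sd mean and sd of the per-word mean f0 (Hz).
#' @param f0Jitter sd (Hz) of the slow within-word pitch fluctuation
#'   (microprosody) superimposed on the word's linear f0 trajectory.
#'   Natural pitch is never a pure tone; the fluctuation spreads each
#'   word's energy over a band of several Hz.
#' @param f0RateMedian,f0RateSdlog lognormal parameters of the per-word f0
#'   rate of change (Hz/s).
#' @param harmonics harmonic orders present in the synthesized audio.
#' @param kernelPeakMs,kernelWidthMs,kernelAmplitude per-feature response
#'   kernel Gaussian parameters (length 2: f1, f2).
#' @param modulationBetas 7-vector of planted word-level gain coefficients
#'   on the standardized features (order [wordFeatureOrder()]).
#' @param modulateFeature which stimulus feature(s) the gain modulation
#'   applies to (default both).
#' @param featureCorrelation 7 x 7 target correlation matrix.
#' @param snrDb per-channel EEG signal-to-noise ratio in dB (noise is
#'   spectrum-matched to the clean response, hence confined to the
#'   analysis band). The default -20 dB is calibrated so that word-level
#'   reconstruction scores come out at the magnitudes observed for real
#'   EEG responses at the fundamental frequency (r of order 0.1-0.2).
#' @param nChannels,nSubjects,nParts study dimensions.
#' @param fs EEG/feature sampling rate (Hz).
#' @param audioFs audio sampling rate for waveform synthesis (Hz).
#' @param f2Phase base phase offset (radians) between the synthesized
#'   fundamental waveform and envelope-modulation features; the default,
#'   together with the per-word jitter, reproduces a speech-like negative
#'   f1-f2 correlation (~ -0.28).
#' @param amplitudeJitterSd lognormal sigma of the per-word stimulus
#'   amplitude (word intensity). Natural speech varies in per-word level
#'   by several dB; the default 0.5 corresponds to ~4 dB of level sd.
#'   This intensity variation is shared across subjects and independent
#'   of the word features, and is the dominant benign source of per-word
#'   score variance.
#' @param f2PhaseJitter sd (radians) of the per-word random phase of f2
#'   around the base offset. Without it f2 would lie exactly in the span
#'   of f1 and its Hilbert transform (the envelope periodicity shares
#'   f1's instantaneous frequency), making the two response kernels
#'   unidentifiable; the jitter emulates the varying envelope-phase
#'   relationship of natural speech.
#' @param seed integer master seed.
#' @return list of class `"SyntheticSpec"`.
#' @export
syntheticSpec <- function(nWords = 5000,
                          wordDurationMean = 0.26,
                          wordDurationSdlog = 0.35,
                          gap = 0.05,
                          voicedFraction = 0.75,
                          f0Base = 107.2, f0Sd = 24.8, f0Jitter = 8,
                          f0RateMedian = 60, f0RateSdlog = 0.5,
                          harmonics = 1:8,
                          kernelPeakMs = c(11, 18),
                          kernelWidthMs = c(2, 3),
                          kernelAmplitude = c(1, 2),
                          modulationBetas = numeric(7),
                          modulateFeature = 1:2,
                          featureCorrelation = defaultFeatureCorrelation(),
                          snrDb = -20,
                          nChannels = 8, nSubjects = 5, nParts = 5,
                          fs = 1000, audioFs = 8000,
                          amplitudeJitterSd = 0.5,
                          f2PhaseJitter = 0.8,
                          f2Phase = acos(max(-1, -0.28 /
                                               exp(-f2PhaseJitter^2 / 2))),
                          seed = 1) {
  spec <- as.list(environment())
  if (length(modulationBetas) != 7)
    stop("modulationBetas must have length 7")
  if (min(eigen(featureCorrelation, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-8)
    stop("featureCorrelation must be positive semidefinite")
  if (any(kernelPeakMs < 0))
    stop("kernel peaks must lie at nonnegative (causal) lags")
  structure(spec, class = "SyntheticSpec")
}

#' @export
print.SyntheticSpec <- function(x, ...) {
  cat(sprintf(paste0(
    "SyntheticSpec: %d words, %d subjects x %d channels, %d parts\n",
    "  f0 %g +/- %g Hz; kernels peak %s ms; SNR %g dB; betas [%s]\n"),
    x$nWords, x$nSubjects, x$nChannels, x$nParts, x$f0Base, x$f0Sd,
    paste(x$kernelPeakMs, collapse = "/"), x$snrDb,
    paste(format(x$modulationBetas, trim = TRUE), collapse = ", ")))
  invisible(x)
}

#' Sample correlated word features via a Gaussian copula
#'
#' Draws a latent multivariate normal with the target correlation and maps
#' each coordinate through a near-linear marginal transform (Gaussian for
#' mean f0, inverted frequency, surprisal and interaction; lognormal for
#' f0 rate and voiced duration; inverse-Gaussian-entropy for precision).
#' The near-linearity keeps the Pearson correlations close to the latent
#' targets.
#'
#' @param n number of words.
#' @param spec a [syntheticSpec()] (supplies correlation and marginals).
#' @param seed integer seed.
#' @return data.frame with the seven feature columns of
#'   [wordFeatureOrder()] plus `wordDuration` (s); attribute
#'   `"standardized"` holds the standardized 7-column matrix used for
#'   planted gains.
#' @export
sampleWordFeatures <- function(n, spec = syntheticSpec(), seed = 1) {
  set.seed(seed)
  C <- spec$featureCorrelation
  Z <- matrix(rnorm(n * 7), n, 7) %*% chol(C)
  durMeanlog <- log(spec$wordDurationMean) - spec$wordDurationSdlog^2 / 2
  wordDuration <- exp(durMeanlog + spec$wordDurationSdlog * Z[, 3])
  out <- data.frame(
    meanF0 = pmax(60, spec$f0Base + spec$f0Sd * Z[, 1]),
    f0Rate = exp(log(spec$f0RateMedian) + spec$f0RateSdlog * Z[, 2]),
    voicedDuration = spec$voicedFraction * wordDuration,
    invFreq = 6.5 + 1.25 * Z[, 4],
    # inverse-entropy marginal, entropy DECREASING in the latent
    # coordinate so that precision is increasing (monotone transforms
    # must preserve the latent correlation's sign)
    precision = 1 / pmax(0.5, 4 - 0.6 * Z[, 5]),
    surprisal = pmax(0.1, 7 + 1.5 * Z[, 6]),
    interaction = 1.8 + 0.6 * Z[, 7])
  out$wordDuration <- wordDuration
  attr(out, "standardized") <-
    apply(as.matrix(out[, wordFeatureOrder()]), 2, .standardize)
  out
}

# --- toy language model -----------------------------------------------------

#' Construct a toy Markov-chain language model
#'
#' Transition rows are drawn from a symmetric Dirichlet; the stationary
#' distribution is computed exactly from the leading left eigenvector.
#'
#' @param nTokens vocabulary size.
#' @param concentration Dirichlet concentration (small values give peaky,
#'   low-entropy rows).
#' @param seed integer seed.
#' @return A [ToyLanguageModel-class].
#' @export
toyLanguageModel <- function(nTokens = 20, concentration = 1, seed = 1) {
  set.seed(seed)
  P <- matrix(rgamma(nTokens^2, shape = concentration), nTokens)
  P <- P / rowSums(P)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  pi0 <- Re(e$vectors[, i])
  pi0 <- pi0 / sum(pi0)
  new("ToyLanguageModel",
      vocabulary = sprintf("w%02d", seq_len(nTokens)),
      transition = P, unigram = pi0)
}

#' Entropy rate of a toy language model
#'
#' `sum_i pi_i H(P[i, ])` in nats: the expected conditional next-token
#' entropy under the stationary distribution, which the empirical mean
#' surprisal of a long sampled sequence converges to.
#'
#' @param lm a [ToyLanguageModel-class].
#' @return entropy rate in nats.
#' @export
entropyRate <- function(lm) {
  P <- lm@transition
  rowH <- -rowSums(ifelse(P > 0, P * log(P), 0))
  sum(lm@unigram * rowH)
}

#' Sample a word stream with exact information-theoretic ground truth
#'
#' Samples a token sequence from the Markov chain (first token from the
#' stationary distribution) and returns, per position, the exact unigram
#' probability, conditional probability, surprisal, conditional entropy,
#' precision (entropy clamped at 1e-6 nats and flagged when the chain is
#' deterministic), inverted frequency, and the precision-surprisal
#' interaction. For the first position the stationary distribution serves
#' as the conditional.
#'
#' @param lm a [ToyLanguageModel-class].
#' @param nWords number of words to sample.
#' @param seed integer seed.
#' @return data.frame, one row per word.
#' @export
generateWordStream <- function(lm, nWords, seed = 1) {
  set.seed(seed)
  K <- length(lm@vocabulary)
  tok <- integer(nWords)
  tok[1] <- sample.int(K, 1, prob = lm@unigram)
  for (i in seq_len(nWords - 1))
    tok[i + 1] <- sample.int(K, 1, prob = lm@transition[tok[i], ])
  condP <- c(lm@unigram[tok[1]],
             lm@transition[cbind(tok[-nWords], tok[-1])])
  rowEnt <- function(p) -sum(ifelse(p > 0, p * log(p), 0))
  entropy <- c(rowEnt(lm@unigram),
               apply(lm@transition[tok[-nWords], , drop = FALSE], 1, rowEnt))
  clamped <- entropy < 1e-6
  precision <- 1 / pmax(entropy, 1e-6)
  surprisal <- -log(condP)
  data.frame(position = seq_len(nWords), word = lm@vocabulary[tok],
             token = tok, unigram = lm@unigram[tok], condP = condP,
             invFreq = -log(lm@unigram[tok]), surprisal = surprisal,
             entropy = entropy, precision = precision,
             interaction = precision * surprisal, clamped = clamped)
}

# --- stimulus synthesis -----------------------------------------------------

# Raised-cosine on/off ramp of length nr samples applied in place.
.applyRamp <- function(x, nr) {
  n <- length(x)
  nr <- min(nr, floor(n / 2))
  if (nr < 1) return(x)
  ramp <- 0.5 * (1 - cos(pi * (seq_len(nr) - 0.5) / nr))
  x[seq_len(nr)] <- x[seq_len(nr)] * ramp
  x[(n - nr + 1):n] <- x[(n - nr + 1):n] * rev(ramp)
  x
}

#' Synthesize a speech-like stimulus from a word table
#'
#' Lays the words out on a timeline (unvoiced gaps between words), renders
#' each word's voiced part as a waveform whose instantaneous frequency
#' follows a linear per-word f0 trajectory (mean = the word's `meanF0`,
#' absolute slope = its `f0Rate`, slope sign alternating at random), and
#' returns the two stimulus features at the EEG rate, the exact pitch
#' track, the word alignment with voiced intervals, and part boundaries.
#' With `audio = TRUE` a harmonic-complex audio waveform (harmonic orders
#' from the spec, 1/h amplitudes) is synthesized at `spec$audioFs` for
#' exercising the audio-analysis path.
#'
#' The synthetic `f2` shares the instantaneous f0 of `f1` with a fixed
#' phase offset, emulating the envelope periodicity of the higher
#' harmonics; the offset reproduces the negative f1-f2 correlation seen in
#' natural speech.
#'
#' @param spec a [syntheticSpec()].
#' @param words word table from [sampleWordFeatures()] (any data.frame
#'   with `meanF0`, `f0Rate`, `voicedDuration`, `wordDuration` columns).
#' @param seed integer seed (slope signs, pitch jitter).
#' @param audio also synthesize the audio waveform.
#' @return list: `features` ([StimulusFeatures-class], whole timeline),
#'   `pitch` ([PitchTrack-class]), `words` (word, part, onset, offset,
#'   meanF0, f0Slope, ...), `voiced` (word, start, end), `partLens`
#'   (samples per part), `audio` (optional), `audioFs`.
#' @export
synthesizeStimulus <- function(spec, words, seed = 1, audio = FALSE) {
  n <- nrow(words)
  fs <- spec$fs
  set.seed(seed + 17)
  slopeSign <- sample(c(-1, 1), n, replace = TRUE)
  f2Jitter <- rnorm(n, sd = spec$f2PhaseJitter %||% 0)
  ampSd <- spec$amplitudeJitterSd %||% 0
  amp <- exp(rnorm(n, -ampSd^2 / 2, ampSd))
  dur <- words$wordDuration
  # words are assigned to contiguous parts of near-equal total duration;
  # each part is laid out independently and padded with trailing silence
  # to a multiple of 4096 samples (part lengths with small prime factors
  # keep the whole-part FFTs - Hilbert transforms, convolutions,
  # spectral surrogates - fast)
  cumDur <- cumsum(dur + spec$gap)
  partOf <- pmin(spec$nParts,
                 floor((cumDur - dur / 2) / (cumDur[n] / spec$nParts)) + 1)
  partOf <- cummax(partOf)
  onset <- numeric(n); partLens <- integer(spec$nParts)
  partStart <- 0
  for (p in seq_len(spec$nParts)) {
    idx <- which(partOf == p)
    localOn <- spec$gap + c(0, cumsum(dur[idx] + spec$gap))[seq_along(idx)]
    onset[idx] <- partStart + localOn
    localEnd <- if (length(idx)) localOn[length(idx)] +
      dur[idx[length(idx)]] + spec$gap else spec$gap
    partLens[p] <- 4096 * ceiling(localEnd * fs / 4096)
    partStart <- partStart + partLens[p] / fs
  }
  offset <- onset + dur
  total <- sum(partLens) / fs
  nSamp <- sum(partLens)
  vStart <- onset + (dur - words$voicedDuration) / 2
  vEnd <- vStart + words$voicedDuration
  f1 <- numeric(nSamp); f2 <- numeric(nSamp)
  f0Track <- rep(NA_real_, nSamp)
  # vectorized rendering over the concatenation of all voiced spans
  i0 <- floor(vStart * fs) + 1
  i1 <- pmin(nSamp, ceiling(vEnd * fs))
  keep <- which(i1 - i0 >= 2)
  lens <- i1[keep] - i0[keep] + 1
  idxAll <- unlist(mapply(seq, i0[keep], i1[keep], SIMPLIFY = FALSE))
  wAll <- rep(keep, lens)                       # word index per sample
  pos <- sequence(lens)                         # position within span
  tAll <- (idxAll - 0.5) / fs
  mid <- (vStart + vEnd) / 2
  f0All <- words$meanF0[wAll] +
    slopeSign[wAll] * words$f0Rate[wAll] * (tAll - mid[wAll])
  jit <- spec$f0Jitter %||% 0
  if (jit > 0) {
    # slow microprosodic fluctuation: exponentially smoothed noise,
    # re-standardized within each word
    a <- exp(-1 / (0.02 * fs))
    u <- as.numeric(stats::filter(rnorm(length(idxAll)) * (1 - a), a,
                                  method = "recursive"))
    gf <- factor(wAll)
    nW <- as.numeric(rowsum(rep(1, length(u)), gf))
    mu <- as.numeric(rowsum(u, gf)) / nW
    s2 <- as.numeric(rowsum(u^2, gf)) / nW - mu^2
    sdw <- sqrt(pmax(s2, 1e-12))
    gi <- as.integer(gf)
    f0All <- f0All + jit * (u - mu[gi]) / sdw[gi]
  }
  f0All <- pmax(40, f0All)
  # phase integration with a reset at every word onset
  cs <- cumsum(f0All)
  startPos <- cumsum(c(1, head(lens, -1)))
  base <- cs[startPos] - f0All[startPos]
  ph <- 2 * pi * (cs - rep(base, lens)) / fs
  # raised-cosine on/off ramps (10 ms) at the span edges
  nr <- pmin(round(0.01 * fs), floor(rep(lens, lens) / 2))
  edge <- pmin(pos - 0.5, rep(lens, lens) - pos + 0.5)
  ramp <- ifelse(edge < nr, 0.5 * (1 - cos(pi * edge / pmax(nr, 1))), 1)
  ampAll <- amp[wAll] * ramp
  f1[idxAll] <- ampAll * sin(ph)
  f2[idxAll] <- ampAll * sin(ph + spec$f2Phase + f2Jitter[wAll])
  f0Track[idxAll] <- f0All
  phaseList <- vector("list", n)
  phaseList[keep] <- split(f0All, factor(wAll, levels = keep))
  idxList <- vector("list", n)
  idxList[keep] <- split(idxAll, factor(wAll, levels = keep))
  frameStep <- 0.01
  frameT <- seq(frameStep / 2, total - frameStep / 2, by = frameStep)
  frameIdx <- pmin(nSamp, floor(frameT * fs) + 1)
  pitch <- pitchTrack(frameT, f0Track[frameIdx], frameStep)
  wordsOut <- cbind(data.frame(word = seq_len(n), part = partOf,
                               onset = onset, offset = offset,
                               f0Slope = slopeSign * words$f0Rate,
                               amplitude = amp),
                    words)
  voiced <- data.frame(word = seq_len(n), start = vStart, end = vEnd)
  out <- list(features = stimulusFeatures(f1, f2, fs), pitch = pitch,
              words = wordsOut, voiced = voiced, partLens = partLens)
  if (audio) {
    afs <- spec$audioFs
    nA <- round(total * afs)
    aud <- numeric(nA)
    for (i in seq_len(n)) {
      if (is.null(idxList[[i]])) next
      a0 <- floor(vStart[i] * afs) + 1
      a1 <- min(nA, ceiling(vEnd[i] * afs))
      if (a1 - a0 < 2) next
      idx <- a0:a1
      # reuse the realized 1 kHz f0 trajectory (incl. jitter) of the word
      f0k <- phaseList[[i]]
      f0 <- approx(seq_along(f0k), f0k,
                   xout = seq(1, length(f0k), length.out = length(idx)))$y
      ph <- 2 * pi * cumsum(f0) / afs
      w <- numeric(length(idx))
      for (h in spec$harmonics)
        if (max(f0) * h < afs / 2) w <- w + sin(h * ph) / h
      aud[idx] <- .applyRamp(w, round(0.01 * afs))
    }
    out$audio <- aud
    out$audioFs <- afs
  }
  out
}

# --- EEG simulation ---------------------------------------------------------

# Gabor response kernel sampled at fs, support 0..(peak + 4 width): a
# Gaussian envelope at the peak latency carrying an oscillation at the
# speaker's mean f0. The carrier makes the kernel pass the f0 band (a
# frequency-following response tracks the fine structure, it does not
# low-pass it); its transfer magnitude is then symmetric around the f0
# distribution center, so per-word reconstruction difficulty does not
# covary linearly with the word's mean f0 under a null (zero-beta) study.
.responseKernel <- function(peakMs, widthMs, amplitude, fs, carrierHz) {
  tMs <- seq(0, peakMs + 4 * widthMs, by = 1000 / fs)
  amplitude * exp(-(tMs - peakMs)^2 / (2 * widthMs^2)) *
    cos(2 * pi * carrierHz * (tMs - peakMs) / 1000)
}

# Fixed channel topography of the study (drawn from the master seed).
# The two response sources project with random but ORTHONORMAL loadings
# (scaled to a common norm): with a handful of desk-scale channels, raw
# Gaussian loadings are occasionally near-collinear and the two kernels
# then cease to be separable, which is a property of a badly placed
# montage, not of the estimators under validation.
.channelWeights <- function(spec) {
  set.seed(spec$seed + 1000)
  w <- matrix(rnorm(spec$nChannels * 2), spec$nChannels, 2)
  qr.Q(qr(w)) * sqrt(spec$nChannels / 2)
}

#' Simulate a subject's EEG as a lagged linear response plus noise
#'
#' Each channel is the sum over the two stimulus features of the
#' convolution of the gain-modulated feature with that feature's response
#' kernel (Gabor time course peaking at the spec's latency, channel
#' topography fixed across subjects), plus spectrum-matched Gaussian noise
#' (a phase-randomized surrogate of the clean response, so the
#' signal-to-noise ratio is flat across frequencies and automatically
#' confined to the analysis band) scaled per channel to the spec's SNR.
#' The per-word gain is `1 + sum_m beta_m x_im` over the
#' standardized word features; non-positive gains are clipped at 0.1 with
#' a warning.
#'
#' @param features [StimulusFeatures-class] of the whole timeline.
#' @param words word table from [synthesizeStimulus()] (needs `onset`,
#'   `offset` and attribute-free feature columns).
#' @param spec the [syntheticSpec()].
#' @param subjectSeed integer seed for this subject's noise.
#' @param standardizedFeatures standardized 7-column matrix aligned with
#'   `words` (defaults to standardizing the word table's feature columns).
#' @return An [EEGRecording-class] (reference `"simulated"`), with
#'   attributes `"gains"` (per word) and `"kernels"`.
#' @export
simulateEEG <- function(features, words, spec, subjectSeed = 1,
                        standardizedFeatures = NULL) {
  cr <- .cleanResponse(features, words, spec, standardizedFeatures)
  set.seed(subjectSeed)
  # noise is a phase-randomized surrogate of the UNMODULATED response:
  # the background must not inherit the planted gain structure, or the
  # per-frequency SNR would cancel any modulation that covaries with a
  # word's spectral position
  noise <- apply(cr$base, 2, .phaseRandomized)
  scale <- sqrt(1 / 10^(spec$snrDb / 10))
  eegDat <- cr$clean + noise * scale
  structure(eegRecording(eegDat, features@fs, reference = "simulated"),
            gains = cr$gains, kernels = cr$kernels)
}

# Deterministic (noise-free) part of the simulated EEG, shared across
# subjects: the gain-modulated response `clean`, the unmodulated response
# `base` that shapes the noise spectrum, and the per-word gains.
.cleanResponse <- function(features, words, spec,
                           standardizedFeatures = NULL) {
  fs <- features@fs
  n <- length(features@f1)
  if (is.null(standardizedFeatures))
    standardizedFeatures <-
      apply(as.matrix(words[, wordFeatureOrder()]), 2, .standardize)
  gains <- 1 + drop(standardizedFeatures %*% spec$modulationBetas)
  if (any(gains <= 0)) {
    warning(sum(gains <= 0), " word gain(s) <= 0 clipped at 0.1")
    gains <- pmax(gains, 0.1)
  }
  g <- rep(1, n)
  i0 <- pmax(1, floor(words$onset * fs) + 1)
  i1 <- pmin(n, ceiling(words$offset * fs))
  for (i in seq_len(nrow(words))) g[i0[i]:i1[i]] <- gains[i]
  W <- .channelWeights(spec)
  kernels <- lapply(1:2, function(j)
    .responseKernel(spec$kernelPeakMs[j], spec$kernelWidthMs[j],
                    spec$kernelAmplitude[j], fs, spec$f0Base))
  fmat <- cbind(features@f1, features@f2)
  clean <- matrix(0, n, spec$nChannels)
  base <- matrix(0, n, spec$nChannels)
  for (j in 1:2) {
    fj <- fmat[, j]
    respBase <- .fftConvolve(fj, kernels[[j]])[seq_len(n)]
    base <- base + outer(respBase, W[, j])
    if (j %in% spec$modulateFeature && any(gains != 1)) {
      resp <- .fftConvolve(fj * g, kernels[[j]])[seq_len(n)]
    } else resp <- respBase
    clean <- clean + outer(resp, W[, j])
  }
  list(clean = clean, base = base, gains = gains, kernels = kernels)
}

# Spectrum-matched Gaussian noise: random phases on a SMOOTHED magnitude
# spectrum of the clean channel (about 2 Hz spectral resolution, assuming
# 1 kHz sampling). Matching the smooth spectral envelope keeps the
# signal-to-noise ratio flat across frequencies, so a word's position in
# the corpus f0 distribution does not change how faithfully it can be
# reconstructed - only the planted gain modulation does. The smoothing is
# essential: an exact-magnitude surrogate shares the signal's full
# autocorrelation, including the temporal fine structure of word timing,
# and is then not informationless noise.
.phaseRandomized <- function(x, resHz = 2, fs = 1000)
  .noiseFromSpectrum(.surrogateMagnitude(x, resHz, fs))

# Smoothed magnitude spectrum of x (circular running mean of the power
# spectrum over ~resHz), power-normalized to the original total power.
.surrogateMagnitude <- function(x, resHz = 2, fs = 1000) {
  n <- length(x)
  P <- Mod(fft(x))^2
  total <- sum(P)
  w <- max(1L, round(resHz * n / fs))
  if (w > 1) {
    cs <- cumsum(c(P, P[seq_len(w)]))        # circular running sum
    P <- (cs[(w + 1):(w + n)] - cs[1:n]) / w
    P <- pmax(P, 0)
  }
  sqrt(P * total / max(sum(P), .Machine$double.eps))
}

# Gaussian noise with the given magnitude spectrum and fresh random
# phases (hermitian-symmetric, one inverse FFT).
.noiseFromSpectrum <- function(mag) {
  n <- length(mag)
  half <- seq(2, ceiling((n + 1) / 2))
  theta <- runif(length(half), 0, 2 * pi)
  Y <- complex(real = numeric(n))
  Y[half] <- complex(modulus = mag[half], argument = theta)
  mirror <- n + 2 - half
  keep <- mirror > ceiling((n + 1) / 2)
  Y[mirror[keep]] <- Conj(Y[half[keep]])
  if (n %% 2 == 0) Y[n / 2 + 1] <- complex(real = mag[n / 2 + 1] *
                                             sign(runif(1) - 0.5))
  Re(fft(Y, inverse = TRUE)) / n
}

#' Simulate a complete multi-subject synthetic study
#'
#' Draws correlated word features, synthesizes the stimulus timeline and
#' pitch track, and generates one EEG recording per subject with the
#' planted response kernels and planted word-level gain modulation. All
#' signals are split into the spec's contiguous recording parts.
#'
#' @param spec a [syntheticSpec()].
#' @return list: `spec`, `words`, `voiced`, `pitch`, `partLens`,
#'   `featureParts` (list of per-part [StimulusFeatures-class]),
#'   `eegParts` (per subject, list of per-part matrices),
#'   `wordSegments` (per-word voiced sample spans, see
#'   [wordVoicedSegments()]), `groundTruth` (betas, gains, kernel peaks,
#'   seeds).
#' @export
simulateStudy <- function(spec = syntheticSpec()) {
  feats <- sampleWordFeatures(spec$nWords, spec, seed = spec$seed)
  stim <- synthesizeStimulus(spec, feats, seed = spec$seed)
  partLens <- stim$partLens
  cuts <- c(0, cumsum(partLens))
  splitVec <- function(v) lapply(seq_along(partLens), function(p)
    v[(cuts[p] + 1):cuts[p + 1]])
  featureParts <- mapply(function(a, b) stimulusFeatures(a, b, spec$fs),
                         splitVec(stim$features@f1),
                         splitVec(stim$features@f2), SIMPLIFY = FALSE)
  eegParts <- vector("list", spec$nSubjects)
  cr <- .cleanResponse(stim$features, stim$words, spec,
                       attr(feats, "standardized"))
  gains <- cr$gains
  scale <- sqrt(1 / 10^(spec$snrDb / 10))
  noiseMag <- apply(cr$base, 2, .surrogateMagnitude)  # shared spectrum
  for (s in seq_len(spec$nSubjects)) {
    set.seed(spec$seed + 100 + s)
    M <- cr$clean + apply(noiseMag, 2, .noiseFromSpectrum) * scale
    eegParts[[s]] <- lapply(seq_along(partLens), function(p)
      M[(cuts[p] + 1):cuts[p + 1], , drop = FALSE])
  }
  wordSegments <- wordVoicedSegments(stim$words, stim$voiced, partLens,
                                     spec$fs)
  list(spec = spec, words = stim$words, voiced = stim$voiced,
       pitch = stim$pitch, partLens = partLens,
       featureParts = featureParts, eegParts = eegParts,
       wordSegments = wordSegments,
       groundTruth = list(
         betas = spec$modulationBetas, gains = gains,
         kernelPeakMs = spec$kernelPeakMs,
         standardizedFeatures = attr(feats, "standardized"),
         seed = spec$seed))
}
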