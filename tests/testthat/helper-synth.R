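# Shared fixtures, built in code at test time.

toneAt <- function(freq, duration = 1, fs = 1000, phase = 0)
  sin(2 * pi * freq * (seq_len(round(duration * fs)) - 0.5) / fs + phase)

centralSpan <- function(n, frac = 0.9) {
  drop <- floor(n * (1 - frac) / 2)
  (drop + 1):(n - drop)
}

# Fit per-subject real and null forward TRFs efficiently by stacking all
# subjects' channels into one recording (ridge solves channels
# independently, so the stacked fit equals per-subject fits) and
# splitting the coefficient array afterwards.
stackedSubjectTRFs <- function(study, lags) {
  nSub <- length(study$eegParts)
  nCh <- ncol(study$eegParts[[1]][[1]])
  parts <- lapply(seq_along(study$featureParts), function(p)
    do.call(cbind, lapply(study$eegParts, `[[`, p)))
  split1 <- function(trf) lapply(seq_len(nSub), function(s) {
    out <- trf
    out@alpha <- trf@alpha[, (s - 1) * nCh + seq_len(nCh), , drop = FALSE]
    out
  })
  real <- fitForwardTRF(parts, study$featureParts, lags)
  null <- fitForwardTRF(parts, study$featureParts, lags,
                        timeReversed = TRUE)
  list(real = split1(real), null = split1(null))
}

# small planted-kernel study used by several forward-model tests
smallStudy <- function(nWords = 150, nSubjects = 1, snrDb = 99, seed = 7,
                       betas = numeric(7), ...) {
  simulateStudy(syntheticSpec(nWords = nWords, nChannels = 4,
                              nSubjects = nSubjects, snrDb = snrDb,
                              seed = seed, modulationBetas = betas, ...))
}
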