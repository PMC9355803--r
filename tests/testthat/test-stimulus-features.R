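# Fundamental waveform and high-frequency envelope modulation extraction.

test_that("pitch band percentiles follow the linear-interpolation rule", {
  pt <- pitchTrack(seq(0, 1.01, by = 0.01), c(NA, seq(100, 200, 1)))
  band <- pitchBandFromPercentiles(pt, 5, 95)
  expect_equal(band@fLo, 105)
  expect_equal(band@fHi, 195)
})

test_that("degenerate and unvoiced pitch tracks are rejected", {
  const <- pitchTrack(seq(0, 0.5, by = 0.01), rep(100, 51))
  expect_error(pitchBandFromPercentiles(const), "degenerate")
  unvoiced <- pitchTrack(seq(0, 0.5, by = 0.01), rep(NA_real_, 51))
  expect_error(pitchBandFromPercentiles(unvoiced), "no pitch")
  expect_error(pitchBandFromPercentiles(
    pitchTrack(0:2 / 100, c(100, 110, 120)), 95, 5), "loPct")
})

test_that("fundamental waveform extraction passes the band and rejects outside it", {
  fs <- 8000
  band <- bandSpec(75, 150)
  x100 <- toneAt(100, 2, fs)
  x300 <- toneAt(300, 2, fs)
  y100 <- extractFundamentalWaveform(x100, fs, band, 1000)
  y300 <- extractFundamentalWaveform(x300, fs, band, 1000)
  expect_length(y100, 2000)
  ref <- sin(2 * pi * 100 * (0:1999) / 1000)   # output-grid time convention
  cs <- centralSpan(2000)
  expect_gt(cor(y100[cs], ref[cs]), 0.99)
  expect_lt(sqrt(mean(y300^2)) / sqrt(mean(x300^2)), 0.01)
})

test_that("band-pass filtering is linear and zero-phase", {
  fs <- 8000
  band <- bandSpec(75, 150)
  set.seed(1)
  x <- rnorm(fs); y <- rnorm(fs)
  h <- designBandpassFIR(band, fs)
  lhs <- zeroPhaseFilter(2 * x + 3 * y, h)
  rhs <- 2 * zeroPhaseFilter(x, h) + 3 * zeroPhaseFilter(y, h)
  expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-9)
  # sum of in-band and out-of-band tones filters to the in-band component
  both <- extractFundamentalWaveform(toneAt(100, 2, fs) + toneAt(300, 2, fs),
                                     fs, band, 1000)
  alone <- extractFundamentalWaveform(toneAt(100, 2, fs), fs, band, 1000)
  cs <- centralSpan(2000)
  expect_gt(cor(both[cs], alone[cs]), 0.99)
  # zero-phase: cross-correlation with a passband tone peaks at lag 0
  tone <- toneAt(100, 1, fs)
  filt <- zeroPhaseFilter(tone, h)
  cs <- centralSpan(fs)
  cc <- ccf(filt[cs], tone[cs], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("band spec is validated against the sampling rate", {
  expect_error(designBandpassFIR(bandSpec(75, 600), 1000), "Nyquist")
  expect_error(extractFundamentalWaveform(toneAt(50, 1, 200), 200,
                                          bandSpec(75, 150)), "too low")
  expect_error(bandSpec(150, 75), "fHi")
})

test_that("auditory spectrogram is tonotopic, nonnegative and silent on silence", {
  fs <- 8000
  spec <- auditorySpectrogram(toneAt(500, 1, fs), fs, nChannels = 32,
                              cfRange = c(180, 3500))
  expect_true(all(spec@values >= 0))
  avg <- colMeans(spec@values)
  expect_equal(which.max(avg), which.min(abs(spec@channelCF - 500)))
  silent <- auditorySpectrogram(numeric(fs), fs, nChannels = 8,
                                cfRange = c(180, 3500))
  expect_true(all(silent@values == 0))
  expect_error(auditorySpectrogram(toneAt(500, 1, fs), fs, nChannels = 1,
                                   cfRange = c(180, 3500)), "channels")
})

test_that("an amplitude-modulated tone leaves its modulation rate in the channel envelope", {
  fs <- 8000
  t <- (seq_len(2 * fs) - 0.5) / fs
  x <- (1 + cos(2 * pi * 100 * t)) * sin(2 * pi * 1000 * t)
  spec <- auditorySpectrogram(x, fs, nChannels = 32, cfRange = c(180, 3500))
  ch <- which.min(abs(spec@channelCF - 1000))
  env <- spec@values[, ch]
  env <- env[centralSpan(length(env))]     # drop onset/offset transients
  env <- env - mean(env)
  n <- length(env)
  p <- Mod(fft(env))[2:floor(n / 2)]
  freqs <- (1:(floor(n / 2) - 1)) * 1000 / n
  expect_lt(abs(freqs[which.max(p)] - 100), 2)
})

test_that("HF envelope modulation tracks the fundamental of a harmonic complex", {
  fs <- 8000
  t <- (seq_len(3 * fs) - 0.5) / fs
  x <- numeric(length(t))
  for (h in 3:10) x <- x + sin(2 * pi * 100 * h * t) / h
  spec <- auditorySpectrogram(x, fs, nChannels = 64, cfRange = c(180, 3500))
  f2full <- extractHFEnvelopeModulation(spec, eegRateBand(75, 150),
                                        cfMin = 300)
  f2 <- f2full[centralSpan(length(f2full), 0.8)]   # steady-state portion
  expect_lt(abs(mean(f2)), 0.01 * sd(f2))          # zero-mean (no DC in band)
  n <- length(f2)
  p <- Mod(fft(f2 - mean(f2)))[2:floor(n / 2)]
  freqs <- (1:(floor(n / 2) - 1)) * 1000 / n
  expect_lt(abs(freqs[which.max(p)] - 100), 2)
  # autocorrelation peak (outside the zero-lag main lobe) at the
  # fundamental period
  ac <- acf(f2, lag.max = 15, plot = FALSE)$acf[-1]
  expect_lt(abs(which.max(ac[6:15]) + 5 - 10), 2)  # 10 ms period
  # a pure low tone leaves nothing above 300 Hz
  pure <- auditorySpectrogram(toneAt(100, 3, fs), fs, nChannels = 64,
                              cfRange = c(180, 3500))
  f2pf <- extractHFEnvelopeModulation(pure, eegRateBand(75, 150), cfMin = 300)
  f2p <- f2pf[centralSpan(length(f2pf), 0.8)]
  expect_lt(sqrt(mean(f2p^2)), 0.01 * sqrt(mean(f2^2)))
  expect_error(extractHFEnvelopeModulation(pure, eegRateBand(), cfMin = 5000),
               "no spectrogram channel")
})

test_that("FIR order follows the Hamming transition rule at the study rates", {
  h44 <- designBandpassFIR(bandSpec(75, 150, 18.7, 38.12), 44100)
  expect_lt(abs(attr(h44, "order") - 3.3 * 44100 / 18.7), 3)
  h1k <- designBandpassFIR(eegRateBand(), 1000)
  expect_lt(abs(attr(h1k, "order") - 3.3 * 1000 / 12.5), 3)
})
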