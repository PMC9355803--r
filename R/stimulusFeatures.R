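# Stimulus feature extraction: fundamental waveform (f1) and high-frequency
# envelope modulation (f2), both delivered at the EEG sampling rate.

#' Band of a speaker's fundamental frequency from pitch percentiles
#'
#' Takes the requested percentiles of the voiced-frame f0 distribution of a
#' pitch track and returns them, rounded to the nearest Hz, as the corner
#' frequencies of the band-pass used to extract the fundamental waveform.
#' Percentiles interpolate linearly between order statistics. Unvoiced
#' frames are excluded.
#'
#' @param pitch a [PitchTrack-class].
#' @param loPct,hiPct percentiles in `[0, 100]`, `loPct < hiPct`. Defaults 5
#'   and 95, which for the narrative speaker studied here (mean f0 107.2 Hz,
#'   sd 24.8 Hz) give the 75-150 Hz band.
#' @param roundTo rounding granularity in Hz (1 = nearest Hz).
#' @param lowerTransition,upperTransition transition bandwidths (Hz) carried
#'   into the resulting [BandSpec-class].
#' @return A [BandSpec-class]. Errors if the track has fewer than two voiced
#'   frames or if the rounded band is degenerate (zero width).
#' @export
pitchBandFromPercentiles <- function(pitch, loPct = 5, hiPct = 95,
                                     roundTo = 1,
                                     lowerTransition = 18.7,
                                     upperTransition = 38.12) {
  stopifnot(is(pitch, "PitchTrack"))
  if (!(loPct >= 0 && loPct < hiPct && hiPct <= 100))
    stop("need 0 <= loPct < hiPct <= 100")
  f0 <- pitch@f0[!is.na(pitch@f0)]
  if (length(f0) == 0) stop("pitch track is entirely unvoiced: no pitch available")
  if (length(f0) < 2) stop("need at least 2 voiced frames")
  qs <- quantile(f0, probs = c(loPct, hiPct) / 100, names = FALSE, type = 7)
  qs <- round(qs / roundTo) * roundTo
  bandSpec(qs[1], qs[2], lowerTransition, upperTransition)
}

#' Extract the fundamental waveform from speech audio
#'
#' Band-passes the raw speech signal to the speaker's f0 range with a
#' zero-phase Hamming-windowed FIR (see [designBandpassFIR()]) and resamples
#' the result to the EEG rate. The output oscillates at the instantaneous
#' fundamental frequency of the voiced speech.
#'
#' @param audio numeric waveform.
#' @param fs sampling rate of `audio` (Hz); must be at least `2 * fHi`.
#' @param band a [BandSpec-class] (typically from
#'   [pitchBandFromPercentiles()]).
#' @param fsOut output sampling rate (Hz), the EEG rate.
#' @return numeric waveform of length `round(duration * fsOut)` with
#'   attributes `"firOrder"` and `"resample"` recording the design.
#' @export
extractFundamentalWaveform <- function(audio, fs, band, fsOut = 1000) {
  stopifnot(is(band, "BandSpec"))
  if (!all(is.finite(audio))) stop("audio must be finite")
  if (fs < 2 * band@fHi) stop("sampling rate too low for the requested band")
  h <- designBandpassFIR(band, fs)
  y <- zeroPhaseFilter(audio, h)
  out <- resampleTo(y, fs, fsOut, bandLimit = band@fHi + band@upperTransition)
  structure(as.numeric(out), firOrder = attr(h, "order"),
            resample = attr(out, "method"))
}

#' Auditory spectrogram via a filterbank approximation of the periphery
#'
#' Approximates early auditory processing by a bank of log-spaced band-pass
#' filters followed by half-wave rectification, leaky integration (8 ms time
#' constant) and cube-root compression, sampled at 1 ms steps. This
#' preserves the properties downstream code relies on - tonotopy, envelope
#' extraction and millisecond resolution - behind an interface that a full
#' cochlear model could equally fill.
#'
#' @param audio numeric waveform.
#' @param fs sampling rate (Hz).
#' @param nChannels number of filterbank channels (>= 2).
#' @param cfRange range of channel center frequencies in Hz; clipped to the
#'   Nyquist limit must hold.
#' @param timeStep output time step in seconds (default 1 ms).
#' @param tau leaky-integrator time constant in seconds.
#' @return An [AuditorySpectrogram-class].
#' @export
auditorySpectrogram <- function(audio, fs, nChannels = 128,
                                cfRange = c(180, 7000), timeStep = 0.001,
                                tau = 0.008) {
  if (!all(is.finite(audio))) stop("audio must be finite")
  if (nChannels < 2) stop("need at least 2 channels")
  if (cfRange[2] >= fs / 2) stop("cfRange must lie within the Nyquist range")
  cf <- exp(seq(log(cfRange[1]), log(cfRange[2]), length.out = nChannels))
  # channel bandwidth: at least one equivalent rectangular bandwidth
  # (cochlear-like, keeps low-frequency channels numerically well
  # conditioned), at least the geometric spacing (keeps dense banks
  # covering)
  step <- (cfRange[2] / cfRange[1])^(1 / (nChannels - 1))
  erb <- 24.7 * (4.37 * cf / 1000 + 1)
  bw <- pmax(erb, cf * (step - 1))
  lo <- pmax(cf - bw / 2, 1)
  hi <- pmin(cf + bw / 2, fs / 2 * 0.999)
  a <- exp(-1 / (tau * fs))
  idx <- round(seq(1, length(audio), by = timeStep * fs))
  out <- matrix(0, length(idx), nChannels)
  for (ch in seq_len(nChannels)) {
    bf <- signal::butter(3, c(lo[ch], hi[ch]) / (fs / 2), type = "pass")
    # forward-backward application: squared magnitude response (36
    # dB/oct skirts), limiting the cross-channel leakage that the
    # compressive nonlinearity would otherwise amplify
    y <- signal::filtfilt(bf, audio)
    y <- pmax(as.numeric(y), 0)                       # half-wave rectification
    y <- as.numeric(stats::filter(y * (1 - a), a, method = "recursive"))
    out[, ch] <- y[idx]
  }
  # compressive nonlinearity with a small floor (a hearing-threshold
  # analogue): cube-root compression alone would amplify numerically tiny
  # out-of-band leakage into visible energy
  out <- pmax(out, 0)
  eps <- 1e-3 * max(out)
  if (eps > 0) out <- (out + eps)^(1 / 3) - eps^(1 / 3)
  new("AuditorySpectrogram", values = out, channelCF = cf,
      timeStep = timeStep)
}

#' High-frequency envelope modulation from an auditory spectrogram
#'
#' Takes the spectrogram channels whose center frequency lies above
#' `cfMin` (the higher harmonics), band-passes each in the range of the
#' fundamental frequency with the same zero-phase FIR design as the
#' fundamental waveform, and averages across channels. The result captures
#' the periodicity of the envelope of the higher harmonics at the f0 rate
#' and is zero-mean since the band excludes 0 Hz.
#'
#' @param spec an [AuditorySpectrogram-class] (1 ms resolution).
#' @param band a [BandSpec-class]; transition defaults at the 1 kHz rate are
#'   12.5 Hz (lower) and 70 Hz (upper).
#' @param cfMin channels with center frequency above this participate (Hz).
#' @return numeric waveform at `1 / timeStep` Hz.
#' @export
extractHFEnvelopeModulation <- function(spec, band, cfMin = 300) {
  stopifnot(is(spec, "AuditorySpectrogram"), is(band, "BandSpec"))
  keep <- spec@channelCF > cfMin
  if (!any(keep)) stop("no spectrogram channel above cfMin = ", cfMin, " Hz")
  fs <- 1 / spec@timeStep
  h <- designBandpassFIR(band, fs)
  vals <- spec@values[, keep, drop = FALSE]
  out <- numeric(nrow(vals))
  for (ch in seq_len(ncol(vals)))
    out <- out + zeroPhaseFilter(vals[, ch], h)
  structure(out / ncol(vals), firOrder = attr(h, "order"))
}

#' EEG-rate band spec for filtering at 1 kHz
#'
#' Convenience constructor: same corner frequencies as the audio-rate band,
#' with the transition bandwidths used at the EEG rate (12.5 Hz lower,
#' 70 Hz upper).
#'
#' @param fLo,fHi corner frequencies (Hz).
#' @return A [BandSpec-class].
#' @export
eegRateBand <- function(fLo = 75, fHi = 150)
  bandSpec(fLo, fHi, lowerTransition = 12.5, upperTransition = 70)

#' Compute both stimulus features from audio
#'
#' End-to-end convenience wrapper: fundamental waveform by direct band-pass
#' of the audio, high-frequency envelope modulation through the auditory
#' spectrogram, both at the EEG rate and trimmed to a common length.
#'
#' @param audio numeric waveform.
#' @param fs audio sampling rate (Hz).
#' @param band audio-rate [BandSpec-class] for the f0 range.
#' @param fsOut EEG sampling rate (Hz).
#' @param nChannels,cfRange filterbank parameters for
#'   [auditorySpectrogram()]; `cfRange = NULL` picks `c(180, min(7000,
#'   0.45 fs))`.
#' @param cfMin harmonics threshold for [extractHFEnvelopeModulation()].
#' @return A [StimulusFeatures-class].
#' @export
computeStimulusFeatures <- function(audio, fs, band, fsOut = 1000,
                                    nChannels = 128, cfRange = NULL,
                                    cfMin = 300) {
  if (is.null(cfRange)) cfRange <- c(180, min(7000, 0.45 * fs))
  f1 <- extractFundamentalWaveform(audio, fs, band, fsOut)
  spec <- auditorySpectrogram(audio, fs, nChannels, cfRange,
                              timeStep = 1 / fsOut)
  bandOut <- eegRateBand(band@fLo, band@fHi)
  f2 <- extractHFEnvelopeModulation(spec, bandOut, cfMin)
  n <- min(length(f1), length(f2))
  stimulusFeatures(f1[seq_len(n)], f2[seq_len(n)], fsOut)
}
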