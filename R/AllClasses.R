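#' @import methods
#' @importFrom stats approx cor cor.test fft friedman.test mad median
#'   nextn p.adjust pnorm qnorm quantile rnorm runif sd var wilcox.test
#'   rgamma complete.cases
#' @importFrom utils head read.csv tail write.csv packageVersion
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Pitch track of a speech recording
#'
#' Frame-wise fundamental-frequency (f0) estimates. Unvoiced frames carry
#' `NA`; a frame is voiced exactly when its f0 is defined, so no separate
#' voicing detector is used anywhere downstream.
#'
#' @slot times frame-center times in seconds, strictly increasing.
#' @slot f0 fundamental frequency in Hz per frame; `NA` in unvoiced frames,
#'   strictly positive where defined.
#' @slot frameStep nominal frame step in seconds.
#'
#' @seealso [pitchTrack()], [pitchBandFromPercentiles()], [acousticFeatures()]
#' @export
setClass("PitchTrack",
  slots = c(times = "numeric", f0 = "numeric", frameStep = "numeric"))

setValidity("PitchTrack", function(object) {
  msg <- NULL
  if (length(object@times) != length(object@f0))
    msg <- c(msg, "times and f0 must have equal length")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  voiced <- !is.na(object@f0)
  if (any(object@f0[voiced] <= 0))
    msg <- c(msg, "defined f0 values must be positive")
  if (length(object@frameStep) != 1 || object@frameStep <= 0)
    msg <- c(msg, "frameStep must be a positive scalar")
  if (is.null(msg)) TRUE else msg
})

#' Construct a PitchTrack
#'
#' @param times frame-center times (s).
#' @param f0 f0 per frame in Hz, `NA` for unvoiced frames.
#' @param frameStep frame step in seconds; defaults to the median time step.
#' @return A [PitchTrack-class] object.
#' @export
pitchTrack <- function(times, f0, frameStep = NULL) {
  if (is.null(frameStep))
    frameStep <- if (length(times) > 1) median(diff(times)) else 0.01
  new("PitchTrack", times = as.numeric(times), f0 = as.numeric(f0),
      frameStep = frameStep)
}

#' Band-pass filter specification
#'
#' Corner frequencies and transition bandwidths of the FIR band-pass used to
#' extract the fundamental waveform (and to filter the auditory-spectrogram
#' channels). The design is a Hamming-windowed sinc, applied zero-phase.
#'
#' @slot fLo,fHi corner frequencies in Hz, `0 < fLo < fHi`.
#' @slot lowerTransition,upperTransition transition bandwidths in Hz.
#' @slot window window name; only `"hamming"` is implemented.
#' @slot phase phase convention; only `"zero"` is implemented.
#'
#' @seealso [bandSpec()], [extractFundamentalWaveform()]
#' @export
setClass("BandSpec",
  slots = c(fLo = "numeric", fHi = "numeric",
            lowerTransition = "numeric", upperTransition = "numeric",
            window = "character", phase = "character"))

setValidity("BandSpec", function(object) {
  msg <- NULL
  if (!(object@fLo > 0)) msg <- c(msg, "fLo must be positive")
  if (!(object@fHi > object@fLo))
    msg <- c(msg, "fHi must exceed fLo (degenerate or inverted band)")
  if (object@lowerTransition <= 0 || object@upperTransition <= 0)
    msg <- c(msg, "transition bandwidths must be positive")
  if (!identical(object@window, "hamming"))
    msg <- c(msg, "only the hamming window is supported")
  if (!identical(object@phase, "zero"))
    msg <- c(msg, "only zero-phase application is supported")
  if (is.null(msg)) TRUE else msg
})

#' Construct a BandSpec
#'
#' @param fLo,fHi corner frequencies (Hz).
#' @param lowerTransition,upperTransition transition bandwidths (Hz).
#' @return A [BandSpec-class] object.
#' @export
bandSpec <- function(fLo, fHi, lowerTransition = 18.7, upperTransition = 38.12) {
  new("BandSpec", fLo = fLo, fHi = fHi,
      lowerTransition = lowerTransition, upperTransition = upperTransition,
      window = "hamming", phase = "zero")
}

#' The two stimulus features of the speech signal
#'
#' `f1` is the fundamental waveform (the speech signal band-passed to the
#' speaker's f0 range); `f2` is the high-frequency envelope modulation (the
#' f0-band-filtered, channel-averaged envelope of auditory-spectrogram
#' channels above 300 Hz). Both are sampled at the EEG rate.
#'
#' @slot f1,f2 unitless waveforms of equal length.
#' @slot fs sampling rate in Hz.
#' @export
setClass("StimulusFeatures",
  slots = c(f1 = "numeric", f2 = "numeric", fs = "numeric"))

setValidity("StimulusFeatures", function(object) {
  msg <- NULL
  if (length(object@f1) != length(object@f2))
    msg <- c(msg, "f1 and f2 must have equal length")
  if (!all(is.finite(object@f1)) || !all(is.finite(object@f2)))
    msg <- c(msg, "stimulus features must be finite")
  if (length(object@fs) != 1 || object@fs <= 0)
    msg <- c(msg, "fs must be a positive scalar")
  if (is.null(msg)) TRUE else msg
})

#' Construct StimulusFeatures
#' @param f1,f2 waveforms of equal length.
#' @param fs sampling rate (Hz).
#' @return A [StimulusFeatures-class] object.
#' @export
stimulusFeatures <- function(f1, f2, fs = 1000) {
  new("StimulusFeatures", f1 = as.numeric(f1), f2 = as.numeric(f2), fs = fs)
}

#' Auditory spectrogram
#'
#' Output of the auditory-periphery approximation: nonnegative energy per
#' (time, channel) at millisecond resolution, with log-spaced channel center
#' frequencies.
#'
#' @slot values time-by-channel matrix of nonnegative energies.
#' @slot channelCF channel center frequencies (Hz), strictly increasing.
#' @slot timeStep time step in seconds (0.001 by construction).
#' @export
setClass("AuditorySpectrogram",
  slots = c(values = "matrix", channelCF = "numeric", timeStep = "numeric"))

setValidity("AuditorySpectrogram", function(object) {
  msg <- NULL
  if (ncol(object@values) != length(object@channelCF))
    msg <- c(msg, "one center frequency per channel required")
  if (length(object@channelCF) > 1 && any(diff(object@channelCF) <= 0))
    msg <- c(msg, "channel center frequencies must be strictly increasing")
  if (any(object@values < 0))
    msg <- c(msg, "spectrogram energies must be nonnegative")
  if (is.null(msg)) TRUE else msg
})

#' Multichannel EEG recording
#'
#' @slot data time-by-channel numeric matrix.
#' @slot fs sampling rate in Hz.
#' @slot channels channel labels, one per column.
#' @slot reference reference state, e.g. `"earlobe"` or `"average"`.
#' @export
setClass("EEGRecording",
  slots = c(data = "matrix", fs = "numeric", channels = "character",
            reference = "character"))

setValidity("EEGRecording", function(object) {
  msg <- NULL
  if (ncol(object@data) != length(object@channels))
    msg <- c(msg, "number of channel labels must match number of columns")
  if (length(object@fs) != 1 || object@fs <= 0)
    msg <- c(msg, "fs must be a positive scalar")
  if (is.null(msg)) TRUE else msg
})

#' Construct an EEGRecording
#' @param data time-by-channel matrix.
#' @param fs sampling rate (Hz).
#' @param channels channel labels; default `"Ch1".."ChN"`.
#' @param reference reference state label.
#' @return An [EEGRecording-class] object.
#' @export
eegRecording <- function(data, fs = 1000, channels = NULL,
                         reference = "unknown") {
  data <- as.matrix(data)
  if (is.null(channels)) channels <- paste0("Ch", seq_len(ncol(data)))
  new("EEGRecording", data = data, fs = fs, channels = channels,
      reference = reference)
}

#' Time-lag grid of a linear stimulus-response model
#'
#' Lags are expressed in milliseconds. A positive lag means the response at
#' time t is explained by the stimulus at t - lag (stimulus precedes the
#' response); negative lags are anticausal. The number of lags is fixed by
#' the grid: `nLags = round((lagMax - lagMin) * fs / 1000) + 1`.
#'
#' @slot lagMin,lagMax lag range in ms (lagMin may be negative).
#' @slot fs sampling rate in Hz.
#' @slot nLags number of lags.
#' @seealso [lagGrid()], [lagTimes()]
#' @export
setClass("LagGrid",
  slots = c(lagMin = "numeric", lagMax = "numeric", fs = "numeric",
            nLags = "integer"))

setValidity("LagGrid", function(object) {
  msg <- NULL
  expected <- as.integer(round((object@lagMax - object@lagMin) *
                                 object@fs / 1000) + 1)
  if (object@nLags != expected)
    msg <- c(msg, sprintf("nLags is %d but the grid implies %d",
                          object@nLags, expected))
  if (object@lagMax < object@lagMin)
    msg <- c(msg, "lagMax must not be below lagMin")
  if (is.null(msg)) TRUE else msg
})

#' Construct a LagGrid
#' @param lagMin,lagMax lag range in ms.
#' @param fs sampling rate (Hz).
#' @return A [LagGrid-class] object.
#' @examples
#' nLags(lagGrid(-250, 499, 1000))  # 750
#' nLags(lagGrid(-5, 49, 1000))     # 55
#' @export
lagGrid <- function(lagMin, lagMax, fs = 1000) {
  new("LagGrid", lagMin = lagMin, lagMax = lagMax, fs = fs,
      nLags = as.integer(round((lagMax - lagMin) * fs / 1000) + 1))
}

#' Complex-valued forward temporal response function
#'
#' Coefficients of the Hilbert-augmented forward model: the EEG at channel c
#' is modeled as a lagged linear combination of each stimulus feature and its
#' Hilbert transform; the paired real coefficients are assembled into one
#' complex coefficient per (lag, channel, feature), exposing response
#' magnitude and phase.
#'
#' @slot alpha complex array of dim (nLags, nChannels, nFeatures).
#' @slot lagGrid the [LagGrid-class] of the fit.
#' @slot lambdaN normalized ridge parameter used.
#' @slot em mean eigenvalue of the design covariance (the ridge unit).
#' @slot provenance named list recording preprocessing/standardization state.
#' @seealso [fitForwardTRF()], [trfSummary()]
#' @export
setClass("ComplexTRF",
  slots = c(alpha = "array", lagGrid = "LagGrid", lambdaN = "numeric",
            em = "numeric", provenance = "list"))

setValidity("ComplexTRF", function(object) {
  msg <- NULL
  if (!is.complex(object@alpha)) msg <- c(msg, "alpha must be complex")
  if (length(dim(object@alpha)) != 3)
    msg <- c(msg, "alpha must be (lag, channel, feature)")
  if (dim(object@alpha)[1] != object@lagGrid@nLags)
    msg <- c(msg, "first dimension of alpha must match the lag grid")
  if (any(!is.finite(Re(object@alpha))) || any(!is.finite(Im(object@alpha))))
    msg <- c(msg, "alpha must be finite")
  if (is.null(msg)) TRUE else msg
})

#' Backward stimulus-reconstruction decoder
#'
#' Real-valued coefficients reconstructing both stimulus features from
#' lagged multichannel EEG, for one normalized regularization value.
#'
#' @slot beta real array of dim (nLags, nChannels, nFeatures).
#' @slot lagGrid the [LagGrid-class] of the fit (-5..49 ms by default).
#' @slot lambdaN normalized ridge parameter.
#' @slot em mean eigenvalue of the lagged-EEG design covariance.
#' @seealso [fitBackwardDecoders()], [reconstructFeatures()]
#' @export
setClass("BackwardDecoder",
  slots = c(beta = "array", lagGrid = "LagGrid", lambdaN = "numeric",
            em = "numeric"))

setValidity("BackwardDecoder", function(object) {
  msg <- NULL
  if (length(dim(object@beta)) != 3)
    msg <- c(msg, "beta must be (lag, channel, feature)")
  if (dim(object@beta)[1] != object@lagGrid@nLags)
    msg <- c(msg, "first dimension of beta must match the lag grid")
  if (!all(is.finite(object@beta))) msg <- c(msg, "beta must be finite")
  if (is.null(msg)) TRUE else msg
})

#' Toy Markov-chain language model
#'
#' A first-order Markov chain over a small vocabulary. Serves as a language
#' probability source with exact, closed-form surprisal, entropy and unigram
#' (stationary) probabilities, standing behind the same interface that a
#' neural language model would fill for real text.
#'
#' @slot vocabulary token labels.
#' @slot transition row-stochastic K-by-K next-token matrix.
#' @slot unigram stationary distribution (satisfies pi P = pi).
#' @seealso [toyLanguageModel()], [generateWordStream()]
#' @export
setClass("ToyLanguageModel",
  slots = c(vocabulary = "character", transition = "matrix",
            unigram = "numeric"))

setValidity("ToyLanguageModel", function(object) {
  msg <- NULL
  K <- length(object@vocabulary)
  if (!all(dim(object@transition) == c(K, K)))
    msg <- c(msg, "transition must be K x K")
  if (any(abs(rowSums(object@transition) - 1) > 1e-9))
    msg <- c(msg, "transition rows must sum to 1")
  if (length(object@unigram) != K)
    msg <- c(msg, "unigram must have one entry per token")
  if (abs(sum(object@unigram) - 1) > 1e-9)
    msg <- c(msg, "unigram must sum to 1")
  statErr <- max(abs(drop(object@unigram %*% object@transition) -
                       object@unigram))
  if (statErr > 1e-6)
    msg <- c(msg, "unigram must be the stationary distribution of transition")
  if (is.null(msg)) TRUE else msg
})
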