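#' Sampling rate accessor
#' @param object an object with a sampling rate.
#' @return sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "EEGRecording", function(object) object@fs)

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "StimulusFeatures", function(object) object@fs)

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "LagGrid", function(object) object@fs)

#' Number of lags in a lag grid
#' @param object a [LagGrid-class] (or object carrying one).
#' @return integer lag count.
#' @export
setGeneric("nLags", function(object) standardGeneric("nLags"))

#' @rdname nLags
#' @export
setMethod("nLags", "LagGrid", function(object) object@nLags)

#' @rdname nLags
#' @export
setMethod("nLags", "ComplexTRF", function(object) object@lagGrid@nLags)

#' @rdname nLags
#' @export
setMethod("nLags", "BackwardDecoder", function(object) object@lagGrid@nLags)

#' Lag times of a grid
#' @param object a [LagGrid-class] or model carrying one.
#' @return numeric vector of lags in ms.
#' @export
setGeneric("lagTimes", function(object) standardGeneric("lagTimes"))

#' @rdname lagTimes
#' @export
setMethod("lagTimes", "LagGrid", function(object)
  object@lagMin + (seq_len(object@nLags) - 1) * 1000 / object@fs)

#' @rdname lagTimes
#' @export
setMethod("lagTimes", "ComplexTRF", function(object) lagTimes(object@lagGrid))

#' @rdname lagTimes
#' @export
setMethod("lagTimes", "BackwardDecoder", function(object)
  lagTimes(object@lagGrid))

#' Channel labels
#' @param object an [EEGRecording-class].
#' @return character vector of channel labels.
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' @rdname channelNames
#' @export
setMethod("channelNames", "EEGRecording", function(object) object@channels)

#' Signal matrix accessor
#' @param object an [EEGRecording-class] or [AuditorySpectrogram-class].
#' @return numeric matrix (time by channel).
#' @export
setGeneric("signalMatrix", function(object) standardGeneric("signalMatrix"))

#' @rdname signalMatrix
#' @export
setMethod("signalMatrix", "EEGRecording", function(object) object@data)

#' @rdname signalMatrix
#' @export
setMethod("signalMatrix", "AuditorySpectrogram", function(object)
  object@values)

#' Voiced-frame subset of a pitch track
#' @param object a [PitchTrack-class].
#' @return data.frame with columns `time` and `f0` over voiced frames only.
#' @export
setGeneric("voicedFrames", function(object) standardGeneric("voicedFrames"))

#' @rdname voicedFrames
#' @export
setMethod("voicedFrames", "PitchTrack", function(object) {
  keep <- !is.na(object@f0)
  data.frame(time = object@times[keep], f0 = object@f0[keep])
})

setMethod("show", "PitchTrack", function(object) {
  voiced <- sum(!is.na(object@f0))
  cat(sprintf("PitchTrack: %d frames (%d voiced), step %.3g s\n",
              length(object@f0), voiced, object@frameStep))
  if (voiced)
    cat(sprintf("  f0 range %.1f-%.1f Hz, mean %.1f Hz\n",
                min(object@f0, na.rm = TRUE), max(object@f0, na.rm = TRUE),
                mean(object@f0, na.rm = TRUE)))
})

setMethod("show", "BandSpec", function(object) {
  cat(sprintf(
    "BandSpec: %.4g-%.4g Hz (transitions %.4g/%.4g Hz, %s window, %s phase)\n",
    object@fLo, object@fHi, object@lowerTransition, object@upperTransition,
    object@window, object@phase))
})

setMethod("show", "StimulusFeatures", function(object) {
  cat(sprintf(
    "StimulusFeatures: %d samples at %g Hz (%.2f s)\n",
    length(object@f1), object@fs, length(object@f1) / object@fs))
})

setMethod("show", "AuditorySpectrogram", function(object) {
  cat(sprintf(
    "AuditorySpectrogram: %d frames x %d channels (%.4g-%.4g Hz), step %g s\n",
    nrow(object@values), ncol(object@values), min(object@channelCF),
    max(object@channelCF), object@timeStep))
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d samples x %d channels at %g Hz (%s reference)\n",
              nrow(object@data), ncol(object@data), object@fs,
              object@reference))
})

setMethod("show", "LagGrid", function(object) {
  cat(sprintf("LagGrid: %g..%g ms at %g Hz (%d lags)\n",
              object@lagMin, object@lagMax, object@fs, object@nLags))
})

setMethod("show", "ComplexTRF", function(object) {
  d <- dim(object@alpha)
  cat(sprintf(
    "ComplexTRF: %d lags x %d channels x %d features (lambda_n = %g, em = %.4g)\n",
    d[1], d[2], d[3], object@lambdaN, object@em))
})

setMethod("show", "BackwardDecoder", function(object) {
  d <- dim(object@beta)
  cat(sprintf(
    "BackwardDecoder: %d lags x %d channels x %d features (lambda_n = %g)\n",
    d[1], d[2], d[3], object@lambdaN))
})

setMethod("show", "ToyLanguageModel", function(object) {
  cat(sprintf("ToyLanguageModel: %d tokens, entropy rate %.4f nats\n",
              length(object@vocabulary), entropyRate(object)))
})
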