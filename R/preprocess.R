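# EEG preprocessing applied ahead of model fitting: band-pass to the
# analysis band around the speech fundamental and re-referencing to the
# channel average.

#' Preprocess an EEG recording for f0-band analysis
#'
#' Band-passes every channel between `fLo` and `fHi` (zero-phase
#' Hamming-window FIR; transition bandwidths 12.5 Hz below and 70 Hz
#' above at 1 kHz) and re-references to the channel average. Models fitted
#' downstream record this contract in their provenance.
#'
#' @param rec an [EEGRecording-class].
#' @param fLo,fHi analysis band corners in Hz (defaults 50 and 280).
#' @param rereference re-reference to the average (default TRUE).
#' @return a new [EEGRecording-class] with reference `"average"` (when
#'   re-referenced) and filtered data.
#' @export
preprocessEEG <- function(rec, fLo = 50, fHi = 280, rereference = TRUE) {
  stopifnot(is(rec, "EEGRecording"))
  band <- bandSpec(fLo, fHi, lowerTransition = 12.5, upperTransition = 70)
  h <- designBandpassFIR(band, rec@fs)
  M <- rec@data
  for (c in seq_len(ncol(M))) M[, c] <- zeroPhaseFilter(M[, c], h)
  ref <- rec@reference
  if (rereference) {
    M <- M - rowMeans(M)
    ref <- "average"
  }
  new("EEGRecording", data = M, fs = rec@fs, channels = rec@channels,
      reference = ref)
}
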