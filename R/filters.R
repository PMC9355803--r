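# FIR design and zero-phase filtering primitives shared by the stimulus
# features and EEG preprocessing. All band-pass kernels are Hamming-windowed
# sincs, applied by forward convolution with exact group-delay compensation
# (linear phase, odd length), which is the zero-phase contract documented in
# BandSpec.

# Hamming-windowed sinc lowpass kernel, odd length n, cutoff fc (Hz).
.firLowpass <- function(n, fc, fs) {
  stopifnot(n %% 2 == 1)
  m <- (n - 1) / 2
  k <- seq(-m, m)
  h <- 2 * fc / fs * sinc(2 * fc / fs * k)
  w <- 0.54 + 0.46 * cos(pi * k / m)  # Hamming, symmetric
  h <- h * w
  h / sum(h) * 1  # unity DC gain for the lowpass prototype
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Design the band-pass FIR kernel for a band specification
#'
#' Hamming-windowed sinc design. The kernel length follows the standard
#' Hamming transition rule `N ~ 3.3 fs / df` applied to the narrower (lower)
#' transition band, rounded up to an odd length; half-amplitude cutoffs sit
#' at the corner frequencies. The kernel is linear-phase; zero-phase
#' application is performed by [zeroPhaseFilter()].
#'
#' @param band a [BandSpec-class].
#' @param fs sampling rate of the signal to be filtered (Hz).
#' @return numeric kernel (odd length) with attribute `"order"` (length - 1).
#' @examples
#' h <- designBandpassFIR(bandSpec(75, 150), fs = 44100)
#' attr(h, "order")
#' @export
designBandpassFIR <- function(band, fs) {
  stopifnot(is(band, "BandSpec"))
  if (band@fHi >= fs / 2)
    stop("band upper corner must lie below the Nyquist frequency (",
         fs / 2, " Hz)")
  tb <- min(band@lowerTransition, band@upperTransition)
  n <- ceiling(3.3 * fs / tb)
  if (n %% 2 == 0) n <- n + 1
  h <- .firLowpass(n, band@fHi, fs) - .firLowpass(n, band@fLo, fs)
  attr(h, "order") <- n - 1
  h
}

#' Zero-phase FIR filtering
#'
#' Applies a linear-phase (symmetric, odd-length) FIR kernel by FFT-based
#' convolution and compensates the group delay exactly, so a passband tone
#' comes out with zero lag. The signal is zero-padded at the edges; roughly
#' half a kernel length at each end is edge-affected.
#'
#' @param x numeric signal.
#' @param h FIR kernel of odd length.
#' @return filtered signal, same length as `x`.
#' @export
zeroPhaseFilter <- function(x, h) {
  n <- length(x)
  m <- length(h)
  if (m %% 2 != 1) stop("kernel must have odd length (linear phase)")
  nf <- nextn(n + m - 1, 2)
  y <- Re(fft(fft(c(x, numeric(nf - n))) *
              fft(c(h, numeric(nf - m))), inverse = TRUE)) / nf
  delay <- (m - 1) / 2
  y[(delay + 1):(delay + n)]
}

# FFT linear convolution of x with kernel k, "full" length n + m - 1.
.fftConvolve <- function(x, k) {
  n <- length(x); m <- length(k)
  nf <- nextn(n + m - 1, 2)
  out <- Re(fft(fft(c(x, numeric(nf - n))) *
                fft(c(k, numeric(nf - m))), inverse = TRUE)) / nf
  out[seq_len(n + m - 1)]
}

#' Anti-aliased resampling to a lower rate
#'
#' Applies a Hamming-windowed sinc anti-aliasing lowpass at 90% of the
#' output Nyquist frequency (skipped when the input is declared band-limited
#' below it) followed by linear interpolation onto the output grid. Linear
#' interpolation is transparent here because every signal that reaches this
#' resampler is confined far below the output Nyquist frequency. The output
#' length is `round(duration * fsOut)`.
#'
#' @param x input signal.
#' @param fsIn,fsOut input and output sampling rates (Hz).
#' @param bandLimit highest frequency present in `x` if known (Hz); used to
#'   skip the redundant anti-aliasing pass.
#' @return resampled signal with attribute `"method"` describing the path.
#' @export
resampleTo <- function(x, fsIn, fsOut, bandLimit = NULL) {
  if (fsOut == fsIn) return(x)
  method <- "linear interpolation"
  cutoff <- 0.45 * fsOut
  if (fsOut < fsIn && (is.null(bandLimit) || bandLimit > cutoff)) {
    n <- ceiling(3.3 * fsIn / (0.1 * fsOut))
    if (n %% 2 == 0) n <- n + 1
    x <- zeroPhaseFilter(x, .firLowpass(n, cutoff, fsIn))
    method <- "windowed-sinc anti-alias + linear interpolation"
  }
  nOut <- round(length(x) / fsIn * fsOut)
  tOut <- (seq_len(nOut) - 1) / fsOut
  tIn <- (seq_along(x) - 1) / fsIn
  out <- approx(tIn, x, xout = pmin(tOut, max(tIn)))$y
  attr(out, "method") <- method
  out
}

#' Imaginary part of the analytic signal (Hilbert transform)
#'
#' Computes the analytic signal by one-sided spectrum doubling in the
#' frequency domain and returns its imaginary part. Applied once over whole
#' recordings, before any lagging or segmentation, to keep boundary
#' distortion minimal.
#'
#' @param x finite numeric signal, length >= 2.
#' @return numeric vector, same length: the Hilbert transform of `x`.
#' @examples
#' t <- seq(0, 1, by = 1e-3)
#' max(abs(hilbertImag(cos(2 * pi * 100 * t)) - sin(2 * pi * 100 * t)))
#' @export
hilbertImag <- function(x) {
  if (!all(is.finite(x))) stop("input must be finite")
  n <- length(x)
  if (n < 2) stop("input must have length >= 2")
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Im(fft(X * h, inverse = TRUE) / n)
}

# Standardize a vector / columns of a matrix to zero mean, unit sd.
.standardize <- function(x) {
  if (is.matrix(x)) {
    mu <- colMeans(x)
    s <- sqrt(colMeans(x^2) - mu^2)
    s[s == 0] <- 1
    sweep(sweep(x, 2, mu), 2, s, "/")
  } else {
    s <- sd(x)
    if (!is.finite(s) || s == 0) s <- 1
    (x - mean(x)) / s
  }
}
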