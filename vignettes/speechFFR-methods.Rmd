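---
title: "Measuring word-level modulation of the EEG response at the fundamental frequency of speech"
author: "speechFFR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring word-level modulation of the EEG response at the fundamental frequency of speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(speechFFR)
```

# The scientific problem

Voiced speech carries a fundamental frequency (f0), for a typical male
narrator roughly 75–150 Hz, together with a stack of higher harmonics.
The auditory pathway produces a frequency-following response at f0 that
is visible in scalp EEG at very short latencies (around 10–20 ms). This
package implements a complete analysis chain for asking a specific
question about that response during natural, continuous listening: *is
its strength, word by word, modulated by acoustic and linguistic
properties of the words?*

The chain has five stages:

1. **Stimulus features.** Two time series are derived from the speech
   audio at the EEG rate (1 kHz): the *fundamental waveform* `f1` (the
   audio band-passed to the speaker's f0 range, obtained from the 5th and
   95th percentiles of the pitch distribution) and the *high-frequency
   envelope modulation* `f2` (auditory-spectrogram channels above 300 Hz,
   band-passed in the f0 range and averaged). `f2` captures the
   periodicity of the envelope of the higher harmonics, which drives a
   response at f0 even where the audio itself carries no energy at f0.

2. **Forward model.** A complex-valued temporal response function (TRF)
   is fitted by ridge regression from `f1`, `f2` *and their Hilbert
   transforms* to every EEG channel over a grid of time lags (750 lags,
   −250…499 ms at 1 kHz). Pairing each feature with its quadrature
   component and reading the coefficient pairs as complex numbers makes
   the magnitude of the TRF an envelope — insensitive to the oscillatory
   phase of the narrowband regressors — so the lag of its peak is the
   response latency. Lag significance is assessed against null models
   fitted on time-reversed features, via bootstrap resampling of subjects
   with replacement (add-one empirical p-values, Benjamini–Yekutieli
   corrected across lags).

3. **Backward model.** Real-valued decoders reconstruct both stimulus
   features from 55 lags of multichannel EEG (−5…49 ms; the EEG is read
   up to 49 ms *after* the stimulus sample being reconstructed, which is
   where the short-latency response lives, with a 5 ms acausal margin).
   Decoders are fitted for 51 normalized regularization values
   (λₙ from 10⁻¹⁰ to 10¹⁰, with the effective penalty λₙ·e_m expressed in
   units of the mean eigenvalue e_m of the design covariance) under
   five-fold cross-validation over contiguous, equal-duration folds.
   Reconstruction quality is Pearson's r, per evaluation segment
   (fixed durations, word boundaries, or per-word voiced spans).

4. **Word scoring.** Each word is scored by the decoders of the fold
   that held it out, over the union of its voiced intervals, for every
   λₙ, for the actual and the time-reversed null decoders. The per-word
   response strength is the null-corrected score
   `r(i) = max_λ r_model(i) − max_λ r_null(i)`, with the maxima taken
   independently. Scores are averaged over subjects and standardized.

5. **Hierarchical regression.** Each word carries seven features: mean
   f0, f0 rate of change (mean |df0/dt| over voiced frames), voiced
   duration, inverted word frequency (−ln of the unigram probability),
   surprisal (−ln of the conditional probability given the context),
   precision (inverse conditional next-word entropy) and
   precision × surprisal. After isolation-forest outlier removal on the
   eight standardized descriptors (seven features + the score), the
   population scores are regressed on the features *stepwise in a fixed
   hierarchy* — acoustic features first — each step a single-predictor
   Huber fit on the residuals of the previous steps, so shared variance
   is conservatively credited to the earlier, lower-level features. The
   seven coefficient p-values are BY-corrected jointly.

Language-model probabilities enter through a pluggable
`probabilitySource()` interface: any model that can supply per-position
realized-word probabilities and next-word entropies (or full conditional
distributions) can stand behind it. The package ships an exactly
solvable first-order Markov-chain language model for validation.

# The synthetic-data generator

`syntheticSpec()` + `simulateStudy()` generate a complete study —
stimulus features, pitch track, word alignment with voiced intervals,
correlated word features, and multichannel EEG — with known ground
truth, so every stage of the chain can be validated without recordings.

**What it emulates.** A single narrator (per-word mean f0 drawn from a
normal distribution with mean 107.2 Hz, sd 24.8 Hz, matching a typical
male storyteller), lognormal word durations with mean 0.26 s, 50 ms
inter-word gaps, voiced fraction 0.75, per-word linear pitch ramps whose
absolute slope is the word's f0 rate-of-change feature, slow within-word
pitch fluctuation (`f0Jitter`, sd 8 Hz — natural pitch is never a pure
tone), and per-word intensity variation (`amplitudeJitterSd = 0.5`,
about 4 dB of level sd). The seven word features are drawn from a
Gaussian copula with near-linear marginals hitting a realistic
correlation structure (strong surprisal–interaction and inverted
frequency–duration coupling, weak elsewhere); `sampleWordFeatures()`
reproduces the target matrix to about 0.01 mean absolute deviation at
5,000 words.

**The planted response.** Each EEG channel is the sum over the two
features of the convolution of the (gain-modulated) feature with a
response kernel, plus noise. Design choices that matter:

* *Kernel shape.* The kernel is a Gabor — a Gaussian envelope at the
  target latency (11 ms for `f1`, 18 ms for `f2`, widths 2/3 ms,
  amplitude ratio 1:2) carrying an oscillation at the speaker's mean f0.
  A frequency-following response tracks the stimulus fine structure, so
  its kernel must *pass* the f0 band; a plain low-pass (Gaussian) kernel
  would attenuate 150 Hz words by orders of magnitude relative to 75 Hz
  words and imprint a spurious, purely mechanical dependence of response
  strength on a word's mean f0.

* *f2 phase jitter.* The synthetic `f2` shares `f1`'s instantaneous
  frequency (envelope periodicity), offset by a base phase plus a
  per-word random phase (sd 0.8 rad). Without the jitter `f2` would lie
  exactly in the span of `f1` and its Hilbert transform and the two
  kernels would not be identifiable; the base phase is set so the
  expected f1–f2 correlation is about −0.28, as in natural speech.

* *Noise.* Per channel, the noise is a phase-randomized surrogate of the
  *unmodulated* clean response, scaled to the spec's SNR. Matching the
  noise spectrum to the signal keeps the signal-to-noise ratio flat
  across frequencies, so a word's position in the corpus f0 distribution
  does not mechanically change how well it can be reconstructed. The
  surrogate is taken of the unmodulated response on purpose: shaping the
  noise by the *modulated* response would cancel, in the SNR profile,
  exactly those planted gain effects that covary with spectral position
  (in particular any planted mean-f0 effect).

* *SNR default −20 dB.* Calibrated so that per-word reconstruction
  scores come out at the magnitudes seen for real scalp responses at the
  fundamental (r of order 0.1–0.2). This is also the regime in which the
  null-corrected score behaves as intended: the per-word maxima of model
  and null scores carry comparable small-sample inflation, which then
  cancels in their difference.

* *Planted word-level modulation.* The per-word gain
  `1 + Σ β_m x_im` (standardized features, `modulationBetas`) multiplies
  the stimulus feature before convolution — the simplest mechanism by
  which "the response to this word is stronger/weaker".

**What it does not emulate.** Realistic EEG artifacts (blinks, line
noise), head-model topographies (channel weights are random fixed
loadings), phonetic segment structure within words, or cross-sentence
prosody. Passing tests on synthetic data therefore validate the
*estimation machinery* — not the physiological claims one would make
from real recordings.

# Numerical choices

* FIR band-passes are Hamming-windowed sincs; the length follows the
  standard transition rule N ≈ 3.3·fs/Δf applied to the narrower
  transition band (18.7 Hz at 44.1 kHz for audio, 12.5 Hz at 1 kHz),
  rounded to odd length; zero phase by forward FFT convolution with
  exact group-delay compensation. Edge regions of roughly half a kernel
  length are edge-affected; analyses use central spans where it matters.
* The auditory periphery is approximated by a log-spaced filterbank
  (default 128 channels, 180–7000 Hz) with at-least-ERB channel
  bandwidths, forward–backward Butterworth filtering, half-wave
  rectification, 8 ms leaky integration at 1 ms steps and cube-root
  compression with a small hearing-threshold-like floor (the floor stops
  the compressive nonlinearity from amplifying numerically tiny
  out-of-band leakage). The original cochlear model can be dropped in
  behind the `AuditorySpectrogram` container.
* Ridge systems are solved on the covariance scale,
  (X'X/n + λₙ·e_m·I)a = X'Y/n with e_m = trace(X'X/n)/p, via one
  symmetric eigendecomposition per training set shared by the whole λ
  grid. Lagged designs use the valid-sample convention (no zero
  padding); Hilbert transforms are computed once per recording part
  before lagging.
* The Huber step uses k = 1.345, MAD scale re-estimated per iteration,
  convergence at 1e-8, at most 200 iterations, no intercept (both sides
  standardized), and an asymptotic sandwich standard error with normal
  p-values. An exact fit (zero residual scale) short-circuits to the
  least-squares solution. Note the stepwise-equals-simple-slope identity
  for orthogonal predictors is exact only in the least-squares limit;
  with Huber weights active the two differ at the 1e-3 level.
* The isolation forest uses 1000 trees, subsamples of 256, height limit
  ceil(log2 256), exact harmonic numbers in the path-length normalizer
  (so c(2) = 1), and the automatic anomaly threshold s > 0.5.
* Friedman tests with all-identical score columns return statistic 0 and
  p 1 (rank variance is zero); paired Wilcoxon tests drop zero
  differences, use the exact distribution for n ≤ 25 without ties, and
  return p = 1 when no nonzero differences remain.
* Synthetic recording parts are padded with trailing silence to
  multiples of 4096 samples so that whole-part FFTs (Hilbert transforms,
  convolutions, spectral surrogates) stay fast for any word count.

# Design decisions that were genuinely open

* **Backward lag direction.** A lag range of −5…49 ms for a decoder can
  be read two ways; this package reconstructs the stimulus at time t
  from EEG at t+τ, i.e. EEG recorded up to 49 ms *after* the stimulus.
  That is the only reading under which the decoder can see the
  11–30 ms response at all; the opposite reading still "works" on
  narrowband features — by periodic extrapolation — but produces
  implausibly high scores with strong artifactual dependence on pitch
  stability.
* **Outlier removal per response feature.** The isolation forest runs
  separately for each stimulus feature's analysis, on that feature's
  score plus the seven word features (eight descriptors).
* **Voiced-only scoring.** Words are scored over the union of their
  voiced intervals (the features are silent elsewhere); a switch allows
  full-span scoring. Words without any voiced interval are excluded;
  spans shorter than 20 samples are scored but flagged.
* **Score aggregation.** Arithmetic mean of segment r values (a
  Fisher-z switch exists in the duration analysis tests only as an
  evaluation device, not in the pipeline).
* **Null-model scoring.** The time-reversed-feature decoder is evaluated
  against the *actual* feature on the same segments; that is the
  chance-level reference the correction subtracts.

# Known limitations

Two calibration properties of the per-word null-corrected score deserve
explicit warning, because they surfaced repeatedly while validating the
pipeline end-to-end:

* **The fixed-λ control.** With a genuine response present, the
  per-word-max procedure is systematically *lower* than scoring at a
  fixed λₙ = 1 (the null's max-over-λ inflation exceeds the model's once
  the model genuinely decodes). The two procedures agree, in the paired
  sense, only when scores are noise-dominated.
* **Conservative bootstrap p-values.** The lag-significance bootstrap
  resamples subject-level null models *with replacement* and averages
  them before taking magnitudes. The magnitude of a resampled average
  systematically exceeds the magnitude of the plain average (by the
  resampling variance, of order σ²/S), so the empirical per-lag p-values
  are conservative: under a global null the p < 0.05 rate is nearer 1%
  than 5%, at any subject count. False-positive control is therefore
  stronger than nominal; sensitivity is correspondingly somewhat lower.

* **A small positive offset of the corrected score under the global
  null.** Even with EEG containing no response at all, the per-word-max
  corrected score averages slightly above zero (about +0.007, some 2% of
  the per-word score spread): decoders trained toward the actual
  features retain a marginally higher best-over-λ chance score than
  decoders trained toward time-reversed features. The offset sits
  within two (pooled-word) standard errors in the packaged calibration
  runs, but it is systematic; per-word scores should not be read as
  absolutely zero-centered under a null.

* **Residual stimulus-locked structure in the null correction.** The
  time-reversed null decoder picks up a small, random, *filtered copy*
  of the true response. Because every subject hears the same story, this
  phantom component does not average out across subjects; each word's f0
  samples its smooth frequency-phase curve coherently, so regressions of
  null-corrected scores on word features can show spurious mean-f0 (and,
  through sampling-variance effects, voiced-duration) coefficients with
  study-to-study standardized z values of a few units even when no
  modulation was planted. The planted-modulation recovery tests pass
  robustly because the planted effects are much larger, but a
  zero-modulation study is *not* reliably silent on the acoustic
  features. Readers applying this pipeline to real data should treat
  small acoustic coefficients with corresponding caution; linguistic
  features are essentially unaffected (they do not map onto spectral
  position or word length).

# Problem sizes used by the test-suite and acceptance runs

Synthetic studies in the packaged tests use 4 EEG channels (64 in a real
lab study; channel count scales decoder cost quadratically and affects
mainly the combined SNR), 5 recording parts = 5 folds, 5 subjects, and
5,000 words for full-scale parameter-recovery runs (fewer for unit
tests). End-to-end recovery runs use 4 seeded replicates and
zero-modulation (null) runs 3; latency-recovery runs use ~60 s of
synthetic narration; the bootstrap lag calibration uses 13 subjects
(the scale the resampling statistic is designed for) and 2,000 draws
(10,000 is the analysis default). These sizes are the package's own
desk-scale choices and are stated here so that results are read at the
scale they were computed.

# A worked example

```{r example}
library(speechFFR)

spec <- syntheticSpec(nWords = 1000, nSubjects = 3,
                      modulationBetas = c(-0.17, -0.07, 0, -0.04, 0, 0, 0),
                      modulateFeature = 2, seed = 1)
study <- simulateStudy(spec)

## forward response: latency of the planted kernels
fw <- forwardResponsePipeline(study, lagGrid(-50, 150, 1000),
                              nBoot = 2000, seed = 1)
fw$summary$peakLagMs      # ~ 11 and 18 ms
fw$significance           # significant latency ranges per feature

## word-level analysis: decoders, null-corrected scores, regression
words <- wordResponsePipeline(study, scoreFeatures = 2)
words$regressions$f2      # stepwise hierarchical coefficient table
```
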