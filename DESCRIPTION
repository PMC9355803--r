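Package: speechFFR
Title: Word-Level Modulation of the EEG Response at the Fundamental
    Frequency of Continuous Speech
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for measuring the early electrophysiological response at
    the fundamental frequency of continuous speech and its modulation by
    word-level acoustic and linguistic features. Extracts the fundamental
    waveform and the high-frequency envelope modulation from speech audio,
    fits complex-valued (Hilbert-augmented) forward temporal response
    functions and real-valued backward decoders by normalized ridge
    regression, scores the neural response word by word against
    time-reversed null models, and relates the per-word scores to acoustic
    and information-theoretic word features (frequency, surprisal,
    precision) through isolation-forest outlier removal and stepwise
    hierarchical Huber regression. A synthetic-data module generates
    speech-like stimuli, toy language models with exact information-theoretic
    ground truth, and EEG with planted response kernels and planted
    word-level gain modulation, so the whole pipeline can be exercised and
    validated without any external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
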