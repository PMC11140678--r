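Package: cortrack
Title: Decoding Cortical Tracking of Spoken-Word Features from Evoked MEG Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs time-varying and time-integrated auditory and linguistic
    features of spoken-word stimuli from evoked sensor responses. Implements an
    auditory filterbank spectrogram, amplitude envelope, frequency spectrum,
    modulation power spectrum and phoneme-sequence features; a kernel (dual) ridge
    convolution decoder with leave-one-out penalty selection, a dual ridge decoder
    for static features, and per-phoneme logistic decoders; leave-two-out pairwise
    evaluation with label-permutation significance; lag-resolved decoding curves
    and cluster-based permutation tests for group comparisons; and a forward
    simulator that generates two-cohort synthetic evoked responses so the full
    analysis runs without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
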