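Package: ltposc
Title: Hippocampal LTP and Neuronal-Oscillation Analysis Around High-Frequency Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-channel hippocampal EEG/LFP recorded
    around high-frequency stimulation (HFS) of the perforant path, together
    with evoked field-potential quantification of long-term potentiation
    (LTP). Implements artifact-aware extraction of 4.1 s epochs from five
    100 s analysis windows, IIR notch filtering and Welch/FFT band-power
    spectra expressed relative to the pre-HFS baseline, envelope-to-signal
    correlation (ESC) phase-amplitude coupling on a Morlet wavelet filter
    bank with circular block-swap surrogate normalization, comodulograms and
    theta-gamma coupling time courses across the ten HFS epochs, fEPSP-slope
    and population-spike measures with baseline-normalized LTP time courses,
    and an Anderson-Darling-gated statistical comparison procedure. A
    synthetic-data generator with known ground-truth coupling, band power and
    plasticity makes every stage testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    nortest,
    minpack.lm,
    data.table,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
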