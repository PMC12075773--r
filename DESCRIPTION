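Package: olfconn
Title: Linear and Nonlinear Connectivity Analysis of Multi-Region Olfactory
    Field Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing odorant representations in multi-region
    local field potential (LFP) recordings: Welch spectra with baseline
    subtraction, complex Morlet wavelet scaleograms with baseline z-scoring,
    magnitude-squared coherence, phase-lag indices (PLI/wPLI) from Hilbert
    analytic signals, weighted symbolic mutual information (wSMI) from ordinal
    patterns, Gaussian-copula co-information (redundancy/synergy) about
    stimulus class, and time-frequency spectral decoding with cluster-based
    permutation inference. Includes a synthetic LFP generator emulating
    odor-evoked narrow-band oscillations across olfactory bulb and
    telencephalic regions, with configurable linear and nonlinear inter-region
    coupling and class-encoding modes, used as the reference input for all
    analysis stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC
Config/testthat/edition: 3
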