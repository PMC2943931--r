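Package: topocov
Title: Topographic Covariance Mapping of EEG Spectral Fluctuations and
    fMRI Resting-State Network Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links the spatial distribution of EEG spectral power
    fluctuations to the temporal dynamics of fMRI resting-state networks
    (RSNs). Provides back-projection of BOLD data onto group network
    templates, extraction of hemodynamically lagged pre-scan EEG spectral
    epochs with two-stage normalization, electrode-by-frequency covariance
    mapping against network dynamics, data-driven discovery of frequency
    band borders by k-means clustering of t-map topographies, and global
    randomization statistics (topographic consistency test, one- and
    two-factorial TANOVA). A seeded synthetic-data generator with planted
    coupling structure makes every stage testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
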