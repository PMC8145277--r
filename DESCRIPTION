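Package: qeegpipe
Title: Quantitative Pharmaco-EEG Analysis with Exact Cluster Permutation Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis workflow for within-subject
    pharmaco-EEG studies: synthetic paired-session multichannel EEG and
    behavioral data, preprocessing (zero-phase filtering, downsampling,
    ocular correction, threshold artifact detection, channel and interval
    interpolation, common-average 1-s epoching), quantitative EEG features
    (Hjorth parameters, spectrum-weighted mean frequency, binned Shannon
    entropy, normalized power spectra), and nonparametric inference via
    exact sign-flip cluster-based permutation tests plus Wilcoxon
    signed-rank statistics with Benjamini-Hochberg correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
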