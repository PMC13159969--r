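Package: meapop
Title: Population Activity Analysis for Multi-Electrode Array Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for analysing spontaneous population
    activity recorded from neural cultures on multi-electrode arrays (MEAs):
    band-pass filtering and threshold-based spike detection, PCA plus
    Gaussian-mixture spike sorting with waveform-correlation merging and
    interspike-interval validation, amplitude-weighted unit localization with
    positional entropy, stationarity screening via half-split rates and
    Kullback-Leibler divergence of moving-rate distributions, Gaussian-smoothed
    pairwise correlations, count and word entropies of the binarized
    population raster, and a second-order maximum-entropy (pairwise Ising)
    model fitted by exact enumeration whose held-out KL divergence quantifies
    population complexity.  A synthetic-data module generates ground-truth
    spike trains (exact Ising sampling, dichotomized-Gaussian correlated
    trains) and raw extracellular voltage with planted units, so every stage
    is verifiable against known structure.  Group comparisons use the
    Brunner-Munzel rank test with Bonferroni correction, alongside
    Kolmogorov-Smirnov, Levene, Welch and Wilcoxon tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    mclust,
    MASS,
    car,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
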