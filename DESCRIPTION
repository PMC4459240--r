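Package: mratio
Title: Multivariate Ratio Analysis of Linear Body Measurements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for delimiting and diagnosing morphologically similar
    species from linear body measurements using multivariate ratio analysis:
    an isometric size axis (isosize) and log-shape coordinates, shape
    principal component analysis, PCA and allometry ratio spectra with
    bootstrap confidence intervals, and an exhaustive ratio extractor that
    ranks body ratios by their standard distance between two groups and
    reports the size-versus-shape measure delta. Includes measurement
    quality control by pairwise log-correlations, deterministic imputation
    of missing measurements, a quantitative dichotomous identification key
    for Anisopteromalus females, Kimura 2-parameter sequence distance
    summaries, and a synthetic-data generator with known ground truth for
    validating every step of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, ape
Suggests: testthat (>= 3.0.0), jsonlite, withr, cluster, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
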