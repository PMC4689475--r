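Package: emonet
Title: Frequency and Network Structure of Everyday Emotions from
    Experience-Sampling Data
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing experience-sampling (ESM/EMA) reports of
    discrete emotions. Provides a SummarizedExperiment-based container for
    binary emotion reports, multilevel (compound-symmetry) estimation of
    emotion frequencies with 95% confidence intervals, report categorisation
    (positive-only, negative-only, mixed, none), hour-of-day and day-of-week
    frequency profiles with a temporal fluctuation-magnitude statistic, a
    signed phi-correlation emotion network with degree centrality and a
    connector/provincial/distal node typology, group comparisons of
    centrality profiles, and a Gaussian-copula (multivariate probit)
    generator of synthetic ESM datasets with participant random intercepts,
    together with the closed-form phi correlations it implies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, lme4, jsonlite, xml2
Suggests: testthat (>= 3.0.0), optparse, knitr, rmarkdown
Config/testthat/edition: 3
biocViews: Software, StatisticalMethod, Network, TimeCourse
RoxygenNote: 7.3.3
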