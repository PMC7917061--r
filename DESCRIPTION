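Package: cdmdim
Title: Dimensionality Assessment for Cognitive Diagnosis Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for determining the number of latent attributes underlying
    dichotomous cognitive-diagnosis (CDM) data. Implements DINA and G-DINA model
    estimation by marginal maximum likelihood (EM), a Monte Carlo simulator for
    CDM response data (constrained random Q-matrices, thresholded equicorrelated
    multivariate-normal attribute profiles, banded item-quality parameters),
    classical dimensionality-assessment statistics (parallel analysis with column
    permutation, minimum average partial, very simple structure, DETECT, empirical
    Kaiser criterion), empirical Q-matrix estimation (discrete factor loadings) and
    validation (Hull/PVAF), a model-comparison procedure that selects the number of
    attributes by AIC, BIC or pairwise residual counts, and a simulation-study
    harness with hit-rate, bias, error and agreement metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
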